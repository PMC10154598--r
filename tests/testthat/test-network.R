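test_that("channel attention reproduces the closed-form special cases", {
  withr::with_seed(2L, {
    C <- 8L
    W0 <- matrix(rnorm(4L * C, sd = 0.5), 4L, C)
    W1 <- matrix(rnorm(C * 4L, sd = 0.5), C, 4L)
    # spatially constant map: avg and max descriptors coincide, so the gate
    # is sigmoid(2 * MLP(avg))
    const_vals <- rnorm(C)
    f <- array(rep(const_vals, each = 16L), c(4L, 4L, C))
    ca <- channel_attention(f, list(W0 = W0, W1 = W1))
    mlp <- function(v) as.vector(W1 %*% pmax(W0 %*% v, 0))
    expect_equal(ca$weights, 1 / (1 + exp(-2 * mlp(const_vals))),
                 tolerance = 1e-12)
    expect_equal(ca$avg, ca$max)
    # all-zero MLP weights: every gate is sigmoid(0) = 0.5
    ca0 <- channel_attention(f, list(W0 = W0 * 0, W1 = W1 * 0))
    expect_equal(ca0$weights, rep(0.5, C))
  })
})

test_that("channel attention matches a direct evaluation of the formula", {
  withr::with_seed(3L, {
    C <- 8L
    f <- array(rnorm(4L * 4L * C), c(4L, 4L, C))
    W0 <- matrix(rnorm(2L * C, sd = 0.3), 2L, C)
    W1 <- matrix(rnorm(C * 2L, sd = 0.3), C, 2L)
    ca <- channel_attention(f, list(W0 = W0, W1 = W1))
    avg <- apply(f, 3L, mean)
    mx <- apply(f, 3L, max)
    mlp <- function(v) as.vector(W1 %*% pmax(W0 %*% v, 0))
    expected <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
    expect_equal(ca$weights, expected, tolerance = 1e-12)
    expect_true(all(ca$weights > 0 & ca$weights < 1))
  })
})

test_that("spatial attention is a gated 7x7 convolution over pooled maps", {
  withr::with_seed(4L, {
    f <- array(rnorm(3L * 3L * 2L), c(3L, 3L, 2L))
    # kernel zero except the centre tap on the channel-mean map
    kern <- array(0, c(7L, 7L, 2L, 1L))
    kern[4L, 4L, 1L, 1L] <- 1.7
    sa <- spatial_attention(f, list(kernel = kern, bias = 0))
    mean_map <- apply(f, c(1L, 2L), mean)
    expect_equal(sa$weights, 1 / (1 + exp(-1.7 * mean_map)),
                 tolerance = 1e-12)
    # shape and range contracts on an arbitrary input
    f2 <- array(rnorm(9L * 5L * 6L), c(9L, 5L, 6L))
    kern2 <- array(rnorm(98L, sd = 0.2), c(7L, 7L, 2L, 1L))
    sa2 <- spatial_attention(f2, list(kernel = kern2, bias = 0.1))
    expect_identical(dim(sa2$weights), c(9L, 5L))
    expect_true(all(sa2$weights > 0 & sa2$weights < 1))
  })
})

test_that("CBAM applies channel then spatial gates multiplicatively", {
  withr::with_seed(5L, {
    C <- 4L
    params <- list(W0 = matrix(rnorm(2L * C), 2L, C),
                   W1 = matrix(rnorm(C * 2L), C, 2L),
                   kernel = array(rnorm(98L, sd = 0.2), c(7L, 7L, 2L, 1L)),
                   bias = 0)
    zero <- array(0, c(5L, 5L, C))
    expect_equal(cbam_apply(zero, params), zero)
    f <- array(rnorm(4L * 5L * C), c(4L, 5L, C))
    out <- cbam_apply(f, params)
    expect_identical(dim(out), dim(f))
    # sequential application equals the fused operator
    ca <- channel_attention(f, params)
    fp <- f * rep(ca$weights, each = 20L)
    sa <- spatial_attention(fp, params)
    expect_equal(out, fp * as.vector(sa$weights), tolerance = 1e-12)
    # attention only attenuates: |F''| <= |F| elementwise
    expect_true(all(abs(out) <= abs(f) + 1e-12))
  })
})

test_that("dense blocks equal their unrolled composite-function chain", {
  withr::with_seed(6L, {
    blk <- daunet:::new_dense_block(4L, 3L, 2L, 0)
    x <- array(rnorm(6L * 6L * 4L), c(6L, 6L, 4L))
    y <- module_forward(blk, x, train = FALSE)
    # manual layer-by-layer chaining of BN -> ReLU -> conv -> dropout
    feats <- list(x)
    for (i in 1:3) {
      ly <- blk$sub[[paste0("layer", i)]]
      inp <- do.call(daunet:::cat_channels, feats)
      h <- module_forward(ly$bn, inp, train = FALSE)
      h <- module_forward(ly$relu, h, train = FALSE)
      h <- module_forward(ly$conv, h, train = FALSE)
      h <- module_forward(ly$drop, h, train = FALSE)
      feats[[i + 1L]] <- h
    }
    concat <- do.call(daunet:::cat_channels, feats)
    expect_identical(dim(concat)[3L], 4L + 3L * 2L)  # cin + n * growth
    manual <- module_forward(blk$sub$transition, concat, train = FALSE)
    expect_equal(y, manual, tolerance = 1e-12)
    # eval-mode determinism
    expect_identical(module_forward(blk, x), module_forward(blk, x))
  })
})

test_that("GN-ASPP has four parallel branches and preserves spatial size", {
  withr::with_seed(7L, {
    aspp <- daunet:::new_gn_aspp(8L, c(6L, 12L, 18L), 4L)
    expect_identical(aspp$n_branches, 4L)
    x <- array(rnorm(32L * 32L * 8L), c(32L, 32L, 8L))
    y <- module_forward(aspp, x)
    expect_identical(dim(y), dim(x))
    dils <- vapply(2:4, function(i)
      aspp$sub[[paste0("branch", i)]]$conv$dilation, integer(1))
    expect_identical(dils, c(6L, 12L, 18L))
    expect_error(daunet:::new_gn_aspp(8L, c(2L, 3L, 4L), 3L), "gn_groups")
  })
})

test_that("the channel schedule doubles per stage and mirrors in the decoder", {
  cfg <- network_config(base_channels = 8L, depth = 4L, cbam_reduction = 4L,
                        gn_groups = 4L, seed = 1L)
  net <- build_network(cfg)
  enc_widths <- vapply(net$enc, function(st) st[[1L]]$cout, integer(1))
  expect_identical(enc_widths, c(8L, 16L, 32L, 64L))
  dec_widths <- vapply(net$dec, function(dm) dm$up$cout, integer(1))
  expect_identical(dec_widths, c(8L, 16L, 32L))   # halves on the way up
})

test_that("network builds are reproducible and forward preserves shape", {
  cfg <- tiny_net_config(seed = 13L)
  n1 <- build_network(cfg)
  n2 <- build_network(cfg)
  expect_equal(daunet:::get_param_state(n1$modules),
               daunet:::get_param_state(n2$modules))
  x <- matrix(runif(32L * 32L), 32L)
  l1 <- net_forward(n1, x)
  expect_identical(dim(l1), c(32L, 32L, 2L))
  expect_equal(l1, net_forward(n2, x), tolerance = 1e-14)
  # batch independence in eval mode
  both <- net_forward(n1, list(x, x))
  expect_identical(both[[1L]], both[[2L]])
  expect_error(net_forward(n1, matrix(0, 33L, 33L)), "divisible by 2")
})

test_that("parameter counts respond to width and toggles as expected", {
  base <- tiny_net_config(seed = 1L)
  all_off <- tiny_net_config(seed = 1L, use_dense = FALSE,
                             use_cbam = FALSE, use_aspp = FALSE)
  n_all <- count_parameters(build_network(base))
  n_off <- count_parameters(build_network(all_off))
  expect_lt(n_off, n_all)
  # enabling any single toggle never removes parameters
  for (tog in c("use_dense", "use_cbam", "use_aspp")) {
    args <- list(seed = 1L, use_dense = FALSE, use_cbam = FALSE,
                 use_aspp = FALSE)
    args[[tog]] <- TRUE
    n_one <- count_parameters(build_network(do.call(tiny_net_config, args)))
    expect_gt(n_one, n_off)
  }
  wider <- network_config(base_channels = 8L, depth = 2L,
                          cbam_reduction = 2L, gn_groups = 2L,
                          dense_layers = 2L, seed = 1L)
  expect_gt(count_parameters(build_network(wider)), n_all)
})

test_that("a minimal plain backbone matches a hand-tallied parameter count", {
  cfg <- network_config(base_channels = 4L, depth = 2L, use_dense = FALSE,
                        use_cbam = FALSE, use_aspp = FALSE,
                        cbam_reduction = 2L, gn_groups = 2L, seed = 1L)
  net <- build_network(cfg)
  tally <- sum(
    3L * 3L * 1L * 4L + 4L,   # encoder 1, conv 1 -> 4
    3L * 3L * 4L * 4L + 4L,   # encoder 1, conv 4 -> 4
    3L * 3L * 4L * 8L + 8L,   # encoder 2, conv 4 -> 8
    3L * 3L * 8L * 8L + 8L,   # encoder 2, conv 8 -> 8
    2L * 2L * 8L * 4L + 4L,   # up-convolution 8 -> 4
    1L * 1L * 8L * 2L + 2L,   # asymmetric fusion projection 8 -> 2
    3L * 3L * 10L * 4L + 4L,  # decoder conv on the 4+4+2 concatenation
    3L * 3L * 4L * 4L + 4L,   # decoder conv 2
    3L * (3L * 3L * 4L * 4L + 4L),  # head: three 3x3 convs
    1L * 1L * 4L * 2L + 2L    # final 1x1 to 2 classes
  )
  expect_identical(count_parameters(net), tally)
})

test_that("checkpoints round-trip and refuse mismatched configurations", {
  cfg <- tiny_net_config(seed = 3L)
  net <- build_network(cfg)
  x <- matrix(runif(32L * 32L), 32L)
  before <- net_forward(net, x)
  path <- file.path(withr::local_tempdir(), "ck.rds")
  save_checkpoint(net, path, meta = list(epoch = 1L))
  other <- build_network(tiny_net_config(seed = 99L))
  meta <- load_checkpoint(other, path)     # same architecture, new weights
  expect_identical(meta$epoch, 1L)
  expect_equal(net_forward(other, x), before, tolerance = 1e-14)
  diff_cfg <- build_network(tiny_net_config(seed = 3L, num_classes = 3L))
  expect_error(load_checkpoint(diff_cfg, path), "hash")
})

test_that("configuration invariants are enforced at construction", {
  expect_error(network_config(base_channels = 6L, cbam_reduction = 4L),
               "cbam_reduction")
  expect_error(network_config(base_channels = 12L, gn_groups = 8L,
                              cbam_reduction = 4L), "gn_groups")
  expect_error(network_config(depth = 1L), "depth")
  expect_error(network_config(dropout_rate = 1), "dropout_rate")
})
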