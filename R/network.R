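#' Network architecture configuration
#'
#' Describes the dense-attention encoder-decoder: a U-shaped backbone whose
#' contraction path doubles the channel width at every stage (64, 128, 256,
#' 512, 1024 with the defaults), dense blocks in the encoder, convolutional
#' block attention (CBAM) in the decoder, symmetric plus asymmetric skip
#' fusion, and a group-normalized atrous spatial pyramid pooling (GN-ASPP)
#' head. The three `use_*` switches are the ablation toggles; with all three
#' off the model reduces to the plain fusion U-Net backbone.
#'
#' @param in_channels Input image channels (1 for a single DWI slice).
#' @param num_classes Output classes: 2 for a single-target model (background
#'   vs gland, or background vs lesion), 3 for the joint
#'   background/gland/lesion model.
#' @param base_channels First-stage width; stage `i` has width
#'   `base_channels * 2^(i-1)`.
#' @param depth Number of encoder stages (5 gives the 64..1024 schedule).
#' @param cbam_reduction Reduction ratio `r` of the shared channel-attention
#'   MLP; must divide the channel count at every CBAM site (i.e.
#'   `base_channels`).
#' @param gn_groups Groups for the ASPP group normalization; must divide
#'   `base_channels`.
#' @param aspp_rates Dilation rates of the three dilated ASPP branches.
#' @param dense_layers Composite layers per dense block.
#' @param dropout_rate Dropout rate inside dense-block composite layers.
#' @param use_dense,use_cbam,use_aspp Ablation toggles.
#' @param seed Seed for parameter initialization.
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_channels = 1L, num_classes = 2L,
                           base_channels = 64L, depth = 5L,
                           cbam_reduction = 16L, gn_groups = 8L,
                           aspp_rates = c(6L, 12L, 18L), dense_layers = 4L,
                           dropout_rate = 0.1, use_dense = TRUE,
                           use_cbam = TRUE, use_aspp = TRUE, seed = 1L) {
  in_channels <- check_count(in_channels, "in_channels")
  num_classes <- check_count(num_classes, "num_classes", min = 2L)
  base_channels <- check_count(base_channels, "base_channels", min = 2L)
  depth <- check_count(depth, "depth", min = 2L)
  cbam_reduction <- check_count(cbam_reduction, "cbam_reduction")
  gn_groups <- check_count(gn_groups, "gn_groups")
  if (!is.numeric(aspp_rates) || length(aspp_rates) != 3L ||
      any(aspp_rates < 1))
    abort_config("aspp_rates", "must be three positive integers")
  dense_layers <- check_count(dense_layers, "dense_layers")
  dropout_rate <- check_number(dropout_rate, "dropout_rate", 0, 1,
                               open_max = TRUE)
  use_dense <- check_flag(use_dense, "use_dense")
  use_cbam <- check_flag(use_cbam, "use_cbam")
  use_aspp <- check_flag(use_aspp, "use_aspp")
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  if (use_cbam && base_channels %% cbam_reduction != 0L)
    abort_config("cbam_reduction",
                 sprintf("(%d) must divide base_channels (%d), the smallest CBAM site",
                         cbam_reduction, base_channels))
  if (use_aspp && base_channels %% gn_groups != 0L)
    abort_config("gn_groups",
                 sprintf("(%d) must divide base_channels (%d)", gn_groups,
                         base_channels))
  if (use_dense && base_channels %% 4L != 0L)
    abort_config("base_channels",
                 "must be divisible by 4 so dense growth = width/4 is integral")
  structure(list(in_channels = in_channels, num_classes = num_classes,
                 base_channels = base_channels, depth = depth,
                 cbam_reduction = cbam_reduction, gn_groups = gn_groups,
                 aspp_rates = as.integer(aspp_rates),
                 dense_layers = dense_layers, dropout_rate = dropout_rate,
                 use_dense = use_dense, use_cbam = use_cbam,
                 use_aspp = use_aspp, seed = seed),
            class = "network_config")
}

stage_width <- function(config, s)
  as.integer(config$base_channels * 2^(s - 1))

# architecture fingerprint: the init seed does not affect checkpoint
# compatibility, so it is excluded
config_hash <- function(config) {
  u <- unclass(config)
  rlang::hash(u[setdiff(names(u), "seed")])
}

#' Build the segmentation network
#'
#' Assembles the encoder (per stage: two 3x3 conv+ReLU, then a dense block
#' when `use_dense`, with 2x2 max-pooling between stages), the decoder (per
#' step: 2x2 up-convolution halving the width, concatenation with the
#' same-level encoder features plus an asymmetric fusion of the next-deeper
#' encoder stage -- bilinearly upsampled and 1x1-projected to half the
#' symmetric skip's width -- then two 3x3 conv+ReLU each followed by CBAM
#' when `use_cbam`), and the head (three 3x3 conv+ReLU, GN-ASPP when
#' `use_aspp`, and a final 1x1 convolution to `num_classes` logits). All
#' parameters are drawn from `config$seed`, so two builds from the same
#' configuration are identical.
#'
#' @param config A [network_config()].
#' @return An object of class `daunet_network`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  net <- new.env(parent = emptyenv())
  net$config <- config
  with_seed(config$seed, {
    depth <- config$depth
    widths <- vapply(seq_len(depth), function(s) stage_width(config, s),
                     integer(1))
    net$enc <- lapply(seq_len(depth), function(s) {
      w <- widths[s]
      cin <- if (s == 1L) config$in_channels else widths[s - 1L]
      mods <- list(new_conv(cin, w), new_relu(), new_conv(w, w), new_relu())
      if (config$use_dense)
        mods <- c(mods, list(new_dense_block(w, config$dense_layers,
                                             w %/% 4L,
                                             config$dropout_rate)))
      mods
    })
    net$pool <- lapply(seq_len(depth - 1L), function(s) new_maxpool2())
    net$dec <- lapply(seq_len(depth - 1L), function(s) {
      w <- widths[s]                     # target width at this level
      wb <- widths[s + 1L]               # width arriving from below
      proj_w <- max(1L, w %/% 2L)        # asymmetric-fusion projection width
      mods <- list(
        up = new_convt2(wb, w),
        asym = new_conv(wb, proj_w, k = 1L),
        conv1 = new_conv(w + w + proj_w, w), relu1 = new_relu(),
        conv2 = new_conv(w, w), relu2 = new_relu())
      if (config$use_cbam) {
        mods$cbam1 <- new_cbam(w, config$cbam_reduction)
        mods$cbam2 <- new_cbam(w, config$cbam_reduction)
      }
      mods
    })
    w1 <- widths[1L]
    head <- list(new_conv(w1, w1), new_relu(), new_conv(w1, w1), new_relu(),
                 new_conv(w1, w1), new_relu())
    if (config$use_aspp)
      head <- c(head, list(new_gn_aspp(w1, config$aspp_rates,
                                       config$gn_groups)))
    net$head <- head
    net$final <- new_conv(w1, config$num_classes, k = 1L)
  })
  net$modules <- leaf_modules(list(net$enc, net$pool, net$dec, net$head,
                                   net$final))
  class(net) <- "daunet_network"
  net
}

#' @export
print.daunet_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<daunet_network depth %d, widths %s, classes %d,",
                     " dense=%s cbam=%s aspp=%s, %d parameters>\n"),
              cfg$depth,
              paste(vapply(seq_len(cfg$depth),
                           function(s) stage_width(cfg, s), integer(1)),
                    collapse = "-"),
              cfg$num_classes, cfg$use_dense, cfg$use_cbam, cfg$use_aspp,
              count_parameters(x)))
  invisible(x)
}

check_input_shape <- function(net, x) {
  div <- 2L^(net$config$depth - 1L)
  d <- dim(x)
  if (d[1L] %% div != 0L || d[2L] %% div != 0L)
    stop(sprintf(paste0("input height and width (%d x %d) must be divisible",
                        " by 2^(depth-1) = %d"), d[1L], d[2L], div),
         call. = FALSE)
  if (d[3L] != net$config$in_channels)
    stop(sprintf("input has %d channels, network expects %d", d[3L],
                 net$config$in_channels), call. = FALSE)
  invisible(NULL)
}

#' Forward pass
#'
#' Maps one image (or a list of images) to per-pixel class logits with the
#' same spatial dimensions as the input (same-padding throughout, so no
#' border cropping is needed to align predictions with masks).
#'
#' @param net A built [build_network()] network.
#' @param x `(H, W)` matrix, `(H, W, in_channels)` array, or a list of them.
#' @param train Training mode (dropout active, batch statistics live).
#' @return `(H, W, num_classes)` logits array (or a list of them).
#' @export
net_forward <- function(net, x, train = FALSE) {
  if (is.list(x))
    return(lapply(x, function(xi) net_forward(net, xi, train)))
  x <- as_cube(x)
  check_input_shape(net, x)
  cfg <- net$config
  depth <- cfg$depth
  e <- vector("list", depth)
  cur <- x
  for (s in seq_len(depth)) {
    e[[s]] <- seq_forward(net$enc[[s]], cur, train)
    if (s < depth) cur <- module_forward(net$pool[[s]], e[[s]], train)
  }
  d <- e[[depth]]
  for (s in rev(seq_len(depth - 1L))) {
    dm <- net$dec[[s]]
    up <- module_forward(dm$up, d, train)
    deeper <- e[[s + 1L]]
    big <- cpp_bilinear_fwd(deeper, dim(up)[1L], dim(up)[2L])
    asym <- module_forward(dm$asym, big, train)
    h <- cat_channels(up, e[[s]], asym)
    h <- module_forward(dm$relu1, module_forward(dm$conv1, h, train), train)
    if (cfg$use_cbam) h <- module_forward(dm$cbam1, h, train)
    h <- module_forward(dm$relu2, module_forward(dm$conv2, h, train), train)
    if (cfg$use_cbam) h <- module_forward(dm$cbam2, h, train)
    d <- h
  }
  h <- seq_forward(net$head, d, train)
  logits <- module_forward(net$final, h, train)
  net$cache <- list(e_dims = lapply(e, dim))
  logits
}

# Backward pass for one sample; call immediately after net_forward on the
# same input. Accumulates parameter gradients into the modules.
net_backward <- function(net, dlogits) {
  cfg <- net$config
  depth <- cfg$depth
  dh <- module_backward(net$final, dlogits)
  dd <- seq_backward(net$head, dh)
  de <- lapply(net$cache$e_dims, function(d) array(0, dim = d))
  for (s in seq_len(depth - 1L)) {
    dm <- net$dec[[s]]
    if (cfg$use_cbam) dd <- module_backward(dm$cbam2, dd)
    dd <- module_backward(dm$conv2, module_backward(dm$relu2, dd))
    if (cfg$use_cbam) dd <- module_backward(dm$cbam1, dd)
    dcat <- module_backward(dm$conv1, module_backward(dm$relu1, dd))
    w <- dim(de[[s]])[3L]
    dup <- dcat[, , seq_len(w), drop = FALSE]
    de[[s]] <- de[[s]] + dcat[, , w + seq_len(w), drop = FALSE]
    dasym <- dcat[, , (2L * w + 1L):dim(dcat)[3L], drop = FALSE]
    dbig <- module_backward(dm$asym, dasym)
    dims <- net$cache$e_dims[[s + 1L]]
    de[[s + 1L]] <- de[[s + 1L]] +
      cpp_bilinear_bwd(dbig, dims[1L], dims[2L])
    dbelow <- module_backward(dm$up, dup)
    if (s + 1L <= depth - 1L) dd <- dbelow
    else de[[depth]] <- de[[depth]] + dbelow
  }
  dcur <- NULL
  for (s in rev(seq_len(depth))) {
    dstage <- de[[s]]
    if (!is.null(dcur)) dstage <- dstage + dcur
    dx <- seq_backward(net$enc[[s]], dstage)
    dcur <- if (s > 1L) module_backward(net$pool[[s - 1L]], dx) else dx
  }
  invisible(dcur)
}

#' Count trainable parameters
#'
#' @param net A built network.
#' @return Total number of trainable scalar parameters.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "daunet_network"))
  n_params(net$modules)
}

#' Save / load a network checkpoint
#'
#' A checkpoint stores the full parameter state together with a hash of the
#' architecture configuration; loading into a network whose configuration
#' hash differs is refused.
#'
#' @param net A built network.
#' @param path Checkpoint file path.
#' @param meta Optional named list stored alongside (e.g. epoch, metrics).
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   invisibly returns the stored `meta`.
#' @export
save_checkpoint <- function(net, path, meta = list()) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(config = net$config, hash = config_hash(net$config),
               params = get_param_state(net$modules),
               running = lapply(net$modules, function(m) {
                 if (m$kind == "bn") list(mean = m$running_mean,
                                          var = m$running_var) else NULL
               }),
               meta = meta, package_version =
                 as.character(packageVersion("daunet"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(net, path) {
  ck <- readRDS(path)
  if (!identical(ck$hash, config_hash(net$config)))
    stop("checkpoint was written for a different network configuration ",
         "(config hash mismatch)", call. = FALSE)
  set_param_state(net$modules, ck$params)
  for (i in seq_along(net$modules)) {
    if (net$modules[[i]]$kind == "bn" && !is.null(ck$running[[i]])) {
      net$modules[[i]]$running_mean <- ck$running[[i]]$mean
      net$modules[[i]]$running_var <- ck$running[[i]]$var
    }
  }
  invisible(ck$meta)
}

# ---------------------------------------------------------------------------
# functional attention surface (operates on plain arrays + parameter lists)

#' Channel attention weights
#'
#' Computes `M_C = sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F)))` where the
#' average and max pools are global per-channel spatial descriptors and the
#' shared two-layer perceptron is `W1 %*% relu(W0 %*% x)` with a `C/r`
#' bottleneck.
#'
#' @param f `(H, W, C)` feature array.
#' @param params List with `W0` (`C/r x C`) and `W1` (`C x C/r`) matrices.
#' @return List of class `channel_attention_weights` with `weights` (length
#'   `C`, each strictly in (0, 1)), and the `avg` and `max` descriptors.
#' @export
channel_attention <- function(f, params) {
  f <- as_cube(f)
  stopifnot(is.matrix(params$W0), is.matrix(params$W1),
            ncol(params$W0) == dim(f)[3L],
            nrow(params$W1) == dim(f)[3L],
            nrow(params$W0) == ncol(params$W1))
  r <- ca_forward(f, params$W0, params$W1)
  structure(list(weights = r$weights, avg = r$avg, max = r$max),
            class = "channel_attention_weights")
}

#' Spatial attention map
#'
#' Stacks the channel-wise mean and max maps into a 2-channel field, applies
#' a 7x7 same-padded convolution and a sigmoid, giving one attention weight
#' in (0, 1) per pixel.
#'
#' @param f `(H, W, C)` feature array.
#' @param params List with `kernel` (array `c(7, 7, 2, 1)` or the equivalent
#'   `98 x 1` matrix) and optional scalar `bias`.
#' @return List of class `spatial_attention_map` with `weights`, an
#'   `(H, W)` matrix of values strictly in (0, 1).
#' @export
spatial_attention <- function(f, params) {
  f <- as_cube(f)
  conv <- new_conv(2L, 1L, k = 7L)
  kern <- params$kernel
  if (!is.null(dim(kern)) && length(dim(kern)) == 4L)
    dim(kern) <- c(prod(dim(kern)[1:3]), dim(kern)[4L])
  stopifnot(nrow(kern) == 98L)
  conv$params$W <- as.matrix(kern)
  conv$params$b <- as.numeric(params$bias %||% 0)
  r <- sa_forward(f, conv, train = FALSE)
  structure(list(weights = r$weights), class = "spatial_attention_map")
}

#' Apply a full CBAM step
#'
#' `F' = M_C(F) (x) F` (per-channel) then `F'' = M_S(F') (x) F'`
#' (per-pixel), both gates sigmoid-bounded so attention can only attenuate.
#'
#' @param f `(H, W, C)` feature array.
#' @param params List with `W0`, `W1` (channel MLP) and `kernel`, `bias`
#'   (spatial 7x7 convolution).
#' @return `(H, W, C)` array of the same shape as `f`.
#' @export
cbam_apply <- function(f, params) {
  f <- as_cube(f)
  ca <- channel_attention(f, params)
  fp <- scale_channels(f, ca$weights)
  sa <- spatial_attention(fp, params)
  fp * as.vector(sa$weights)
}
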