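# Minimal define-by-wire neural-network layer framework.
#
# Every layer ("module") is an environment holding its parameters, gradient
# accumulators and the forward cache of the most recent call. Batches are
# processed one sample at a time with backward() invoked directly after the
# corresponding forward(), so a single cache per module suffices; gradients
# accumulate additively across the samples of a batch and are cleared with
# zero_grads(). Feature maps are (H, W, C) arrays.
#
# Convolution weights use the layout documented in src/ops.cpp: an
# (k*k*Cin, Cout) matrix whose row index is ki + kj*k + ci*k*k (0-based),
# equivalent to an R array of dim c(k, k, Cin, Cout).

new_module <- function(.kind, .params = list(), .sub = list(), ...) {
  m <- new.env(parent = emptyenv())
  m$kind <- .kind
  m$params <- .params
  m$grads <- lapply(.params, zeros_like)
  m$sub <- .sub
  m$cache <- NULL
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = m)
  class(m) <- "daunet_module"
  m
}

zeros_like <- function(p) {
  if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
}

he_mat <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Create a convolution layer
#'
#' Stride-1 2-D convolution with zero padding chosen so the spatial
#' dimensions are preserved (`pad = dilation * (k - 1) / 2` by default) and
#' optional dilation. Weights are He-initialized from the current RNG state.
#'
#' @param cin,cout Input/output channel counts.
#' @param k Kernel size (odd).
#' @param dilation Dilation rate.
#' @param pad Zero padding; defaults to same-padding.
#' @return A `daunet_module`.
#' @export
new_conv <- function(cin, cout, k = 3L, dilation = 1L,
                     pad = dilation * (k - 1L) %/% 2L) {
  new_module("conv",
             .params = list(W = he_mat(k * k * cin, cout, k * k * cin),
                           b = numeric(cout)),
             cin = cin, cout = cout, k = as.integer(k),
             dilation = as.integer(dilation), pad = as.integer(pad))
}

new_convt2 <- function(cin, cout) {
  new_module("convt2",
             .params = list(W = he_mat(4L * cin, cout, 4L * cin),
                           b = numeric(cout)),
             cin = cin, cout = cout)
}

new_linear <- function(cin, cout) {
  new_module("linear", .params = list(W = he_mat(cout, cin, cin)),
             cin = cin, cout = cout)
}

new_relu <- function() new_module("relu")

new_maxpool2 <- function() new_module("maxpool2")

new_dropout <- function(rate) new_module("dropout", rate = rate)

new_groupnorm <- function(channels, groups, eps = 1e-5) {
  if (channels %% groups != 0L)
    abort_config("gn_groups",
                 sprintf("(%d) must divide the channel count %d", groups,
                         channels))
  new_module("gn", .params = list(gamma = rep(1, channels),
                                 beta = rep(0, channels)),
             channels = channels, groups = groups, eps = eps)
}

new_batchnorm <- function(channels, eps = 1e-5, momentum = 0.1) {
  m <- new_module("bn", .params = list(gamma = rep(1, channels),
                                      beta = rep(0, channels)),
                  channels = channels, eps = eps, momentum = momentum)
  m$running_mean <- rep(0, channels)
  m$running_var <- rep(1, channels)
  m
}

# channel-attention half of CBAM; r is the MLP bottleneck reduction ratio
new_chanatt <- function(channels, r) {
  if (channels %% r != 0L)
    abort_config("cbam_reduction",
                 sprintf("(%d) must divide the channel count %d", r,
                         channels))
  hid <- channels %/% r
  new_module("chanatt",
             .params = list(W0 = he_mat(hid, channels, channels),
                           W1 = he_mat(channels, hid, hid)),
             channels = channels, r = r)
}

# spatial-attention half of CBAM: 7x7 conv over [mean, max] channel pools
new_spatatt <- function(k = 7L) {
  new_module("spatatt", .sub = list(conv = new_conv(2L, 1L, k = k)), k = k)
}

new_cbam <- function(channels, r) {
  new_module("cbam_seq", .sub = list(ca = new_chanatt(channels, r),
                                    sa = new_spatatt()))
}

# DenseNet-style block: n composite layers (BN -> ReLU -> 3x3 conv emitting
# `growth` channels -> dropout), each consuming the concatenation of the
# block input and all previous layer outputs, closed by a 1x1 transition
# convolution back to `cout` channels.
new_dense_block <- function(cin, n_layers, growth, dropout_rate,
                            cout = cin) {
  layers <- lapply(seq_len(n_layers) - 1L, function(l) {
    cin_l <- cin + l * growth
    list(bn = new_batchnorm(cin_l), relu = new_relu(),
         conv = new_conv(cin_l, growth, k = 3L),
         drop = new_dropout(dropout_rate))
  })
  sub <- list(transition = new_conv(cin + n_layers * growth, cout, k = 1L))
  for (i in seq_along(layers)) sub[[paste0("layer", i)]] <- layers[[i]]
  new_module("dense", .sub = sub, cin = cin, n_layers = n_layers,
             growth = growth, cout = cout)
}

# GN-ASPP head: four parallel branches (1x1 conv + three dilated 3x3 convs,
# padding == dilation), each followed by group normalization; branch outputs
# concatenated then 1x1-projected back to `cout` channels.
new_gn_aspp <- function(cin, rates = c(6L, 12L, 18L), gn_groups = 8L,
                        cout = cin) {
  branches <- c(list(list(conv = new_conv(cin, cin, k = 1L),
                          gn = new_groupnorm(cin, gn_groups))),
                lapply(rates, function(r) {
                  list(conv = new_conv(cin, cin, k = 3L, dilation = r),
                       gn = new_groupnorm(cin, gn_groups))
                }))
  sub <- list(project = new_conv(cin * (length(rates) + 1L), cout, k = 1L))
  for (i in seq_along(branches)) sub[[paste0("branch", i)]] <- branches[[i]]
  new_module("aspp", .sub = sub, cin = cin, cout = cout,
             n_branches = length(branches))
}

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

cat_channels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  array(unlist(xs, use.names = FALSE),
        dim = c(d[1L], d[2L], sum(vapply(xs, function(x) dim(x)[3L],
                                         integer(1)))))
}

scale_channels <- function(x, s) {
  d <- dim(x)
  array(matrix(x, d[1L] * d[2L], d[3L]) *
          rep(s, each = d[1L] * d[2L]), dim = d)
}

# ---------------------------------------------------------------------------
# forward / backward dispatch

#' Run a layer forward
#'
#' @param m A `daunet_module`.
#' @param x Input array `(H, W, C)` (a matrix is treated as one channel).
#' @param train Training mode (enables dropout and batch statistics).
#' @return Output array.
#' @export
module_forward <- function(m, x, train = FALSE) {
  x <- as_cube(x)
  switch(m$kind,
    conv = {
      m$cache <- list(x = x)
      cpp_conv2d_fwd(x, m$params$W, m$params$b, m$k, m$pad, m$dilation)
    },
    convt2 = {
      m$cache <- list(x = x)
      cpp_convt2_fwd(x, m$params$W, m$params$b)
    },
    relu = {
      m$cache <- list(pos = x > 0)
      x * (x > 0)
    },
    maxpool2 = {
      r <- cpp_maxpool2_fwd(x)
      m$cache <- list(idx = r$idx)
      r$y
    },
    dropout = {
      if (train && m$rate > 0) {
        keep <- array(runif(length(x)) >= m$rate, dim = dim(x))
        m$cache <- list(keep = keep)
        x * keep / (1 - m$rate)
      } else {
        m$cache <- list(keep = NULL)
        x
      }
    },
    gn = gn_forward(m, x),
    bn = bn_forward(m, x, train),
    chanatt = {
      r <- ca_forward(x, m$params$W0, m$params$W1)
      m$cache <- r
      scale_channels(x, r$weights)
    },
    spatatt = {
      r <- sa_forward(x, m$sub$conv, train)
      m$cache <- r
      x * as.vector(r$weights)   # (H,W) map recycled over channels
    },
    cbam_seq = {
      h <- module_forward(m$sub$ca, x, train)
      module_forward(m$sub$sa, h, train)
    },
    dense = dense_forward(m, x, train),
    aspp = aspp_forward(m, x, train),
    linear = stop("linear layers are driven by the attention modules"),
    stop("unknown module kind: ", m$kind)
  )
}

#' Back-propagate through a layer
#'
#' Accumulates parameter gradients into the module and returns the gradient
#' with respect to the layer input of the most recent [module_forward()].
#'
#' @param m A `daunet_module`.
#' @param dy Gradient of the loss w.r.t. the layer output.
#' @return Gradient w.r.t. the layer input.
#' @export
module_backward <- function(m, dy) {
  dy <- as_cube(dy)
  switch(m$kind,
    conv = {
      r <- cpp_conv2d_bwd(m$cache$x, m$params$W, dy, m$k, m$pad, m$dilation)
      m$grads$W <- m$grads$W + r$dw
      m$grads$b <- m$grads$b + as.vector(r$db)
      r$dx
    },
    convt2 = {
      r <- cpp_convt2_bwd(m$cache$x, m$params$W, dy)
      m$grads$W <- m$grads$W + r$dw
      m$grads$b <- m$grads$b + as.vector(r$db)
      r$dx
    },
    relu = dy * m$cache$pos,
    maxpool2 = cpp_maxpool2_bwd(dy, m$cache$idx),
    dropout = if (is.null(m$cache$keep)) dy else
      dy * m$cache$keep / (1 - m$rate),
    gn = gn_backward(m, dy),
    bn = bn_backward(m, dy),
    chanatt = ca_backward(m, dy),
    spatatt = sa_backward(m, dy),
    cbam_seq = module_backward(m$sub$ca, module_backward(m$sub$sa, dy)),
    dense = dense_backward(m, dy),
    aspp = aspp_backward(m, dy),
    stop("unknown module kind: ", m$kind)
  )
}

seq_forward <- function(mods, x, train = FALSE) {
  for (m in mods) x <- module_forward(m, x, train)
  x
}

seq_backward <- function(mods, dy) {
  for (m in rev(mods)) dy <- module_backward(m, dy)
  dy
}

# ---------------------------------------------------------------------------
# normalization layers

gn_forward <- function(m, x) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  g <- m$groups
  cg <- m$channels %/% g
  xm <- matrix(x, hw, d[3L])
  grp <- rep(seq_len(g), each = cg)
  mu <- vapply(seq_len(g), function(k) mean(xm[, grp == k]), numeric(1))
  va <- vapply(seq_len(g), function(k) {
    v <- xm[, grp == k]; mean((v - mu[k])^2)
  }, numeric(1))
  inv <- 1 / sqrt(va + m$eps)
  xhat <- (xm - rep(mu[grp], each = hw)) * rep(inv[grp], each = hw)
  y <- xhat * rep(m$params$gamma, each = hw) +
    rep(m$params$beta, each = hw)
  m$cache <- list(xhat = xhat, inv = inv, grp = grp, hw = hw, d = d)
  array(y, dim = d)
}

gn_backward <- function(m, dy) {
  cc <- m$cache
  hw <- cc$hw
  dym <- matrix(dy, hw, cc$d[3L])
  m$grads$gamma <- m$grads$gamma + colSums(dym * cc$xhat)
  m$grads$beta <- m$grads$beta + colSums(dym)
  dxhat <- dym * rep(m$params$gamma, each = hw)
  g <- m$groups
  dxm <- matrix(0, hw, cc$d[3L])
  for (k in seq_len(g)) {
    cols <- cc$grp == k
    n <- hw * sum(cols)
    dxh <- dxhat[, cols]
    xh <- cc$xhat[, cols]
    dxm[, cols] <- cc$inv[k] *
      (dxh - mean(dxh) - xh * sum(dxh * xh) / n)
  }
  array(dxm, dim = cc$d)
}

# Batch normalization over the spatial extent of the current forward call;
# running statistics are tracked for eval mode.
bn_forward <- function(m, x, train) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  xm <- matrix(x, hw, d[3L])
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2L, mu)^2)
    m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * mu
    m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * va
  } else {
    mu <- m$running_mean
    va <- m$running_var
  }
  inv <- 1 / sqrt(va + m$eps)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, m$params$gamma, "*"), 2L, m$params$beta, "+")
  m$cache <- list(xhat = xhat, inv = inv, hw = hw, d = d, train = train)
  array(y, dim = d)
}

bn_backward <- function(m, dy) {
  cc <- m$cache
  hw <- cc$hw
  dym <- matrix(dy, hw, cc$d[3L])
  m$grads$gamma <- m$grads$gamma + colSums(dym * cc$xhat)
  m$grads$beta <- m$grads$beta + colSums(dym)
  dxhat <- sweep(dym, 2L, m$params$gamma, "*")
  if (cc$train) {
    n <- hw
    dxm <- sweep(dxhat -
                   matrix(colMeans(dxhat), hw, ncol(dxhat), byrow = TRUE) -
                   cc$xhat * matrix(colSums(dxhat * cc$xhat) / n, hw,
                                    ncol(dxhat), byrow = TRUE),
                 2L, cc$inv, "*")
  } else {
    dxm <- sweep(dxhat, 2L, cc$inv, "*")
  }
  array(dxm, dim = cc$d)
}

# ---------------------------------------------------------------------------
# attention internals

# Channel attention: sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F))) with the
# two-layer perceptron W1 %*% relu(W0 %*% x) shared between both branches.
ca_forward <- function(x, W0, W1) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  xm <- matrix(x, hw, d[3L])
  avg <- colMeans(xm)
  arg <- vapply(seq_len(d[3L]), function(c) which.max(xm[, c]), integer(1))
  mx <- xm[cbind(arg, seq_len(d[3L]))]
  z0a <- as.vector(W0 %*% avg); ha <- pmax(z0a, 0)
  z0m <- as.vector(W0 %*% mx);  hm <- pmax(z0m, 0)
  pre <- as.vector(W1 %*% ha) + as.vector(W1 %*% hm)
  list(weights = sigmoid(pre), avg = avg, max = mx, arg = arg,
       z0a = z0a, ha = ha, z0m = z0m, hm = hm, x = x, d = d, hw = hw)
}

ca_backward <- function(m, dy) {
  cc <- m$cache
  hw <- cc$hw
  d <- cc$d
  dym <- matrix(dy, hw, d[3L])
  xm <- matrix(cc$x, hw, d[3L])
  s <- cc$weights
  dMc <- colSums(dym * xm)
  dxm <- dym * rep(s, each = hw)
  dpre <- dMc * s * (1 - s)
  W0 <- m$params$W0; W1 <- m$params$W1
  dha <- as.vector(t(W1) %*% dpre)
  dhm <- dha                       # shared W1, same upstream gradient
  dz0a <- dha * (cc$z0a > 0)
  dz0m <- dhm * (cc$z0m > 0)
  m$grads$W1 <- m$grads$W1 + outer(dpre, cc$ha) + outer(dpre, cc$hm)
  m$grads$W0 <- m$grads$W0 + outer(dz0a, cc$avg) + outer(dz0m, cc$max)
  davg <- as.vector(t(W0) %*% dz0a)
  dmax <- as.vector(t(W0) %*% dz0m)
  dxm <- dxm + matrix(davg / hw, hw, d[3L], byrow = TRUE)
  dxm[cbind(cc$arg, seq_len(d[3L]))] <-
    dxm[cbind(cc$arg, seq_len(d[3L]))] + dmax
  array(dxm, dim = d)
}

# Spatial attention: 7x7 convolution (then sigmoid) over the 2-channel field
# of channel-wise mean and max maps.
sa_forward <- function(x, conv, train) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  xm <- matrix(x, hw, d[3L])
  mu <- rowMeans(xm)
  arg <- max.col(xm, ties.method = "first")
  mx <- xm[cbind(seq_len(hw), arg)]
  pooled <- array(c(mu, mx), dim = c(d[1L], d[2L], 2L))
  z <- module_forward(conv, pooled, train)
  w <- sigmoid(z[, , 1L])
  list(weights = w, arg = arg, x = x, d = d, hw = hw)
}

sa_backward <- function(m, dy) {
  cc <- m$cache
  d <- cc$d
  hw <- cc$hw
  dym <- matrix(dy, hw, d[3L])
  xm <- matrix(cc$x, hw, d[3L])
  w <- as.vector(cc$weights)
  dW <- rowSums(dym * xm)
  dxm <- dym * w
  dz <- dW * w * (1 - w)
  dpooled <- module_backward(m$sub$conv,
                             array(dz, dim = c(d[1L], d[2L], 1L)))
  dmu <- as.vector(dpooled[, , 1L])
  dmx <- as.vector(dpooled[, , 2L])
  dxm <- dxm + dmu / d[3L]
  idx <- cbind(seq_len(hw), cc$arg)
  dxm[idx] <- dxm[idx] + dmx
  array(dxm, dim = d)
}

# ---------------------------------------------------------------------------
# composite blocks

dense_forward <- function(m, x, train) {
  feats <- list(x)
  for (i in seq_len(m$n_layers)) {
    ly <- m$sub[[paste0("layer", i)]]
    inp <- do.call(cat_channels, feats)
    h <- module_forward(ly$bn, inp, train)
    h <- module_forward(ly$relu, h, train)
    h <- module_forward(ly$conv, h, train)
    h <- module_forward(ly$drop, h, train)
    feats[[i + 1L]] <- h
  }
  concat <- do.call(cat_channels, feats)
  m$cache <- list(widths = vapply(feats, function(f) dim(f)[3L],
                                  integer(1)))
  module_forward(m$sub$transition, concat, train)
}

dense_backward <- function(m, dy) {
  widths <- m$cache$widths
  dcat <- module_backward(m$sub$transition, dy)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  dfeats <- lapply(seq_along(widths), function(i) {
    dcat[, , starts[i]:ends[i], drop = FALSE]
  })
  for (i in rev(seq_len(m$n_layers))) {
    ly <- m$sub[[paste0("layer", i)]]
    dh <- module_backward(ly$drop, dfeats[[i + 1L]])
    dh <- module_backward(ly$conv, dh)
    dh <- module_backward(ly$relu, dh)
    dinp <- module_backward(ly$bn, dh)
    for (j in seq_len(i)) {
      dfeats[[j]] <- dfeats[[j]] +
        dinp[, , starts[j]:ends[j], drop = FALSE]
    }
  }
  dfeats[[1L]]
}

aspp_forward <- function(m, x, train) {
  outs <- lapply(seq_len(m$n_branches), function(i) {
    br <- m$sub[[paste0("branch", i)]]
    module_forward(br$gn, module_forward(br$conv, x, train), train)
  })
  module_forward(m$sub$project, do.call(cat_channels, outs), train)
}

aspp_backward <- function(m, dy) {
  dcat <- module_backward(m$sub$project, dy)
  cin <- m$cin
  dx <- NULL
  for (i in seq_len(m$n_branches)) {
    br <- m$sub[[paste0("branch", i)]]
    sl <- dcat[, , ((i - 1L) * cin + 1L):(i * cin), drop = FALSE]
    dxi <- module_backward(br$conv, module_backward(br$gn, sl))
    dx <- if (is.null(dx)) dxi else dx + dxi
  }
  dx
}

# ---------------------------------------------------------------------------
# parameter plumbing

leaf_modules <- function(x) {
  if (inherits(x, "daunet_module")) {
    subs <- unlist(lapply(x$sub, leaf_modules), recursive = FALSE)
    if (length(x$params) > 0L) c(list(x), subs) else subs
  } else if (is.list(x)) {
    unlist(lapply(x, leaf_modules), recursive = FALSE)
  } else {
    list()
  }
}

zero_grads <- function(mods) {
  for (m in mods) m$grads <- lapply(m$params, zeros_like)
  invisible(NULL)
}

n_params <- function(mods) {
  sum(vapply(mods, function(m) sum(vapply(m$params, length, integer(1))),
             integer(1)))
}

get_param_state <- function(mods) {
  lapply(mods, function(m) m$params)
}

set_param_state <- function(mods, state) {
  stopifnot(length(mods) == length(state))
  for (i in seq_along(mods)) {
    stopifnot(identical(lapply(mods[[i]]$params, dim),
                        lapply(state[[i]], dim)))
    mods[[i]]$params <- state[[i]]
  }
  invisible(NULL)
}

# One Adam step over all leaf modules; optimizer moments live in the modules.
adam_step <- function(mods, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (m in mods) {
    if (is.null(m$opt))
      m$opt <- lapply(m$params, function(p) {
        list(m = zeros_like(p), v = zeros_like(p))
      })
    for (nm in names(m$params)) {
      g <- m$grads[[nm]]
      st <- m$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      m$opt[[nm]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      m$params[[nm]] <- m$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}
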