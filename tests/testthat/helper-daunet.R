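# Shared fixtures: everything is generated in code at test time.

tiny_phantom_config <- function(seed = 1L, image_size = 32L,
                                lesion_probability = 0.5, noise_sd = 0.05) {
  phantom_config(image_size = image_size,
                 lesion_probability = lesion_probability,
                 noise_sd = noise_sd, seed = seed)
}

tiny_net_config <- function(seed = 1L, ...) {
  network_config(base_channels = 4L, depth = 2L, cbam_reduction = 2L,
                 gn_groups = 2L, dense_layers = 2L, dropout_rate = 0,
                 seed = seed, ...)
}

tiny_train_config <- function(epochs = 2L, seed = 1L,
                              learning_rate = 1e-3, ...) {
  train_config(epochs = epochs, learning_rate = learning_rate,
               batch_size = 2L,
               early_stop_patience = min(epochs, 15L),
               checkpoint_dir = withr::local_tempdir(.local_envir =
                                                       parent.frame()),
               seed = seed, ...)
}

# direct (nested-loop) 2-D convolution oracle, zero-padded, dilated
conv2d_oracle <- function(x, w_arr, b, pad, dil) {
  k <- dim(w_arr)[1L]
  cin <- dim(w_arr)[3L]
  cout <- dim(w_arr)[4L]
  H <- dim(x)[1L]; W <- dim(x)[2L]
  y <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(H)) for (j in seq_len(W)) {
      acc <- b[co]
      for (ci in seq_len(cin)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
        si <- i + dil * (ki - 1L) - pad
        sj <- j + dil * (kj - 1L) - pad
        if (si >= 1L && si <= H && sj >= 1L && sj <= W)
          acc <- acc + x[si, sj, ci] * w_arr[ki, kj, ci, co]
      }
      y[i, j, co] <- acc
    }
  }
  y
}

# finite-difference gradient check of a module against module_backward
expect_gradients_match <- function(mod, x, tol = 1e-4, n_checks = 12L,
                                   seed = 1L) {
  loss_weights <- NULL
  loss_of <- function() {
    y <- module_forward(mod, x, train = FALSE)
    if (is.null(loss_weights))
      loss_weights <<- array(rnorm(length(y)), dim = dim(y))
    sum(y * loss_weights)
  }
  withr::with_seed(seed, {
    base <- loss_of()
    daunet:::zero_grads(daunet:::leaf_modules(mod))
    y <- module_forward(mod, x, train = FALSE)
    module_backward(mod, loss_weights)
    leaves <- daunet:::leaf_modules(mod)
    eps <- 1e-6
    for (ch in seq_len(n_checks)) {
      m <- leaves[[sample(length(leaves), 1L)]]
      pn <- sample(names(m$params), 1L)
      pi <- sample(length(m$params[[pn]]), 1L)
      orig <- m$params[[pn]][pi]
      m$params[[pn]][pi] <- orig + eps; lp <- loss_of()
      m$params[[pn]][pi] <- orig - eps; lm <- loss_of()
      m$params[[pn]][pi] <- orig
      g_num <- (lp - lm) / (2 * eps)
      g_an <- m$grads[[pn]][pi]
      expect_lt(abs(g_an - g_num) / max(1e-6, abs(g_an) + abs(g_num)), tol)
    }
  })
}

# independent HD oracle: boundary = mask pixel with a 4-neighbour (or grid
# edge) outside the mask; distances by exhaustive all-pairs scan
hd_oracle <- function(pred, gt, percentile = 95, spacing = 1) {
  pred <- pred > 0
  gt <- gt > 0
  bnd <- function(b) {
    pts <- which(b, arr.ind = TRUE)
    keep <- apply(pts, 1L, function(p) {
      i <- p[1L]; j <- p[2L]
      nb <- rbind(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
      any(apply(nb, 1L, function(q) {
        q[1L] < 1L || q[1L] > nrow(b) || q[2L] < 1L || q[2L] > ncol(b) ||
          !b[q[1L], q[2L]]
      }))
    })
    pts[keep, , drop = FALSE]
  }
  bp <- bnd(pred); bg <- bnd(gt)
  one_way <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      min(sqrt((a[i, 1L] - b[, 1L])^2 + (a[i, 2L] - b[, 2L])^2))
    }, numeric(1))
  }
  quantile(c(one_way(bp, bg), one_way(bg, bp)), percentile / 100,
           names = FALSE) * spacing
}

random_mask <- function(h, w, n_fg) {
  m <- matrix(0L, h, w)
  m[sample(h * w, n_fg)] <- 1L
  m
}
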