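#' @useDynLib daunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile sd setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

abort_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    abort_config(field, "must be TRUE or FALSE")
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < min)
    abort_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_number <- function(x, field, min = -Inf, max = Inf,
                         open_min = FALSE, open_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_config(field, "must be a single finite number")
  lo_ok <- if (open_min) x > min else x >= min
  hi_ok <- if (open_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    abort_config(field, sprintf("must lie in %s%g, %g%s",
                                if (open_min) "(" else "[", min, max,
                                if (open_max) ")" else "]"))
  as.numeric(x)
}

# Deterministic argmax over the 3rd dimension of an (H, W, K) array;
# ties resolve to the lowest class index. Returns labels 0..K-1.
argmax_classes <- function(logits) {
  stopifnot(length(dim(logits)) == 3L)
  k <- dim(logits)[3L]
  lab <- matrix(0L, dim(logits)[1L], dim(logits)[2L])
  best <- logits[, , 1L]
  if (k > 1L) for (c in 2L:k) {
    sl <- logits[, , c]
    take <- sl > best
    lab[take] <- c - 1L
    best[take] <- sl[take]
  }
  lab
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. With seed = NULL the current stream is
# used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
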