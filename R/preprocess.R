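#' Min-max intensity normalization
#'
#' Rescales an image linearly to `[0, 1]` using its own extrema:
#' `Xnorm = (X - Xmin) / (Xmax - Xmin)`. Normalization is per-image, not
#' dataset-global, so every slice reaches the full dynamic range regardless
#' of scanner scaling. A constant image (max == min) maps to all zeros rather
#' than erroring, so blank padding slices pass through batch pipelines.
#'
#' @param image Numeric matrix with finite entries.
#' @return Numeric matrix with range `[0, 1]` (all zeros if constant).
#' @export
minmax_normalize <- function(image) {
  if (!is.numeric(image)) stop("image must be numeric", call. = FALSE)
  if (any(!is.finite(image)))
    stop("image contains NaN or infinite values", call. = FALSE)
  lo <- min(image)
  hi <- max(image)
  if (hi == lo) return(array(0, dim = dim(image)))
  (image - lo) / (hi - lo)
}

#' Augmentation configuration
#'
#' Each transform in the configuration is applied independently to the
#' original sample, giving `length(rotation_degrees) + 4 * (shifts) +
#' length(scale_factors)` outputs per input (10 with the defaults; the 0
#' degree rotation is the identity copy). Images are resampled bilinearly,
#' masks by nearest neighbour so the label alphabet is preserved;
#' out-of-canvas regions are filled with background (0).
#'
#' @param rotation_degrees Rotation angles in degrees.
#' @param shift_fraction Shift magnitude as a fraction of the image side,
#'   applied once in each of the four axis directions.
#' @param scale_factors Rescale factors; outputs are resampled back onto the
#'   original canvas (centre crop above 1, background pad below 1) so all
#'   samples share one shape.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_degrees = c(-10, 0, 45, 60),
                                shift_fraction = 0.1,
                                scale_factors = c(0.9, 1.1)) {
  if (length(rotation_degrees) < 1L || !is.numeric(rotation_degrees))
    abort_config("rotation_degrees", "must be a non-empty numeric vector")
  shift_fraction <- check_number(shift_fraction, "shift_fraction", 0, 1,
                                 open_min = TRUE, open_max = TRUE)
  if (length(scale_factors) < 1L || !is.numeric(scale_factors) ||
      any(scale_factors <= 0))
    abort_config("scale_factors", "must be a non-empty positive numeric")
  structure(list(rotation_degrees = as.numeric(rotation_degrees),
                 shift_fraction = shift_fraction,
                 scale_factors = as.numeric(scale_factors)),
            class = "augmentation_config")
}

clamp_mask <- function(m) {
  m <- round(m)
  m[m < 0] <- 0
  m[m > 2] <- 2
  storage.mode(m) <- "integer"
  m
}

rotate_pair <- function(sample, angle) {
  if (angle == 0) {
    out <- sample
  } else {
    h <- nrow(sample$image); w <- ncol(sample$image)
    img <- EBImage::rotate(sample$image, angle, filter = "bilinear",
                           output.dim = c(h, w), bg.col = 0)
    msk <- EBImage::rotate(sample$mask, angle, filter = "none",
                           output.dim = c(h, w), bg.col = 0)
    out <- image_sample(as.matrix(img), clamp_mask(as.matrix(msk)),
                        paste0(sample$sample_id, sprintf("_rot%+d",
                                                         round(angle))))
  }
  attr(out, "transform") <- sprintf("rotate:%g", angle)
  out
}

shift_pair <- function(sample, v, name) {
  img <- EBImage::translate(sample$image, v, bg.col = 0)
  msk <- EBImage::translate(sample$mask, v, filter = "none", bg.col = 0)
  out <- image_sample(as.matrix(img), clamp_mask(as.matrix(msk)),
                      paste0(sample$sample_id, "_shift-", name))
  attr(out, "transform") <- sprintf("shift:%s", name)
  out
}

scale_pair <- function(sample, f) {
  h <- nrow(sample$image); w <- ncol(sample$image)
  nh <- max(1L, round(h * f)); nw <- max(1L, round(w * f))
  img <- as.matrix(EBImage::resize(sample$image, w = nh, h = nw))
  msk <- as.matrix(EBImage::resize(sample$mask, w = nh, h = nw,
                                   filter = "none"))
  fit <- function(x, fill) {
    out <- matrix(fill, h, w)
    if (nh >= h) {           # centre crop
      oi <- (nh - h) %/% 2; oj <- (nw - w) %/% 2
      out[, ] <- x[oi + seq_len(h), oj + seq_len(w)]
    } else {                 # centre pad with background
      oi <- (h - nh) %/% 2; oj <- (w - nw) %/% 2
      out[oi + seq_len(nh), oj + seq_len(nw)] <- x
    }
    out
  }
  out <- image_sample(fit(img, 0), clamp_mask(fit(msk, 0)),
                      paste0(sample$sample_id, sprintf("_scale%g", f)))
  attr(out, "transform") <- sprintf("scale:%g", f)
  out
}

#' Augment one sample
#'
#' @param sample An [image_sample()].
#' @param config An [augmentation_config()].
#' @return List of augmented [image_sample()] objects, one per configured
#'   transform (default 4 rotations + 4 shifts + 2 rescales = 10).
#' @export
augment_sample <- function(sample, config = augmentation_config()) {
  stopifnot(inherits(sample, "image_sample"),
            inherits(config, "augmentation_config"))
  d <- round(config$shift_fraction * nrow(sample$image))
  shifts <- list(up = c(-d, 0), down = c(d, 0), left = c(0, -d),
                 right = c(0, d))
  c(lapply(config$rotation_degrees, function(a) rotate_pair(sample, a)),
    mapply(function(v, nm) shift_pair(sample, v, nm), shifts, names(shifts),
           SIMPLIFY = FALSE, USE.NAMES = FALSE),
    lapply(config$scale_factors, function(f) scale_pair(sample, f)))
}

#' Augment a dataset
#'
#' @param samples List of [image_sample()] objects.
#' @param config An [augmentation_config()].
#' @param keep_original Prepend each original sample to its augmentations.
#' @return Flat list of samples.
#' @export
augment_dataset <- function(samples, config = augmentation_config(),
                            keep_original = FALSE) {
  out <- lapply(samples, function(s) {
    aug <- augment_sample(s, config)
    if (keep_original) c(list(s), aug) else aug
  })
  unlist(out, recursive = FALSE)
}

#' Dataset split specification
#'
#' @param train_fraction Fraction assigned to training (default 0.7, i.e. a
#'   70/30 train/test split).
#' @param n_folds Number of cross-validation folds (default 4).
#' @param seed Seed driving the shuffling.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7, n_folds = 4L, seed = 1L) {
  train_fraction <- check_number(train_fraction, "train_fraction", 0, 1,
                                 open_min = TRUE, open_max = TRUE)
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(train_fraction = train_fraction, n_folds = n_folds,
                 seed = seed), class = "split_spec")
}

# Largest-remainder apportionment of `total` across strata of sizes `sizes`.
apportion <- function(sizes, fraction, total) {
  ideal <- sizes * fraction
  base <- floor(ideal)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(ideal - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(ideal - base)
    take <- ord[base[ord] > 0][seq_len(-rem)]
    base[take] <- base[take] - 1L
  }
  as.integer(base)
}

#' Train/test split, stratified by lesion presence
#'
#' Assigns `round(train_fraction * n)` samples to training. Stratification by
#' the `has_lesion` flag keeps the lesion prevalence of both partitions close
#' to the dataset's, which matters when lesion-bearing samples are the
#' minority; per-stratum counts are apportioned by largest remainder so the
#' total is exact.
#'
#' @param dataset List of [image_sample()] objects (length >= 2).
#' @param spec A [split_spec()].
#' @return List with elements `train` and `test`.
#' @export
train_test_split <- function(dataset, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(dataset)
  if (n < 2L) stop("dataset must contain at least 2 samples", call. = FALSE)
  lesion <- vapply(dataset, has_lesion, logical(1))
  n_train <- round(spec$train_fraction * n)
  strata <- split(seq_len(n), lesion)
  counts <- apportion(lengths(strata), spec$train_fraction, n_train)
  with_seed(spec$seed, {
    train_idx <- unlist(mapply(function(idx, k) {
      idx[sample.int(length(idx), length(idx))][seq_len(k)]
    }, strata, counts, SIMPLIFY = FALSE), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = dataset[train_idx], test = dataset[setdiff(seq_len(n),
                                                          train_idx)])
}

#' K-fold cross-validation folds
#'
#' Shuffles the training set once (seeded) and partitions it into `n_folds`
#' near-equal folds. Each round uses one fold for validation and the rest for
#' training; every sample is in the validation fold of exactly one round.
#'
#' @param train_set List of samples (length >= `n_folds`).
#' @param spec A [split_spec()].
#' @return List of `n_folds` lists, each with integer vectors `train` and
#'   `validation` indexing into `train_set`.
#' @export
make_folds <- function(train_set, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(train_set)
  if (n < spec$n_folds)
    stop(sprintf("need at least n_folds = %d samples, got %d", spec$n_folds,
                 n), call. = FALSE)
  perm <- with_seed(spec$seed + 1L, sample.int(n))
  fold_of <- rep(seq_len(spec$n_folds), length.out = n)[order(perm)]
  lapply(seq_len(spec$n_folds), function(k) {
    list(train = which(fold_of != k), validation = which(fold_of == k))
  })
}
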