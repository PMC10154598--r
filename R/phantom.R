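#' Configuration for the synthetic DWI phantom generator
#'
#' Describes the geometry, contrast and noise of synthetic single-slice
#' "DWI-like" phantoms: a bright elliptical gland on a darker background,
#' optionally carrying a hyperintense lesion disk strictly inside the gland.
#' The default contrast ordering (lesion > gland > background) mimics the
#' appearance of high-b-value diffusion-weighted images, where restricted
#' diffusion renders tumours hyperintense.
#'
#' @param image_size Side length of the square image, in pixels.
#' @param gland_axis_range Length-2 numeric, (min, max) gland semi-axis as a
#'   fraction of `image_size`; both must lie in (0, 0.5).
#' @param lesion_probability Probability that a sample carries a lesion. The
#'   default 58/180 reproduces a cohort mixing healthy and lesion-bearing
#'   subjects at roughly 122:58.
#' @param lesion_radius_range Length-2 numeric, (min, max) lesion radius as a
#'   fraction of the gland's minor semi-axis.
#' @param intensity_background,intensity_gland,intensity_lesion Intensity
#'   levels in `[0, 1]`; must satisfy background < gland < lesion.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units); the noisy image is clipped back to `[0, 1]`.
#' @param seed Integer seed making the generator a pure function of its
#'   configuration.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L,
                           gland_axis_range = c(0.15, 0.35),
                           lesion_probability = 58 / 180,
                           lesion_radius_range = c(0.2, 0.5),
                           intensity_background = 0.1,
                           intensity_gland = 0.55,
                           intensity_lesion = 0.9,
                           noise_sd = 0.05,
                           seed = 1L) {
  image_size <- check_count(image_size, "image_size", min = 8L)
  if (!is.numeric(gland_axis_range) || length(gland_axis_range) != 2L)
    abort_config("gland_axis_range", "must be a length-2 numeric")
  a <- gland_axis_range
  if (!(a[1] > 0 && a[1] <= a[2] && a[2] < 0.5))
    abort_config("gland_axis_range", "must satisfy 0 < min <= max < 0.5")
  lesion_probability <- check_number(lesion_probability,
                                     "lesion_probability", 0, 1)
  if (!is.numeric(lesion_radius_range) || length(lesion_radius_range) != 2L ||
      lesion_radius_range[1] <= 0 ||
      lesion_radius_range[1] > lesion_radius_range[2] ||
      lesion_radius_range[2] > 1)
    abort_config("lesion_radius_range",
                 "must satisfy 0 < min <= max <= 1 (fractions of minor axis)")
  intensity_background <- check_number(intensity_background,
                                       "intensity_background", 0, 1)
  intensity_gland <- check_number(intensity_gland, "intensity_gland", 0, 1)
  intensity_lesion <- check_number(intensity_lesion, "intensity_lesion", 0, 1)
  if (!(intensity_background < intensity_gland &&
        intensity_gland < intensity_lesion))
    abort_config("intensity_gland",
                 "levels must satisfy background < gland < lesion")
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(image_size = image_size,
                 gland_axis_range = as.numeric(gland_axis_range),
                 lesion_probability = lesion_probability,
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 intensity_background = intensity_background,
                 intensity_gland = intensity_gland,
                 intensity_lesion = intensity_lesion,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_config")
}

#' Construct an image/mask sample
#'
#' The unit of all pipeline I/O: one grayscale image, one integer label mask
#' (0 = background, 1 = gland, 2 = lesion) and an identifier.
#'
#' @param image Numeric matrix.
#' @param mask Integer matrix of the same dimensions with values in
#'   \{0, 1, 2\}.
#' @param sample_id Character scalar.
#' @return An object of class `image_sample`.
#' @export
image_sample <- function(image, mask, sample_id) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must have identical dimensions", call. = FALSE)
  if (!all(mask %in% c(0L, 1L, 2L)))
    stop("mask may contain only the labels 0, 1, 2", call. = FALSE)
  if (!is.character(sample_id) || length(sample_id) != 1L)
    stop("sample_id must be a single string", call. = FALSE)
  storage.mode(mask) <- "integer"
  structure(list(image = image, mask = mask, sample_id = sample_id),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf("<image_sample '%s' %dx%d, labels {%s}>\n", x$sample_id,
              nrow(x$image), ncol(x$image),
              paste(sort(unique(as.vector(x$mask))), collapse = ",")))
  invisible(x)
}

has_lesion <- function(sample) any(sample$mask == 2L)

#' Generate one synthetic DWI phantom
#'
#' Draws a rotated elliptical gland (uniform orientation in `[0, pi)`), with
#' probability `lesion_probability` places a lesion disk whose pixels all lie
#' inside the gland (rejection sampling of the centre, up to 1000 tries, then
#' the radius is shrunk and sampling retried), assigns the configured
#' intensity levels, and adds Gaussian noise to the image only. The mask is
#' noise-free by construction.
#'
#' @param config A [phantom_config()].
#' @param seed Seed for this draw; defaults to `config$seed`. Pass `NULL` to
#'   consume the caller's RNG stream instead (used by [generate_dataset()]).
#' @param sample_id Identifier for the sample.
#' @return An [image_sample()].
#' @export
generate_phantom <- function(config, seed = config$seed,
                             sample_id = "phantom_001") {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    n <- config$image_size
    # pixel-centre coordinates on the unit square scaled to pixels
    cx <- (n + 1) / 2 + runif(1, -0.05, 0.05) * n
    cy <- (n + 1) / 2 + runif(1, -0.05, 0.05) * n
    ax <- runif(1, config$gland_axis_range[1], config$gland_axis_range[2]) * n
    ay <- runif(1, config$gland_axis_range[1], config$gland_axis_range[2]) * n
    th <- runif(1, 0, pi)
    xs <- matrix(rep(seq_len(n), times = n), n, n)  # row coordinate
    ys <- matrix(rep(seq_len(n), each = n), n, n)   # column coordinate
    u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    gland <- (u / ax)^2 + (v / ay)^2 <= 1
    mask <- matrix(0L, n, n)
    mask[gland] <- 1L

    if (runif(1) < config$lesion_probability) {
      r <- runif(1, config$lesion_radius_range[1],
                 config$lesion_radius_range[2]) * min(ax, ay)
      gi <- which(gland, arr.ind = TRUE)
      repeat {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          ctr <- gi[sample.int(nrow(gi), 1L), ]
          disk <- (xs - ctr[1])^2 + (ys - ctr[2])^2 <= r^2
          if (all(gland[disk])) {
            mask[disk] <- 2L
            placed <- TRUE
            break
          }
        }
        if (placed) break
        r <- r * 0.8  # cap reached: shrink and retry
        if (r < 1) {  # degenerate gland; single-pixel lesion at the centre
          ctr <- gi[sample.int(nrow(gi), 1L), ]
          mask[ctr[1], ctr[2]] <- 2L
          break
        }
      }
    }

    img <- matrix(config$intensity_background, n, n)
    img[mask == 1L] <- config$intensity_gland
    img[mask == 2L] <- config$intensity_lesion
    if (config$noise_sd > 0)
      img <- img + matrix(rnorm(n * n, sd = config$noise_sd), n, n)
    img <- pmin(pmax(img, 0), 1)
    out <- image_sample(img, mask, sample_id)
    # pre-lesion gland support, kept for containment checks
    attr(out, "gland_region") <- gland
    out
  })
}

#' Generate a dataset of phantoms
#'
#' Draws `n` samples from a single RNG stream seeded with `config$seed`, so
#' the whole dataset is a pure function of (config, seed) and equals `n`
#' sequential [generate_phantom()] calls on that stream.
#'
#' @param config A [phantom_config()].
#' @param n Number of samples (>= 1).
#' @param id_prefix Prefix for the generated sample identifiers.
#' @return List of [image_sample()] objects with distinct `sample_id`s.
#' @export
generate_dataset <- function(config, n, id_prefix = "phantom") {
  stopifnot(inherits(config, "phantom_config"))
  n <- check_count(n, "n", min = 1L)
  with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      generate_phantom(config, seed = NULL,
                       sample_id = sprintf("%s_%03d", id_prefix, i))
    })
  })
}

#' Write / read one sample
#'
#' Two storage back-ends are supported. `"tiff"` stores the image as 16-bit
#' grayscale TIFF (values quantized to 1/65535) and the mask as 8-bit TIFF
#' with raw label values; `"nifti"` stores single-slice volumes, image as
#' float32 and mask as uint8. Either way the mask round-trips exactly and the
#' image to at worst 16-bit quantization.
#'
#' @param sample An [image_sample()].
#' @param dir Output directory (created if missing).
#' @param format `"tiff"` or `"nifti"`.
#' @return `write_sample` invisibly returns a named list with the image and
#'   mask paths; `read_sample` returns the reconstructed [image_sample()].
#' @export
write_sample <- function(sample, dir, format = c("tiff", "nifti")) {
  stopifnot(inherits(sample, "image_sample"))
  format <- match.arg(format)
  if (any(sample$image < 0) || any(sample$image > 1))
    stop("image intensities must lie in [0, 1] for storage", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "tiff") {
    ip <- file.path(dir, paste0(sample$sample_id, "_image.tif"))
    mp <- file.path(dir, paste0(sample$sample_id, "_mask.tif"))
    tiff::writeTIFF(sample$image, ip, bits.per.sample = 16L)
    tiff::writeTIFF(sample$mask / 255, mp, bits.per.sample = 8L)
  } else {
    ip <- file.path(dir, paste0(sample$sample_id, "_image.nii.gz"))
    mp <- file.path(dir, paste0(sample$sample_id, "_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(sample$image, datatype = "float"), ip)
    RNifti::writeNifti(RNifti::asNifti(sample$mask, datatype = "uint8"), mp)
  }
  invisible(list(image_path = ip, mask_path = mp))
}

#' @rdname write_sample
#' @param image_path,mask_path Paths written by `write_sample`.
#' @param sample_id Identifier to attach; defaults to the image file stem.
#' @export
read_sample <- function(image_path, mask_path,
                        sample_id = sub("_image\\..*$", "",
                                        basename(image_path))) {
  if (!file.exists(image_path) || !file.exists(mask_path))
    stop("sample files not found: ", image_path, " / ", mask_path,
         call. = FALSE)
  nifti <- grepl("\\.nii(\\.gz)?$", image_path)
  strip <- function(a) {
    a <- drop(as.array(a))
    matrix(as.numeric(a), nrow(a), ncol(a))
  }
  if (nifti) {
    img <- strip(RNifti::readNifti(image_path))
    msk <- strip(RNifti::readNifti(mask_path))
  } else {
    img <- tiff::readTIFF(image_path)
    msk <- round(tiff::readTIFF(mask_path) * 255)
  }
  msk <- round(msk)
  storage.mode(msk) <- "integer"
  image_sample(img, msk, sample_id)
}

#' Write / read a dataset with a CSV manifest
#'
#' The manifest has columns `sample_id`, `image_path`, `mask_path`,
#' `has_lesion` (and, for augmented datasets, `transform`). Paths are stored
#' relative to the manifest's directory.
#'
#' @param samples List of [image_sample()] objects.
#' @param dir Output directory.
#' @param format Storage back-end, see [write_sample()].
#' @return `write_dataset` invisibly returns the manifest path;
#'   `read_dataset` returns the list of samples.
#' @export
write_dataset <- function(samples, dir, format = c("tiff", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    p <- write_sample(s, dir, format)
    data.frame(sample_id = s$sample_id,
               image_path = basename(p$image_path),
               mask_path = basename(p$mask_path),
               has_lesion = has_lesion(s),
               transform = attr(s, "transform") %||% "none",
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' @rdname write_dataset
#' @param manifest_path Path to a `manifest.csv` written by `write_dataset`.
#' @export
read_dataset <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    read_sample(file.path(base, man$image_path[i]),
                file.path(base, man$mask_path[i]),
                sample_id = man$sample_id[i])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
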