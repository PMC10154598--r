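#' Pixel-wise confusion counts for one class
#'
#' @param pred,gt Integer label matrices of identical dimensions.
#' @param label The class evaluated one-vs-rest.
#' @return A list of class `confusion_counts` with fields `tp`, `fp`, `fn`,
#'   `tn` summing to the total pixel count.
#' @export
confusion <- function(pred, gt, label = 1L) {
  if (!identical(dim(pred), dim(gt)))
    stop("pred and gt must have identical dimensions", call. = FALSE)
  p <- pred == label
  g <- gt == label
  structure(list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g),
                 tn = sum(!p & !g)), class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' `dice = 2tp / (2tp + fp + fn)`, `iou = tp / (tp + fp + fn)`,
#' `accuracy = (tp + tn) / total`, `sensitivity = tp / (tp + fn)`.
#' Degenerate conventions: if both masks are empty for the class
#' (`tp + fp + fn == 0`) Dice, IoU and sensitivity are 1 (a lesion-free
#' phantom predicted lesion-free is a perfect answer); if the ground truth is
#' empty but the prediction is not, Dice and IoU are 0; sensitivity with an
#' empty ground truth (`tp + fn == 0`) is 1, since no positive was missed.
#'
#' @param c A `confusion_counts` object.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(c) {
  if (2 * c$tp + c$fp + c$fn == 0) return(1)
  2 * c$tp / (2 * c$tp + c$fp + c$fn)
}

#' @rdname dice
#' @export
iou <- function(c) {
  if (c$tp + c$fp + c$fn == 0) return(1)
  c$tp / (c$tp + c$fp + c$fn)
}

#' @rdname dice
#' @export
accuracy <- function(c) (c$tp + c$tn) / (c$tp + c$fp + c$fn + c$tn)

#' @rdname dice
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0) return(1)
  c$tp / (c$tp + c$fn)
}

#' Surface-distance specification
#'
#' @param pixel_spacing In-plane pixel size in millimetres (default 1 mm).
#' @param percentile Percentile of the pooled symmetric surface-distance set
#'   (default 95, the robust Hausdorff convention).
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(pixel_spacing = 1.0, percentile = 95) {
  pixel_spacing <- check_number(pixel_spacing, "pixel_spacing", min = 0,
                                open_min = TRUE)
  percentile <- check_number(percentile, "percentile", 0, 100,
                             open_min = TRUE)
  structure(list(pixel_spacing = pixel_spacing, percentile = percentile),
            class = "surface_spec")
}

# Boundary pixels of a binary mask: the mask minus its erosion under
# 4-connectivity (3x3 diamond brush). Isolated pixels erode away entirely and
# are therefore their own boundary.
boundary_points <- function(bin) {
  if (!any(bin)) return(matrix(numeric(0), 0, 2))
  # zero-pad so the image border counts as background before eroding
  padded <- matrix(0, nrow(bin) + 2L, ncol(bin) + 2L)
  padded[2:(nrow(bin) + 1L), 2:(ncol(bin) + 1L)] <- bin
  er <- EBImage::erode(padded, EBImage::makeBrush(3L, "diamond")) > 0.5
  er <- er[2:(nrow(bin) + 1L), 2:(ncol(bin) + 1L)]
  which(bin & !er, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance
#'
#' Extracts the boundary of each mask (erosion difference, 4-connectivity),
#' collects the directed nearest-neighbour Euclidean distances in both
#' directions, pools them, and returns the configured percentile scaled by
#' the pixel spacing. The pooled symmetric formulation is the common
#' medical-segmentation convention and is symmetric in its arguments.
#'
#' If both masks are empty for the class the distance is 0; if exactly one is
#' empty the distance is undefined and `NA` is returned with attribute
#' `valid = FALSE`.
#'
#' @param pred,gt Integer label matrices.
#' @param spec A [surface_spec()].
#' @param label Class evaluated one-vs-rest.
#' @return Distance in millimetres (possibly `NA` with `valid` attribute).
#' @export
hd95 <- function(pred, gt, spec = surface_spec(), label = 1L) {
  if (!identical(dim(pred), dim(gt)))
    stop("pred and gt must have identical dimensions", call. = FALSE)
  stopifnot(inherits(spec, "surface_spec"))
  p <- pred == label
  g <- gt == label
  if (!any(p) && !any(g)) return(structure(0, valid = TRUE))
  if (!any(p) || !any(g)) return(structure(NA_real_, valid = FALSE))
  bp <- boundary_points(p)
  bg <- boundary_points(g)
  d2 <- outer(bp[, 1], bg[, 1], "-")^2 + outer(bp[, 2], bg[, 2], "-")^2
  d_pg <- sqrt(apply(d2, 1, min))  # pred boundary -> nearest gt boundary
  d_gp <- sqrt(apply(d2, 2, min))  # gt boundary -> nearest pred boundary
  val <- unname(quantile(c(d_pg, d_gp), spec$percentile / 100, names = FALSE))
  structure(val * spec$pixel_spacing, valid = TRUE)
}

#' Evaluate one prediction against its ground truth
#'
#' Computes all five reported metrics (Dice, IoU, accuracy, sensitivity,
#' HD95) for one class from a single mask pair.
#'
#' @param pred,gt Integer label matrices.
#' @param label Class evaluated one-vs-rest.
#' @param spec A [surface_spec()].
#' @return A list of class `metric_report` with fields `dice`, `iou`,
#'   `accuracy`, `sensitivity`, `hd95`, `hd95_valid`.
#' @export
evaluate_pair <- function(pred, gt, label = 1L, spec = surface_spec()) {
  cc <- confusion(pred, gt, label)
  h <- hd95(pred, gt, spec, label)
  structure(list(dice = dice(cc), iou = iou(cc), accuracy = accuracy(cc),
                 sensitivity = sensitivity(cc), hd95 = as.numeric(h),
                 hd95_valid = isTRUE(attr(h, "valid"))),
            class = "metric_report")
}

#' Aggregate metric reports
#'
#' Arithmetic mean and sample standard deviation per metric. With a single
#' report the standard deviation is 0 by convention. HD95 is aggregated over
#' the reports whose surface distance was defined.
#'
#' @param reports List of `metric_report` objects.
#' @return Data frame with columns `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  one <- function(vals) {
    vals <- vals[!is.na(vals)]
    c(mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else 0,
      n = length(vals))
  }
  metrics <- c("dice", "iou", "accuracy", "sensitivity", "hd95")
  rows <- lapply(metrics, function(m) {
    vals <- vapply(reports, function(r) r[[m]], numeric(1))
    if (m == "hd95") {
      ok <- vapply(reports, function(r) r$hd95_valid, logical(1))
      vals <- vals[ok]
      if (length(vals) == 0L) vals <- NA_real_
    }
    s <- one(vals)
    data.frame(metric = m, mean = s[["mean"]], sd = s[["sd"]], n = s[["n"]])
  })
  do.call(rbind, rows)
}
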