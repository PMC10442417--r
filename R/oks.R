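#' Object Keypoint Similarity (OKS) evaluation
#'
#' 2D keypoint predictions are scored against ground truth with the COCO
#' object-keypoint-similarity measure: per keypoint,
#' \eqn{\exp(-d_i^2 / (2 k_i^2 s^2))}, where \eqn{d_i} is the pixel
#' distance to the ground-truth point, \eqn{k_i} the per-keypoint falloff
#' (0.08, the human-keypoint median, for all mouse keypoints), and \eqn{s}
#' the object scale: the square root of the bounding-box area, taken as the
#' minimal box over the ground-truth keypoints. The aggregate score is the
#' mean over all 20 keypoints. Thresholding the per-keypoint term at T is
#' equivalent to asking the prediction to fall within a pixel radius
#' \eqn{R = k s \sqrt{-2 \ln T}} of the truth.
#'
#' @name keypoint_metrics
NULL

#' OKS configuration
#'
#' @param falloff per-keypoint falloff constant(s), default 0.08 for all.
#' @param n_keypoints number of keypoints in the schema (default 20).
#' @param visible_only if `TRUE`, aggregate only over keypoints marked
#'   visible in the truth (off by default: occluded points are annotated
#'   with a best guess and still count).
#' @export
oks_config <- function(falloff = 0.08, n_keypoints = 20L,
                       visible_only = FALSE) {
  if (any(falloff <= 0)) stop("falloff must be positive")
  structure(list(falloff = falloff, n_keypoints = as.integer(n_keypoints),
                 visible_only = visible_only), class = "oks_config")
}

#' Minimal bounding-box area over a keypoint set
#'
#' @param points an `observed_keypoints2d` or n x 2 matrix of pixels.
#' @return Area in square pixels of the tightest axis-aligned box.
#' @export
keypoint_bbox_area <- function(points) {
  uv <- if (inherits(points, "observed_keypoints2d"))
    as.matrix(points[, c("u", "v")]) else as.matrix(points)
  diff(range(uv[, 1L])) * diff(range(uv[, 2L]))
}

#' Score a predicted keypoint set against ground truth
#'
#' @param pred,truth `observed_keypoints2d` sharing keypoint names.
#' @param bbox_area object bounding-box area in square pixels (> 0);
#'   defaults to the minimal box over the ground-truth keypoints.
#' @param config an `oks_config`.
#' @return Object of class `oks_result`: list with `per_keypoint` (named
#'   scores in [0, 1]), `aggregate` (their mean over `n_keypoints`), and
#'   `scale` (the s used).
#' @export
oks <- function(pred, truth, bbox_area = keypoint_bbox_area(truth),
                config = oks_config()) {
  if (bbox_area <= 0) stop("bbox_area must be positive")
  nm <- rownames(truth)
  missing <- setdiff(nm, rownames(pred))
  if (length(missing))
    stop("prediction missing keypoints: ", paste(missing, collapse = ", "))
  if (config$visible_only) nm <- nm[truth[nm, "visible"]]
  s <- sqrt(bbox_area)
  k <- rep_len(config$falloff, length(nm))
  d2 <- rowSums((as.matrix(pred[nm, c("u", "v")]) -
                   as.matrix(truth[nm, c("u", "v")]))^2)
  terms <- exp(-d2 / (2 * k^2 * s^2))
  denom <- if (config$visible_only) length(nm) else config$n_keypoints
  structure(list(per_keypoint = terms, aggregate = sum(terms) / denom,
                 scale = s), class = "oks_result")
}

#' Proportion of per-keypoint OKS scores above a threshold
#'
#' @param results list of `oks_result` (one per evaluated instance).
#' @param threshold OKS threshold T in (0, 1).
#' @return Named numeric vector: per keypoint name, the fraction of
#'   instances whose score exceeds T.
#' @export
accuracy_at_threshold <- function(results, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (length(results) == 0L) stop("no results")
  scores <- do.call(rbind, lapply(results, `[[`, "per_keypoint"))
  colMeans(scores > threshold)
}

#' Pixel radius equivalent to an OKS threshold
#'
#' The distance at which the per-keypoint OKS term equals T:
#' \eqn{R = k s \sqrt{-2 \ln T}}.
#'
#' @param threshold T in (0, 1).
#' @param falloff per-keypoint falloff k.
#' @param scale_s object scale s (sqrt of bounding-box area), pixels.
#' @return Radius in pixels.
#' @examples
#' s <- scale_from_radius(0.5, 0.08, 11.4)
#' radius_for_threshold(0.7, 0.08, s)  # ~8.2 px
#' @export
radius_for_threshold <- function(threshold, falloff, scale_s) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  falloff * scale_s * sqrt(-2 * log(threshold))
}

#' Object scale implied by a threshold/radius pair
#'
#' Exact inverse of [radius_for_threshold()].
#'
#' @inheritParams radius_for_threshold
#' @param radius pixel radius (> 0).
#' @export
scale_from_radius <- function(threshold, falloff, radius) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (radius <= 0) stop("radius must be positive")
  radius / (falloff * sqrt(-2 * log(threshold)))
}

#' Threshold-sweep report in the style of a keypoint-accuracy table
#'
#' @param preds,truths lists of `observed_keypoints2d` (paired frames).
#' @param thresholds OKS thresholds to report.
#' @param config an `oks_config`.
#' @return data.frame: one row per threshold with the equivalent radius at
#'   the mean object scale and per-keypoint-name accuracy columns.
#' @export
oks_report <- function(preds, truths, thresholds = c(0.5, 0.7, 0.9),
                       config = oks_config()) {
  if (length(preds) != length(truths)) stop("preds and truths must pair up")
  results <- Map(function(p, t) oks(p, t, config = config), preds, truths)
  scales <- vapply(results, `[[`, numeric(1), "scale")
  out <- lapply(thresholds, function(T) {
    acc <- accuracy_at_threshold(results, T)
    cbind(data.frame(threshold = T,
                     radius_px = radius_for_threshold(
                       T, config$falloff[1L], mean(scales))),
          as.data.frame(as.list(acc), check.names = FALSE))
  })
  do.call(rbind, out)
}
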