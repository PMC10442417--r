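#' Keypoint and pose file I/O
#'
#' 2D keypoints travel in a COCO-keypoint-style JSON dialect: a category
#' listing the 20 mouse keypoint names, one image record per frame, and one
#' annotation per frame whose `keypoints` array flattens
#' (x, y, confidence) per keypoint in category order. Fitted poses are
#' written as JSON lines, one record per frame, for diffability.
#'
#' @name cli_io
NULL

mouse_category <- function(keypoint_names) {
  list(id = 1L, name = "mouse", supercategory = "animal",
       keypoints = as.list(keypoint_names))
}

#' Write 2D keypoint frames to a COCO-style annotation file
#'
#' @param frames list of `observed_keypoints2d`, one per frame (frame order
#'   becomes image id order, 0-based).
#' @param path output JSON path.
#' @param keypoint_names category keypoint order; defaults to the first
#'   frame's rownames.
#' @export
write_keypoints <- function(frames, path,
                            keypoint_names = rownames(frames[[1]])) {
  images <- lapply(seq_along(frames) - 1L, function(id)
    list(id = id, file_name = sprintf("frame_%06d.png", id)))
  annotations <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    kp <- as.numeric(t(cbind(fr[keypoint_names, "u"],
                             fr[keypoint_names, "v"],
                             fr[keypoint_names, "confidence"])))
    list(id = i - 1L, image_id = i - 1L, category_id = 1L, keypoints = kp)
  })
  jsonlite::write_json(
    list(images = images, annotations = annotations,
         categories = list(mouse_category(keypoint_names))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read 2D keypoint frames from a COCO-style annotation file
#'
#' @param path annotation JSON path.
#' @param expected_names keypoint names the category must contain (default:
#'   the 20 default mouse keypoints); a mismatched schema is an error that
#'   names the missing keypoints.
#' @return List of `observed_keypoints2d` ordered by image id (empty list,
#'   with a warning, for an empty annotation set).
#' @export
read_keypoints <- function(path,
                           expected_names =
                             build_default_mouse_skeleton()$keypoint_names) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$categories) || length(obj$categories) == 0L)
    stop("annotation file has no categories: ", path)
  kp_names <- unlist(obj$categories[[1L]]$keypoints)
  missing <- setdiff(expected_names, kp_names)
  if (length(missing))
    stop("keypoint schema mismatch, missing: ",
         paste(missing, collapse = ", "))
  if (length(obj$annotations) == 0L) {
    warning("annotation file contains no annotations")
    return(list())
  }
  ids <- vapply(obj$annotations, function(a) as.numeric(a$image_id),
                numeric(1))
  frames <- lapply(obj$annotations[order(ids)], function(a) {
    kp <- matrix(unlist(a$keypoints), ncol = 3L, byrow = TRUE)
    if (nrow(kp) != length(kp_names))
      stop("annotation keypoint count does not match category")
    rownames(kp) <- kp_names
    observed_keypoints2d(kp[, 1:2, drop = FALSE], confidence = kp[, 3L])
  })
  frames
}

#' Write fitted poses as JSON lines
#'
#' One record per frame: joint angles (radians), bone lengths (mm), 3D
#' keypoints (mm), energy, reprojection RMSE, and convergence diagnostics.
#' Failed frames carry `ok = FALSE` and the error message.
#'
#' @param fits list of `pose_fit` (or `lift_failure`) from
#'   [lift_sequence()].
#' @param path output path (.jsonl).
#' @export
write_poses <- function(fits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    rec <- if (inherits(f, "pose_fit")) {
      list(frame = i - 1L, ok = TRUE, converged = f$converged,
           angles = as.numeric(f$pose$angles),
           bone_lengths = as.list(f$pose$bone_lengths),
           root_translation = f$pose$root_translation,
           keypoints3d = stats::setNames(
             lapply(seq_len(nrow(f$keypoints3d)), function(r)
               as.numeric(f$keypoints3d[r, ])),
             rownames(f$keypoints3d)),
           energy = f$final_energy,
           reprojection_rmse = f$final_reprojection_rmse,
           n_iterations = f$n_iterations)
    } else {
      list(frame = i - 1L, ok = FALSE, converged = FALSE,
           error = f$message)
    }
    writeLines(jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read fitted poses written by [write_poses()]
#'
#' @param path .jsonl path.
#' @return List of per-frame records (lists).
#' @export
read_poses <- function(path) {
  lapply(readLines(path), function(ln)
    jsonlite::fromJSON(ln, simplifyVector = TRUE))
}
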