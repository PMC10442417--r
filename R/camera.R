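#' Pinhole cameras, projection, and multiview triangulation
#'
#' Cameras follow the standard computer-vision pinhole convention: the
#' extrinsics map world coordinates (mm) into the camera frame, the
#' normalized coordinates (x/z, y/z) pass through an optional Brown-Conrady
#' distortion (three radial, two tangential coefficients), and the
#' intrinsics map to pixels with the origin at the top-left pixel center,
#' x right, y down.
#'
#' @name camera
NULL

#' Construct a camera model
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels.
#' @param rotation world-to-camera rotation: a 3x3 orthonormal matrix with
#'   determinant +1, or a length-3 rotation vector.
#' @param translation world-to-camera translation, mm (camera coordinates of
#'   the world origin).
#' @param distortion up to 5 Brown-Conrady coefficients (k1, k2, p1, p2, k3);
#'   shorter vectors are zero-padded. Default: no distortion.
#' @param image_size optional c(width, height) in pixels.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy, rotation = diag(3),
                         translation = c(0, 0, 0), distortion = numeric(5),
                         image_size = NULL) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (!is.matrix(rotation)) rotation <- rotvec_to_matrix(rotation)
  if (!is_rotation_matrix(rotation))
    stop("rotation must be orthonormal with determinant +1")
  if (length(distortion) > 5L) stop("at most 5 distortion coefficients")
  d <- numeric(5); d[seq_along(distortion)] <- distortion
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 rotation = rotation, translation = as.numeric(translation),
                 distortion = d, image_size = image_size),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> f=(%.1f, %.1f) c=(%.1f, %.1f) center=(%s) mm\n",
              x$fx, x$fy, x$cx, x$cy,
              paste(sprintf("%.1f", camera_center(x)), collapse = ", ")))
  invisible(x)
}

#' Camera center in world coordinates (mm)
#' @param camera a `camera_model`.
#' @export
camera_center <- function(camera) {
  as.numeric(-crossprod(camera$rotation, camera$translation))
}

apply_distortion <- function(xn, yn, d) {
  if (all(d == 0)) return(cbind(xn, yn))
  r2 <- xn^2 + yn^2
  radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
  xd <- xn * radial + 2 * d[3] * xn * yn + d[4] * (r2 + 2 * xn^2)
  yd <- yn * radial + d[3] * (r2 + 2 * yn^2) + 2 * d[4] * xn * yn
  cbind(xd, yd)
}

#' Project 3D world points to pixel coordinates
#'
#' @param camera a `camera_model`.
#' @param points a 3-vector or n x 3 matrix of world points (mm).
#' @return n x 2 matrix of (u, v) pixel coordinates (rownames preserved).
#'   Points at or behind the camera plane raise an error.
#' @examples
#' cam <- camera_model(fx = 100, fy = 100, cx = 0, cy = 0)
#' project(cam, c(10, 0, 100))  # (10, 0)
#' @export
project <- function(camera, points) {
  stopifnot(inherits(camera, "camera_model"))
  p <- if (is.null(dim(points))) matrix(points, 1L, 3L) else as.matrix(points)
  if (ncol(p) != 3L) stop("points must be n x 3")
  pc <- p %*% t(camera$rotation) +
    matrix(camera$translation, nrow(p), 3L, byrow = TRUE)
  if (any(pc[, 3L] <= 0))
    stop("point behind camera (z <= 0 in camera frame)")
  xy <- apply_distortion(pc[, 1L] / pc[, 3L], pc[, 2L] / pc[, 3L],
                         camera$distortion)
  out <- cbind(u = camera$fx * xy[, 1L] + camera$cx,
               v = camera$fy * xy[, 2L] + camera$cy)
  rownames(out) <- rownames(p)
  out
}

#' A 2D keypoint observation set
#'
#' @param uv n x 2 matrix of pixel coordinates with keypoint rownames.
#' @param confidence per-keypoint confidence in [0, 1] (default 1).
#' @param visible logical per keypoint (default `confidence > 0`).
#' @return Object of class `observed_keypoints2d`: a data.frame with columns
#'   u, v, confidence, visible and keypoint rownames.
#' @export
observed_keypoints2d <- function(uv, confidence = NULL, visible = NULL) {
  uv <- as.matrix(uv)
  if (ncol(uv) != 2L || is.null(rownames(uv)))
    stop("uv must be an n x 2 matrix with keypoint rownames")
  n <- nrow(uv)
  if (is.null(confidence)) confidence <- rep(1, n)
  if (any(confidence < 0 | confidence > 1)) stop("confidence must be in [0, 1]")
  if (is.null(visible)) visible <- confidence > 0
  if (any(visible & (!is.finite(uv[, 1L]) | !is.finite(uv[, 2L]))))
    stop("visible keypoints must have finite coordinates")
  structure(data.frame(u = uv[, 1L], v = uv[, 2L],
                       confidence = as.numeric(confidence),
                       visible = as.logical(visible),
                       row.names = rownames(uv)),
            class = c("observed_keypoints2d", "data.frame"))
}

# Rows of the homogeneous DLT system for one view
dlt_rows <- function(camera, uv) {
  P <- cbind(camera$rotation, camera$translation)
  K <- matrix(c(camera$fx, 0, 0, 0, camera$fy, 0, camera$cx, camera$cy, 1),
              3L, 3L)
  P <- K %*% P
  rbind(uv[1L] * P[3L, ] - P[1L, ],
        uv[2L] * P[3L, ] - P[2L, ])
}

reprojection_residuals <- function(point, cameras, observations) {
  unlist(lapply(seq_along(cameras), function(i)
    as.numeric(project(cameras[[i]], point)) - as.numeric(observations[[i]])))
}

#' Triangulate a 3D point from two or more calibrated views
#'
#' Direct linear transform (homogeneous least squares via SVD) for the
#' initial estimate, followed by Gauss-Newton refinement of the squared
#' pixel reprojection error. Refinement never worsens the reprojection RMSE:
#' steps that would increase it are rejected.
#'
#' @param observations list of (u, v) pixel pairs, one per camera.
#' @param cameras list of `camera_model`, same length (>= 2).
#' @param max_iterations Gauss-Newton iteration cap (default 50).
#' @param step_tolerance stop when the step norm falls below this (mm).
#' @return List with `point` (3-vector, mm), `rmse` (pixels, across all
#'   residuals), `per_view_rmse`, `dlt_rmse`, and `ill_conditioned` (TRUE
#'   when the viewing rays are near-parallel).
#' @export
triangulate <- function(observations, cameras, max_iterations = 50L,
                        step_tolerance = 1e-10) {
  if (length(cameras) < 2L || length(observations) < 2L)
    stop("triangulation requires at least 2 views")
  if (length(observations) != length(cameras))
    stop("observations and cameras must align")
  A <- do.call(rbind, Map(dlt_rows, cameras, observations))
  sv <- svd(A)
  X <- sv$v[, 4L]
  if (abs(X[4L]) < 1e-12) stop("degenerate DLT solution")
  point <- X[1:3] / X[4L]
  # ray-parallelism check: smallest pairwise angle between viewing rays
  dirs <- vapply(cameras, function(cm) {
    d <- point - camera_center(cm); d / sqrt(sum(d^2))
  }, numeric(3))
  max_ang <- 0
  for (i in seq_len(ncol(dirs) - 1L))
    for (k in (i + 1L):ncol(dirs)) {
      cang <- abs(sum(dirs[, i] * dirs[, k]))
      max_ang <- max(max_ang, acos(min(1, cang)))
    }
  ill <- max_ang < (1 * pi / 180)

  rss <- function(p) sum(reprojection_residuals(p, cameras, observations)^2)
  nres <- 2L * length(cameras)
  dlt_rmse <- sqrt(rss(point) / nres)
  cur <- rss(point)
  for (it in seq_len(max_iterations)) {
    r <- reprojection_residuals(point, cameras, observations)
    # numeric Jacobian, central differences
    J <- vapply(1:3, function(k) {
      h <- max(1e-6, abs(point[k]) * 1e-7)
      e <- numeric(3); e[k] <- h
      (reprojection_residuals(point + e, cameras, observations) -
         reprojection_residuals(point - e, cameras, observations)) / (2 * h)
    }, numeric(nres))
    step <- tryCatch(solve(crossprod(J), -crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- point + lambda * as.numeric(step)
      new <- tryCatch(rss(cand), error = function(e) Inf)
      if (new <= cur) { point <- cand; cur <- new; break }
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    if (sqrt(sum((lambda * step)^2)) < step_tolerance) break
  }
  res <- matrix(reprojection_residuals(point, cameras, observations),
                ncol = 2L, byrow = TRUE)
  list(point = point,
       rmse = sqrt(cur / nres),
       per_view_rmse = sqrt(rowSums(res^2) / 2),
       dlt_rmse = dlt_rmse,
       ill_conditioned = ill)
}

#' Reconstruct a full 3D keypoint set from multiple views
#'
#' Triangulates each keypoint independently from the cameras in which it is
#' visible. Keypoints visible in fewer than 2 views are returned with the
#' valid flag unset rather than raising an error.
#'
#' @param observations list of `observed_keypoints2d`, one per camera.
#' @param cameras list of `camera_model`, same length.
#' @return A `keypoints3d` over the union of observed keypoint names, with
#'   per-point validity flags and a `rmse` attribute (pixels, per point).
#' @export
reconstruct_pose_multiview <- function(observations, cameras) {
  if (length(observations) != length(cameras))
    stop("observations and cameras must align")
  names_all <- unique(unlist(lapply(observations, rownames)))
  pos <- matrix(NA_real_, length(names_all), 3L,
                dimnames = list(names_all, NULL))
  valid <- logical(length(names_all))
  rmse <- rep(NA_real_, length(names_all))
  for (i in seq_along(names_all)) {
    nm <- names_all[i]
    use <- which(vapply(observations, function(o)
      nm %in% rownames(o) && o[nm, "visible"], logical(1)))
    if (length(use) < 2L) next
    tri <- triangulate(lapply(use, function(k)
      as.numeric(observations[[k]][nm, c("u", "v")])), cameras[use])
    pos[i, ] <- tri$point
    valid[i] <- TRUE
    rmse[i] <- tri$rmse
  }
  pos[!valid, ] <- 0  # placeholder; flagged invalid
  out <- keypoints3d(pos, valid)
  attr(out, "rmse") <- stats::setNames(rmse, names_all)
  out
}

#' Save a camera calibration to YAML
#'
#' The file stores the 3x3 intrinsics matrix, the distortion vector, the
#' world-to-camera rotation matrix and translation, and the image size.
#'
#' @param camera a `camera_model`.
#' @param path output path.
#' @export
save_calibration <- function(camera, path) {
  obj <- list(
    camera_matrix = lapply(1:3, function(i)
      c(camera$fx, 0, camera$cx, 0, camera$fy, camera$cy, 0, 0, 1)[
        (3 * i - 2):(3 * i)]),
    distortion = as.numeric(camera$distortion),
    rotation = lapply(1:3, function(i) as.numeric(camera$rotation[i, ])),
    translation = as.numeric(camera$translation),
    image_size = camera$image_size
  )
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' Load a camera calibration from YAML
#'
#' Missing distortion blocks default to zero. A non-orthonormal or
#' reflecting rotation is rejected.
#'
#' @param path calibration file written by [save_calibration()].
#' @return A `camera_model`.
#' @export
load_calibration <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$camera_matrix) || is.null(obj$rotation) ||
      is.null(obj$translation))
    stop("malformed calibration file: ", path)
  K <- do.call(rbind, obj$camera_matrix)
  R <- do.call(rbind, obj$rotation)
  if (!is_rotation_matrix(R, tol = 1e-6))
    stop("calibration rotation is not a proper rotation matrix")
  # snap to the nearest rotation: file precision may leave ~1e-9 residuals
  sv <- svd(R)
  R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  camera_model(fx = K[1, 1], fy = K[2, 2], cx = K[1, 3], cy = K[2, 3],
               rotation = R, translation = unlist(obj$translation),
               distortion = obj$distortion %||% numeric(5),
               image_size = obj$image_size)
}

#' Convenience constructor: a camera looking at a target point
#'
#' Builds extrinsics so the optical axis points from `position` toward
#' `target`, with the image x-axis horizontal where possible.
#'
#' @param position camera center, world mm.
#' @param target point on the optical axis, world mm.
#' @param fx,fy,cx,cy intrinsics (pixels).
#' @param up approximate up direction used to fix the roll.
#' @param ... passed to [camera_model()].
#' @export
look_at_camera <- function(position, target, fx = 800, fy = 800,
                           cx = 320, cy = 240, up = c(0, 0, 1), ...) {
  z <- target - position
  z <- z / sqrt(sum(z^2))
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])  # up x z gives a right-handed frame
  nx <- sqrt(sum(x^2))
  if (nx < 1e-8) { # optical axis parallel to up: fall back
    x <- c(1, 0, 0); nx <- 1
  }
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- unname(rbind(x, y, z))
  camera_model(fx = fx, fy = fy, cx = cx, cy = cy, rotation = R,
               translation = as.numeric(-R %*% position), ...)
}
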