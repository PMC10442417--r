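#' @keywords internal
"_PACKAGE"

#' Rotation matrix from an axis-angle (rotation-vector) triple
#'
#' Rodrigues' formula. The zero vector maps to the identity; near zero a
#' second-order series keeps the map smooth (no 0/0).
#'
#' @param v numeric length-3 rotation vector (radians times unit axis).
#' @return 3x3 rotation matrix.
#' @keywords internal
rotvec_to_matrix <- function(v) {
  stopifnot(length(v) == 3L)
  th <- sqrt(sum(v^2))
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3L, 3L)
  if (th < 1e-8) {
    # sin(th)/th ~ 1 - th^2/6, (1-cos th)/th^2 ~ 1/2 - th^2/24
    diag(3L) + K * (1 - th^2 / 6) + (K %*% K) * (0.5 - th^2 / 24)
  } else {
    diag(3L) + K * (sin(th) / th) + (K %*% K) * ((1 - cos(th)) / th^2)
  }
}

#' Numerically stable log(sum(exp(x)))
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Check a matrix is a proper rotation (orthonormal, det +1)
#' @keywords internal
is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3L))) < tol && abs(det(R) - 1) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
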