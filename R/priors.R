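#' Pose and shape priors
#'
#' Monocular lifting is ill-posed: many 3D poses project to the same 2D
#' keypoints. Two Gaussian-mixture priors regularize the optimization. The
#' pose prior is fit over canonically normalized 3D poses (5 components),
#' the shape prior over per-animal bone-length vectors (7 components), and
#' both enter the energy as negative log-likelihood penalties.
#'
#' Pose normalization removes rigid placement and overall scale: poses are
#' translated so the base of the neck (upper spine) sits at the origin,
#' rotated so the vector to the middle of the spine lies along +x with unit
#' length, and rolled so the hip midpoint lies in the y = 0 half-plane on
#' the ventral (-z) side, i.e. dorsal side up.
#'
#' @name priors
NULL

#' Canonically normalize a 3D pose
#'
#' @param points a `keypoints3d` (or named n x 3 matrix) containing at least
#'   the spine points; hip joints, when present, fix the roll.
#' @param skeleton skeleton whose joint list selects and orders the output
#'   (ear keypoints are dropped).
#' @return An object of class `normalized_pose`: an n_joints x 3 matrix,
#'   dimensionless, with `upper_spine` at the origin and `middle_spine`
#'   at (1, 0, 0).
#' @export
normalize_pose <- function(points, skeleton = build_default_mouse_skeleton()) {
  pts <- as.matrix(points)
  need <- c("upper_spine", "middle_spine")
  if (!all(need %in% rownames(pts)))
    stop("normalization requires upper_spine and middle_spine")
  keep <- intersect(skeleton$joint_names, rownames(pts))
  pts <- pts[keep, , drop = FALSE]
  out <- normalize_core(pts,
                        match("upper_spine", keep),
                        match("middle_spine", keep),
                        match("left_hip", keep),
                        match("right_hip", keep))
  structure(out, class = "normalized_pose")
}

# alignment workhorse, index-based (also used in the optimizer hot loop):
# translate joint iu to the origin, rotate joint im onto +x, roll the hip
# midpoint into the y = 0 / z <= 0 half-plane, scale the iu->im bone to 1
normalize_core <- function(pts, iu, im, il, ir) {
  origin <- pts[iu, ]
  v <- pts[im, ] - origin
  s <- sqrt(sum(v^2))
  if (s < 1e-12)
    stop("degenerate pose: upper_spine and middle_spine coincide")
  pts <- pts - rep(origin, each = nrow(pts))
  a <- v / s
  axis <- c(0, a[3], -a[2])  # a x e1
  sa <- sqrt(sum(axis^2)); ca <- a[1]
  R1 <- if (sa < 1e-12) {
    if (ca > 0) diag(3) else diag(c(-1, -1, 1))  # 180 degrees about z
  } else {
    rotvec_to_matrix(axis / sa * atan2(sa, ca))
  }
  pts <- pts %*% t(R1)
  if (!is.na(il) && !is.na(ir)) {
    h <- (pts[il, ] + pts[ir, ]) / 2
    if (abs(h[2]) > 1e-12 || abs(h[3]) > 1e-12) {
      phi <- atan2(h[2], h[3]) + pi
      pts <- pts %*% t(rotvec_to_matrix(c(phi, 0, 0)))
    }
  }
  pts / s
}

#' Flatten a normalized pose to a feature vector
#'
#' Row-major concatenation (x, y, z per joint, joints in skeleton order);
#' the representation the pose prior is fit on (D = 54 for 18 joints).
#'
#' @param np a `normalized_pose`.
#' @return Numeric vector of length 3 x n_joints.
#' @export
flatten_pose <- function(np) as.numeric(t(unclass(np)))

## ---- Gaussian mixture machinery ----

# k-means++ seeding (Arthur & Vassilvitskii), then Lloyd assignment for the
# initial responsibilities. Runs under the caller's RNG state.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (i in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i, ] <- X[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[i, ])^2))
  }
  centers
}

# floor eigenvalues of a symmetric matrix; returns list(cov, chol inverse
# pieces) used for stable log-density evaluation
floor_covariance <- function(S, floor = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  list(cov = e$vectors %*% (vals * t(e$vectors)),
       logdet = sum(log(vals)),
       rot = e$vectors, inv_vals = 1 / vals)
}

# log N(x; mu, Sigma) for rows of X, from the eigendecomposition pieces
log_gauss <- function(X, mu, fc) {
  D <- length(mu)
  Z <- sweep(X, 2L, mu) %*% fc$rot
  maha <- as.numeric(Z^2 %*% fc$inv_vals)
  -0.5 * (D * log(2 * pi) + fc$logdet + maha)
}

#' Fit a Gaussian mixture model by expectation-maximization
#'
#' Full covariances, k-means++ initialization under the given seed, a
#' 1e-6 eigenvalue floor on every covariance (so degenerate directions --
#' e.g. the pinned coordinates of normalized poses -- stay well defined),
#' and the best of `n_restarts` runs by log-likelihood. With a fixed seed
#' the fit is bit-reproducible.
#'
#' @param samples numeric matrix, one sample per row (n >= n_components).
#' @param n_components number of mixture components.
#' @param seed integer RNG seed for initialization.
#' @param n_restarts independent initializations (default 5).
#' @param max_iterations EM iteration cap per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @param covariance_floor eigenvalue floor for covariances.
#' @return An object of class `gmm_prior`.
#' @export
fit_gmm <- function(samples, n_components, seed, n_restarts = 5L,
                    max_iterations = 200L, tol = 1e-8,
                    covariance_floor = 1e-6) {
  X <- as.matrix(samples)
  n <- nrow(X); D <- ncol(X); k <- as.integer(n_components)
  if (k < 1L) stop("n_components must be >= 1")
  if (n < k) stop(sprintf("need at least %d samples for %d components", k, k))
  if (any(apply(X, 2L, stats::var) < .Machine$double.eps) && D > 1L)
    warning("zero-variance dimension(s); covariance floor applies")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- withr::with_seed(seed + r - 1L,
                            em_gmm_once(X, k, max_iterations, tol,
                                        covariance_floor))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(list(n_components = k, weights = best$weights,
                 means = best$means, covariances = best$covariances,
                 dimension = D, fit_seed = as.integer(seed),
                 loglik = best$loglik, floors = best$floors,
                 var_names = colnames(X)),
            class = "gmm_prior")
}

em_gmm_once <- function(X, k, max_iterations, tol, floor) {
  n <- nrow(X); D <- ncol(X)
  centers <- kmeanspp_centers(X, k)
  assign <- apply(outer(rowSums(X^2), rowSums(centers^2), "+") -
                    2 * X %*% t(centers), 1L, which.min)
  w <- tabulate(assign, k) / n
  w[w == 0] <- 1 / n; w <- w / sum(w)
  mu <- centers
  fcs <- vector("list", k)
  for (j in seq_len(k)) {
    idx <- which(assign == j)
    S <- if (length(idx) > 1L) stats::cov(X[idx, , drop = FALSE]) else
      diag(D) * mean(apply(X, 2L, stats::var))
    if (length(idx) >= 1L) mu[j, ] <- colMeans(X[idx, , drop = FALSE])
    fcs[[j]] <- floor_covariance(S, floor)
  }
  ll_old <- -Inf
  for (it in seq_len(max_iterations)) {
    # E step (log domain)
    lp <- vapply(seq_len(k), function(j)
      log(w[j]) + log_gauss(X, mu[j, ], fcs[[j]]), numeric(n))
    lse <- apply(lp, 1L, logsumexp)
    ll <- sum(lse)
    G <- exp(lp - lse)  # responsibilities
    # M step
    nk <- colSums(G)
    nk <- pmax(nk, 1e-10)
    w <- nk / n
    mu <- (t(G) %*% X) / nk
    for (j in seq_len(k)) {
      Xc <- sweep(X, 2L, mu[j, ])
      S <- crossprod(Xc * G[, j], Xc) / nk[j]
      fcs[[j]] <- floor_covariance(S, floor)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12))
      { ll_old <- ll; break }
    ll_old <- ll
  }
  list(weights = as.numeric(w), means = mu,
       covariances = lapply(fcs, `[[`, "cov"),
       floors = fcs, loglik = ll_old)
}

#' @export
print.gmm_prior <- function(x, ...) {
  cat(sprintf("<gmm_prior> %d components in %d dimensions (loglik %.2f)\n",
              x$n_components, x$dimension, x$loglik))
  invisible(x)
}

prior_floors <- function(prior) {
  prior$floors %||% lapply(prior$covariances, floor_covariance, floor = 0)
}

#' Negative log-likelihood of a point under a GMM prior
#'
#' \eqn{-\log \sum_j w_j N(x; \mu_j, \Sigma_j)}; finite for any finite x.
#'
#' @param prior a `gmm_prior`.
#' @param x numeric vector of length `prior$dimension`, or a matrix with one
#'   point per row.
#' @return Numeric vector of NLL values.
#' @export
neg_log_likelihood <- function(prior, x) {
  X <- if (is.null(dim(x))) matrix(x, 1L) else as.matrix(x)
  if (ncol(X) != prior$dimension)
    stop(sprintf("dimension mismatch: prior is %d-dimensional, x has %d",
                 prior$dimension, ncol(X)))
  fcs <- prior_floors(prior)
  lp <- vapply(seq_len(prior$n_components), function(j)
    log(prior$weights[j]) + log_gauss(X, prior$means[j, ], fcs[[j]]),
    numeric(nrow(X)))
  if (nrow(X) == 1L) lp <- matrix(lp, 1L)
  -apply(lp, 1L, logsumexp)
}

#' Lower bound of a GMM prior's negative log-likelihood
#'
#' \eqn{-\log \sum_j w_j N(\mu_j;\mu_j,\Sigma_j)}, used to shift the prior
#' penalty into a nonnegative least-squares residual.
#'
#' @param prior a `gmm_prior`.
#' @export
nll_lower_bound <- function(prior) {
  fcs <- prior_floors(prior)
  peaks <- vapply(seq_len(prior$n_components), function(j)
    log(prior$weights[j]) -
      0.5 * (prior$dimension * log(2 * pi) + fcs[[j]]$logdet), numeric(1))
  -logsumexp(peaks)
}

# precomputed per-component pieces for fast repeated evaluation
gmm_cache <- function(prior) {
  fcs <- prior_floors(prior)
  lapply(seq_len(prior$n_components), function(j) list(
    mu = prior$means[j, ],
    rot = fcs[[j]]$rot,
    inv_vals = fcs[[j]]$inv_vals,
    inv_sqrt = sqrt(fcs[[j]]$inv_vals),
    logdet = fcs[[j]]$logdet,
    logw = log(prior$weights[j]),
    D = prior$dimension))
}

gmm_log_joint <- function(cache, x) {
  vapply(cache, function(cj) {
    z <- as.numeric(crossprod(cj$rot, x - cj$mu))
    cj$logw - 0.5 * (cj$D * log(2 * pi) + cj$logdet +
                       sum(z^2 * cj$inv_vals))
  }, numeric(1))
}

# posterior component responsibilities at x
gmm_responsibilities <- function(cache, x) {
  lp <- gmm_log_joint(cache, x)
  g <- exp(lp - max(lp))
  g / sum(g)
}

#' Mixture mean of a GMM prior
#' @param prior a `gmm_prior`.
#' @export
prior_mean <- function(prior) {
  as.numeric(crossprod(prior$means, prior$weights))
}

#' Fit the pose prior from a collection of 3D poses
#'
#' Each pose is canonically normalized ([normalize_pose()]), flattened to a
#' 54-vector, and a 5-component Gaussian mixture is fit.
#'
#' @param poses list of `keypoints3d` (>= 5).
#' @param seed integer RNG seed.
#' @param skeleton skeleton giving the joint order.
#' @param n_components mixture size (default 5).
#' @return A `gmm_prior` over normalized pose coordinates.
#' @export
fit_pose_prior <- function(poses, seed,
                           skeleton = build_default_mouse_skeleton(),
                           n_components = 5L) {
  if (length(poses) < n_components)
    stop(sprintf("need at least %d poses", n_components))
  X <- t(vapply(poses, function(p)
    flatten_pose(normalize_pose(p, skeleton)),
    numeric(3L * skeleton$n_joints)))
  colnames(X) <- paste(rep(skeleton$joint_names, each = 3L),
                       c("x", "y", "z"), sep = ".")
  fit_gmm(X, n_components, seed)
}

#' Fit the shape prior from a bone-length table
#'
#' One row per animal, 17 bone lengths (mm) per row, as tabulated from CT
#' scans of a cohort spanning sex, age, and weight; a 7-component Gaussian
#' mixture is fit over the length vectors.
#'
#' @param length_table matrix or data.frame, n >= 7 rows, one column per
#'   bone (all entries positive, mm).
#' @param seed integer RNG seed.
#' @param n_components mixture size (default 7).
#' @return A `gmm_prior` over bone-length vectors.
#' @export
fit_shape_prior <- function(length_table, seed, n_components = 7L) {
  X <- as.matrix(length_table)
  if (any(!is.finite(X)) || any(X <= 0))
    stop("bone lengths must be positive and finite")
  if (nrow(X) < n_components)
    stop(sprintf("need at least %d specimens", n_components))
  fit_gmm(X, n_components, seed)
}

#' Save / load a GMM prior as JSON
#'
#' @param prior a `gmm_prior`.
#' @param path file path.
#' @export
save_prior <- function(prior, path) {
  obj <- list(n_components = prior$n_components, weights = prior$weights,
              means = prior$means, covariances = prior$covariances,
              dimension = prior$dimension, fit_seed = prior$fit_seed,
              loglik = prior$loglik, var_names = prior$var_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_prior
#' @export
load_prior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- if (is.array(obj$covariances) && length(dim(obj$covariances)) == 3L)
    lapply(seq_len(dim(obj$covariances)[1L]), function(j)
      matrix(obj$covariances[j, , ], obj$dimension, obj$dimension))
  else lapply(obj$covariances, function(m) matrix(unlist(m), obj$dimension))
  structure(list(n_components = obj$n_components, weights = obj$weights,
                 means = matrix(unlist(obj$means), obj$n_components,
                                obj$dimension),
                 covariances = covs, dimension = obj$dimension,
                 fit_seed = obj$fit_seed, loglik = obj$loglik,
                 floors = lapply(covs, floor_covariance, floor = 0),
                 var_names = obj$var_names),
            class = "gmm_prior")
}
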