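#' Monocular 3D pose lifting
#'
#' Given one camera view's 2D keypoints, the lifter minimizes
#' \deqn{E(a, l) = \sum_i || proj(T(a, l)) - k_i ||^2
#'   + \lambda_p p_p(a) + \lambda_s p_s(l)}
#' over the 54 joint angles and 17 bone lengths of the kinematic chain:
#' the squared pixel distance between the projected forward-kinematics
#' joints and the observed keypoints, plus Gaussian-mixture pose and shape
#' penalties (negative log-likelihoods). Because the overall size and the
#' distance to the camera are confounded in a single view, the root is
#' constrained to a fixed, known distance from the camera center; it moves
#' on that sphere via two ray parameters. Bone lengths are optimized in log
#' space to stay positive. Ear keypoints never contribute residuals.
#'
#' The mixture penalties are minimized by majorize-minimize: at each outer
#' round the component responsibilities are frozen, which turns each
#' penalty into a responsibility-weighted sum of Mahalanobis quadratics
#' (the standard EM bound, tight at the current iterate); the resulting
#' nonlinear least-squares problem -- pixel residuals stacked with
#' whitened, sqrt(lambda)-scaled prior residuals -- is passed to
#' Levenberg-Marquardt. Every outer round can only decrease the true
#' energy.
#'
#' @name pose_optimizer
NULL

#' Configuration of the lifting energy
#'
#' @param fixed_distance root-to-camera-center distance in mm (> 0); the
#'   monocular scale anchor. Required.
#' @param lambda_pose weight of the pose-prior penalty (default 1e-2; kept
#'   small so the prior steers depth ambiguities without pinning the pose
#'   to the mixture).
#' @param lambda_shape weight of the shape-prior penalty (default 1e-1;
#'   larger, because bone lengths are only weakly constrained monocularly).
#' @param max_iterations inner least-squares iteration cap per outer round
#'   (default 200).
#' @param max_outer_rounds responsibility refreshes (default 8).
#' @param step_tolerance relative step-size stopping tolerance (default 1e-8).
#' @param residual_tolerance relative energy-decrease tolerance across outer
#'   rounds (default 1e-8).
#' @param confidence_floor keypoints with confidence below this are excluded
#'   from the residual (default 0.05); occluded detections carry confidence 0.
#' @param seed integer seed for any stochastic fallback.
#' @return Object of class `energy_config`.
#' @export
energy_config <- function(fixed_distance, lambda_pose = 1e-2,
                          lambda_shape = 1e-1, max_iterations = 200L,
                          max_outer_rounds = 8L,
                          step_tolerance = 1e-8, residual_tolerance = 1e-8,
                          confidence_floor = 0.05, seed = 1L) {
  if (fixed_distance <= 0) stop("fixed_distance must be positive")
  if (lambda_pose < 0 || lambda_shape < 0) stop("penalty weights must be >= 0")
  if (step_tolerance <= 0 || residual_tolerance <= 0)
    stop("tolerances must be positive")
  structure(list(fixed_distance = fixed_distance, lambda_pose = lambda_pose,
                 lambda_shape = lambda_shape,
                 max_iterations = as.integer(max_iterations),
                 max_outer_rounds = as.integer(max_outer_rounds),
                 step_tolerance = step_tolerance,
                 residual_tolerance = residual_tolerance,
                 confidence_floor = confidence_floor, seed = as.integer(seed)),
            class = "energy_config")
}

## ---- fast internal kinematics (no class overhead, used in the hot loop) ----

make_skel_cache <- function(skeleton) {
  n <- skeleton$n_joints
  order <- integer(0); done <- logical(n)
  repeat {
    ready <- which(!done & (is.na(skeleton$parent_index) |
                              done[pmax(skeleton$parent_index, 1L)]))
    if (length(ready) == 0L) break
    order <- c(order, ready); done[ready] <- TRUE
  }
  rest <- matrix(0, n, 3L)
  non_root <- setdiff(seq_len(n), skeleton$root_index)
  rest[non_root, ] <- skeleton$rest_direction[skeleton$joint_names[non_root], ]
  list(n = n, parent = skeleton$parent_index, order = order,
       root = skeleton$root_index, rest = rest,
       names = skeleton$joint_names, non_root = non_root,
       bone_names = skeleton$joint_names[non_root],
       iu = match("upper_spine", skeleton$joint_names),
       im = match("middle_spine", skeleton$joint_names),
       il = match("left_hip", skeleton$joint_names),
       ir = match("right_hip", skeleton$joint_names))
}

# joint positions (n x 3, named) from angle vector, per-joint length vector
# (root slot ignored) and root translation
fk_positions <- function(cache, angles, lengths_by_joint, root_t) {
  pos <- matrix(0, cache$n, 3L)
  rots <- vector("list", cache$n)
  for (i in cache$order) {
    Ri <- rotvec_to_matrix(angles[(3L * i - 2L):(3L * i)])
    p <- cache$parent[i]
    if (is.na(p)) {
      rots[[i]] <- Ri
      pos[i, ] <- root_t
    } else {
      G <- rots[[p]] %*% Ri
      rots[[i]] <- G
      pos[i, ] <- pos[p, ] + as.numeric(G %*% cache$rest[i, ]) *
        lengths_by_joint[i]
    }
  }
  rownames(pos) <- cache$names
  pos
}

# camera ray parameterization of the root: direction ~ (alpha, beta, 1) in
# the camera frame, scaled to the fixed distance, mapped back to world
ray_to_root <- function(camera, alpha, beta, distance) {
  d <- c(alpha, beta, 1)
  d <- d / sqrt(sum(d^2))
  as.numeric(crossprod(camera$rotation, distance * d - camera$translation))
}

root_to_ray <- function(camera, root_world) {
  pc <- as.numeric(camera$rotation %*% root_world + camera$translation)
  if (pc[3L] <= 0) stop("root behind camera")
  c(alpha = pc[1L] / pc[3L], beta = pc[2L] / pc[3L])
}

# lean projection of an n x 3 position block; NULL when any point is at or
# behind the camera plane
project_fast <- function(camera, pos) {
  pc <- pos %*% t(camera$rotation) +
    rep(camera$translation, each = nrow(pos))
  if (any(pc[, 3L] <= 0)) return(NULL)
  xy <- apply_distortion(pc[, 1L] / pc[, 3L], pc[, 2L] / pc[, 3L],
                         camera$distortion)
  cbind(camera$fx * xy[, 1L] + camera$cx, camera$fy * xy[, 2L] + camera$cy)
}

included_keypoints <- function(observations, skeleton, config) {
  nm <- intersect(rownames(observations), skeleton$joint_names)
  nm[observations[nm, "visible"] &
       observations[nm, "confidence"] >= config$confidence_floor]
}

#' Evaluate the lifting energy with its term-wise breakdown
#'
#' @param pose a `pose_state`.
#' @param observations an `observed_keypoints2d` keyed by skeleton keypoint
#'   names; keypoints below the confidence floor (and the ears) are excluded.
#' @param camera a `camera_model`.
#' @param pose_prior,shape_prior `gmm_prior` objects (either may be `NULL`
#'   when the corresponding weight is zero).
#' @param skeleton a `skeleton_definition`.
#' @param config an `energy_config`.
#' @return List with `total`, `reprojection`, `pose_penalty` (already
#'   weighted), `shape_penalty`, `included` (keypoint names), and
#'   `reprojection_rmse` (pixels per keypoint). The three terms sum to the
#'   total exactly.
#' @export
energy <- function(pose, observations, camera, pose_prior, shape_prior,
                   skeleton, config) {
  inc <- included_keypoints(observations, skeleton, config)
  if (length(inc) == 0L) stop("no keypoints above the confidence floor")
  kp <- forward_kinematics(skeleton, pose)
  uv <- project(camera, unclass(kp)[inc, , drop = FALSE])
  d2 <- rowSums((uv - as.matrix(observations[inc, c("u", "v")]))^2)
  reproj <- sum(d2)
  pp <- if (config$lambda_pose > 0) {
    if (is.null(pose_prior)) stop("lambda_pose > 0 requires a pose prior")
    config$lambda_pose *
      neg_log_likelihood(pose_prior,
                         flatten_pose(normalize_pose(kp, skeleton)))
  } else 0
  ps <- if (config$lambda_shape > 0) {
    if (is.null(shape_prior)) stop("lambda_shape > 0 requires a shape prior")
    config$lambda_shape * neg_log_likelihood(shape_prior,
                                             as.numeric(pose$bone_lengths))
  } else 0
  list(total = reproj + pp + ps, reprojection = reproj,
       pose_penalty = pp, shape_penalty = ps, included = inc,
       reprojection_rmse = sqrt(mean(d2)))
}

#' Initial pose estimate from one view's observations
#'
#' Rest-pose angles; the root is placed on the back-projected ray of the
#' lower-spine observation at the configured fixed distance (falling back to
#' the centroid of all visible keypoints when the spine is unobserved); the
#' body yaw about the camera's optical axis is chosen by a coarse-to-fine
#' 1-D search matching the projected spine keypoints; bone lengths are the
#' shape prior's mixture mean (or the stock mouse lengths without a prior).
#'
#' @inheritParams energy
#' @param shape_prior optional `gmm_prior` over bone lengths.
#' @return A `pose_state`; attribute `fallback` is `TRUE` when the centroid
#'   fallback was used.
#' @export
initialize_pose <- function(observations, camera, skeleton, config,
                            shape_prior = NULL) {
  lens <- if (!is.null(shape_prior)) {
    l <- prior_mean(shape_prior)
    names(l) <- shape_prior$var_names %||%
      skeleton$joint_names[-skeleton$root_index]
    l
  } else default_bone_lengths(skeleton)
  inc <- included_keypoints(observations, skeleton, config)
  fallback <- FALSE
  root_name <- skeleton$joint_names[skeleton$root_index]
  if (root_name %in% inc) {
    uv <- as.numeric(observations[root_name, c("u", "v")])
  } else {
    vis <- rownames(observations)[observations$visible]
    if (length(vis) == 0L) {
      uv <- c(camera$cx, camera$cy); fallback <- TRUE
    } else {
      uv <- colMeans(as.matrix(observations[vis, c("u", "v")]))
      fallback <- TRUE
    }
  }
  alpha <- (uv[1L] - camera$cx) / camera$fx
  beta <- (uv[2L] - camera$cy) / camera$fy
  root_t <- ray_to_root(camera, alpha, beta, config$fixed_distance)
  # yaw search about the optical axis
  axis_world <- as.numeric(crossprod(camera$rotation, c(0, 0, 1)))
  cache <- make_skel_cache(skeleton)
  lens_by_joint <- numeric(cache$n)
  lens_by_joint[cache$non_root] <- lens[cache$bone_names]
  spine <- intersect(c("lower_spine", "middle_spine", "upper_spine", "nose"),
                     inc)
  angles0 <- rep(0, 3L * cache$n)
  spine_idx <- match(spine, cache$names)
  obs_spine <- as.matrix(observations[spine, c("u", "v")])
  yaw_cost <- function(g) {
    ang <- angles0
    ang[(3L * cache$root - 2L):(3L * cache$root)] <- axis_world * g
    pos <- fk_positions(cache, ang, lens_by_joint, root_t)
    uvp <- project_fast(camera, pos[spine_idx, , drop = FALSE])
    if (is.null(uvp)) return(1e12)
    sum((uvp - obs_spine)^2)
  }
  yaw <- 0
  if (length(spine) >= 2L) {
    grid <- seq(0, 2 * pi, length.out = 73L)[-73L]
    costs <- vapply(grid, yaw_cost, numeric(1))
    g0 <- grid[which.min(costs)]
    opt <- stats::optimize(yaw_cost, lower = g0 - 0.2, upper = g0 + 0.2,
                           tol = 1e-10)
    yaw <- opt$minimum
  }
  ang <- angles0
  ang[(3L * cache$root - 2L):(3L * cache$root)] <- axis_world * yaw
  # body-scale estimate from the observed spine span: the projected spine
  # length is directly observable at the fixed distance, so rescaling the
  # prior-mean lengths here starts the optimizer in the right size regime
  if (length(spine) >= 2L) {
    pos <- fk_positions(cache, ang, lens_by_joint, root_t)
    uvp <- project_fast(camera, pos[spine_idx, , drop = FALSE])
    if (!is.null(uvp)) {
      span <- function(m) {
        cc <- colMeans(m)
        mean(sqrt((m[, 1L] - cc[1L])^2 + (m[, 2L] - cc[2L])^2))
      }
      s_hat <- span(obs_spine) / span(uvp)
      if (is.finite(s_hat) && s_hat > 0.3 && s_hat < 3) lens <- lens * s_hat
    }
  }
  out <- pose_state(ang, lens, root_t, skeleton)
  attr(out, "fallback") <- fallback
  out
}

# stacked whitened residual block for one GMM penalty with responsibilities
# frozen at gamma: rows A and offset b with
# ||A x - b||^2 = (lambda / 2) * sum_j gamma_j * mahalanobis_j(x),
# the EM majorizer of lambda * NLL(x) up to an x-independent constant
prior_quad_stack <- function(cache, gamma, lambda, drop_tol = 1e-10) {
  use <- which(gamma > drop_tol)
  blocks <- lapply(use, function(j) {
    cj <- cache[[j]]
    A <- sqrt(lambda * gamma[j] / 2) * (cj$inv_sqrt * t(cj$rot))
    list(A = A, b = as.numeric(A %*% cj$mu))
  })
  list(A = do.call(rbind, lapply(blocks, `[[`, "A")),
       b = unlist(lapply(blocks, `[[`, "b")))
}

pose_to_theta <- function(pose, camera, cache) {
  c(pose$angles, log(as.numeric(pose$bone_lengths[cache$bone_names])),
    root_to_ray(camera, pose$root_translation))
}

theta_to_pose <- function(theta, camera, cache, config, skeleton) {
  na <- 3L * cache$n
  lens <- exp(theta[na + seq_along(cache$non_root)])
  names(lens) <- cache$bone_names
  ab <- theta[(na + length(cache$non_root) + 1L):length(theta)]
  pose_state(theta[seq_len(na)], lens,
             ray_to_root(camera, ab[1L], ab[2L], config$fixed_distance),
             skeleton)
}

# pose positions and decomposed quantities from the parameter vector
theta_parts <- function(theta, camera, cache, config) {
  na <- 3L * cache$n
  lens <- exp(theta[na + seq_along(cache$non_root)])
  lens_by_joint <- numeric(cache$n)
  lens_by_joint[cache$non_root] <- lens
  ab <- theta[c(na + length(cache$non_root) + 1L,
                na + length(cache$non_root) + 2L)]
  root_t <- ray_to_root(camera, ab[1L], ab[2L], config$fixed_distance)
  pos <- fk_positions(cache, theta[seq_len(na)], lens_by_joint, root_t)
  list(pos = pos, lens = lens)
}

norm_vec_from_pos <- function(pos, cache) {
  as.numeric(t(normalize_core(pos, cache$iu, cache$im, cache$il, cache$ir)))
}

# true energy at theta via the cached prior pieces
energy_at_theta <- function(theta, camera, cache, config, inc_idx, obs_uv,
                            pcache, scache) {
  parts <- theta_parts(theta, camera, cache, config)
  uv <- project_fast(camera, parts$pos[inc_idx, , drop = FALSE])
  if (is.null(uv)) return(Inf)
  reproj <- sum((uv - obs_uv)^2)
  pp <- if (!is.null(pcache))
    -logsumexp(gmm_log_joint(pcache, norm_vec_from_pos(parts$pos, cache))) *
      config$lambda_pose else 0
  ps <- if (!is.null(scache))
    -logsumexp(gmm_log_joint(scache, parts$lens)) * config$lambda_shape else 0
  reproj + pp + ps
}

#' Fit the 3D pose to one view's 2D keypoints
#'
#' Majorize-minimize over the mixture priors with Levenberg-Marquardt
#' inner solves (see [pose_optimizer]); the decision variables are the 54
#' joint angles, 17 log-bone-lengths, and 2 root-ray parameters. The
#' recorded energy trace (true energy at the end of each outer round) is
#' non-increasing. Non-convergence is reported in the result, not raised.
#'
#' @inheritParams energy
#' @param initial optional `pose_state` to start from; when absent,
#'   [initialize_pose()] is used.
#' @return A `pose_fit`: list with `pose` (a `pose_state`), `keypoints3d`,
#'   `energy_trace`, `final_energy`, `final_reprojection_rmse` (pixels),
#'   `converged`, `excluded_keypoints`, `n_iterations`, and `message`.
#' @export
optimize_pose <- function(observations, camera, skeleton, pose_prior,
                          shape_prior, config, initial = NULL) {
  inc <- included_keypoints(observations, skeleton, config)
  if (length(inc) < 4L)
    stop(sprintf("only %d usable keypoints (need >= 4)", length(inc)))
  cache <- make_skel_cache(skeleton)
  if (is.null(initial))
    initial <- initialize_pose(observations, camera, skeleton, config,
                               shape_prior)
  use_pose <- config$lambda_pose > 0
  use_shape <- config$lambda_shape > 0
  if (use_pose && is.null(pose_prior))
    stop("lambda_pose > 0 requires a pose prior")
  if (use_shape && is.null(shape_prior))
    stop("lambda_shape > 0 requires a shape prior")
  pcache <- if (use_pose) gmm_cache(pose_prior) else NULL
  scache <- if (use_shape) gmm_cache(shape_prior) else NULL
  inc_idx <- match(inc, cache$names)
  obs_uv <- as.matrix(observations[inc, c("u", "v")])
  n_par <- 3L * cache$n + length(cache$non_root) + 2L

  theta <- pose_to_theta(initial, camera, cache)
  e_cur <- energy_at_theta(theta, camera, cache, config, inc_idx, obs_uv,
                           pcache, scache)
  trace <- e_cur
  total_iter <- 0L
  converged <- FALSE
  message <- ""
  rounds <- if (use_pose || use_shape) config$max_outer_rounds else 1L
  for (round in seq_len(rounds)) {
    parts <- theta_parts(theta, camera, cache, config)
    qp <- if (use_pose)
      prior_quad_stack(pcache,
                       gmm_responsibilities(
                         pcache, norm_vec_from_pos(parts$pos, cache)),
                       config$lambda_pose) else NULL
    qs <- if (use_shape)
      prior_quad_stack(scache, gmm_responsibilities(scache, parts$lens),
                       config$lambda_shape) else NULL
    n_res <- 2L * length(inc) +
      (if (use_pose) nrow(qp$A) else 0L) +
      (if (use_shape) nrow(qs$A) else 0L)
    pad <- max(0L, n_par + 1L - n_res)
    big <- rep(1e6, n_res + pad)
    fn <- function(th) {
      pr <- tryCatch(theta_parts(th, camera, cache, config),
                     error = function(e) NULL)
      if (is.null(pr)) return(big)
      uv <- project_fast(camera, pr$pos[inc_idx, , drop = FALSE])
      if (is.null(uv)) return(big)
      r <- as.numeric(uv - obs_uv)
      if (use_pose) {
        npv <- tryCatch(norm_vec_from_pos(pr$pos, cache),
                        error = function(e) NULL)
        if (is.null(npv)) return(big)
        r <- c(r, as.numeric(qp$A %*% npv) - qp$b)
      }
      if (use_shape) r <- c(r, as.numeric(qs$A %*% pr$lens) - qs$b)
      if (pad) c(r, numeric(pad)) else r
    }
    # inner solves may legitimately stop at maxiter between responsibility
    # refreshes; convergence is judged at the outer level
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = theta, fn = fn,
      control = minpack.lm::nls.lm.control(
        maxiter = config$max_iterations, ptol = config$step_tolerance,
        ftol = config$residual_tolerance, nprint = 0, maxfev = 100000L)))
    total_iter <- total_iter + fit$niter
    message <- fit$message
    e_new <- energy_at_theta(fit$par, camera, cache, config, inc_idx, obs_uv,
                             pcache, scache)
    # MM guarantees descent of the true energy; guard against numerics
    if (e_new <= e_cur) {
      theta <- fit$par
      trace <- c(trace, e_new)
    } else {
      converged <- TRUE
      break
    }
    if (e_cur - e_new <=
        config$residual_tolerance * (abs(e_cur) + 1)) {
      converged <- TRUE
      e_cur <- e_new
      break
    }
    e_cur <- e_new
  }
  pose <- theta_to_pose(theta, camera, cache, config, skeleton)
  kp <- forward_kinematics(skeleton, pose)
  uv <- project(camera, unclass(kp)[inc, , drop = FALSE])
  d2 <- rowSums((uv - obs_uv)^2)
  structure(list(
    pose = pose,
    keypoints3d = kp,
    energy_trace = trace,
    final_energy = e_cur,
    final_reprojection_rmse = sqrt(mean(d2)),
    converged = converged,
    excluded_keypoints = setdiff(
      intersect(rownames(observations), skeleton$keypoint_names), inc),
    n_iterations = total_iter,
    message = message
  ), class = "pose_fit")
}

#' @export
print.pose_fit <- function(x, ...) {
  cat(sprintf(paste0("<pose_fit> energy %.4g, reprojection RMSE %.3g px, ",
                     "%d iterations, %sconverged\n"),
              x$final_energy, x$final_reprojection_rmse, x$n_iterations,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Lift a sequence of frames
#'
#' Frame t > 1 is warm-started from frame t-1's solution; a frame that
#' fails (e.g. all keypoints occluded) is flagged and the sequence
#' continues, the next frame restarting from the last good solution or the
#' default initializer.
#'
#' @param frames list of `observed_keypoints2d`, one per frame.
#' @inheritParams energy
#' @return List of `pose_fit` (failed frames hold a `lift_failure` entry
#'   with the error message).
#' @export
lift_sequence <- function(frames, camera, skeleton, pose_prior, shape_prior,
                          config) {
  if (length(frames) < 1L) stop("need at least one frame")
  out <- vector("list", length(frames))
  last_good <- NULL
  for (t in seq_along(frames)) {
    res <- tryCatch(
      optimize_pose(frames[[t]], camera, skeleton, pose_prior, shape_prior,
                    config, initial = last_good),
      error = function(e) structure(list(converged = FALSE,
                                         message = conditionMessage(e)),
                                    class = "lift_failure"))
    out[[t]] <- res
    if (inherits(res, "pose_fit")) last_good <- res$pose
  }
  out
}
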