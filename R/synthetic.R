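#' Synthetic scenes and traces with known ground truth
#'
#' Every stage of the pipeline is exercised against synthetic data built by
#' inverting the reconstruction problem: pose a skeleton by forward
#' kinematics, project it through known cameras, add Gaussian pixel noise
#' and occlusions, and generate periodic foot traces of known frequency.
#' All generators are pure functions of their parameters and a seed.
#'
#' @name synthetic_fixtures
NULL

#' The default synthetic camera rig
#'
#' Mirrors a three-camera capture rig over a mouse cage: one top-down
#' camera and two side cameras 90 degrees apart in azimuth, 350-450 mm
#' from the cage center, all 640x480 px with 800 px focal length.
#'
#' @return List of three `camera_model`s named top, side1, side2.
#' @export
default_camera_rig <- function() {
  list(
    top = look_at_camera(c(0, 0, 400), c(0, 0, 0)),
    side1 = look_at_camera(c(450, 0, 60), c(0, 0, 20)),
    side2 = look_at_camera(c(0, 450, 60), c(0, 0, 20))
  )
}

#' Synthetic cohort bone-length table
#'
#' Emulates a CT-measured cohort structured into body-size groups (e.g.
#' weight-by-sex groups): each group scales the stock adult bone lengths by
#' a factor evenly spaced in [0.8, 1.2], with 3% within-group coefficient
#' of variation per bone.
#'
#' @param n_specimens rows to generate (>= n_groups).
#' @param n_groups number of size groups (default 4).
#' @param seed integer RNG seed.
#' @param skeleton skeleton providing the bone names.
#' @return n x 17 matrix of lengths (mm), bone-named columns, with a
#'   `group` attribute giving each specimen's group index.
#' @export
sample_cohort_bone_lengths <- function(n_specimens, n_groups = 4L, seed = 1L,
                                       skeleton = build_default_mouse_skeleton()) {
  if (n_specimens < n_groups) stop("need at least one specimen per group")
  base <- default_bone_lengths(skeleton)
  scales <- if (n_groups == 1L) 1 else seq(0.8, 1.2, length.out = n_groups)
  group <- rep(seq_len(n_groups), length.out = n_specimens)
  group <- sort(group)
  X <- withr::with_seed(seed, {
    t(vapply(seq_len(n_specimens), function(i)
      base * scales[group[i]] * (1 + stats::rnorm(length(base), 0, 0.03)),
      numeric(length(base))))
  })
  colnames(X) <- names(base)
  attr(X, "group") <- group
  attr(X, "group_scales") <- scales
  X
}

# limb-swing angle pattern of a diagonal (trot-like) gait at a given phase:
# forelimb and contralateral hindlimb swing together
gait_angles <- function(skeleton, phase, amplitude = pi / 6) {
  ang <- rep(0, 3L * skeleton$n_joints)
  set_y <- function(joint, value) {
    i <- match(joint, skeleton$joint_names)
    ang[3L * i - 1L] <<- value
  }
  s <- sin(phase); s2 <- sin(phase - pi / 4)
  set_y("left_shoulder", amplitude * s)
  set_y("right_shoulder", -amplitude * s)
  set_y("left_elbow", amplitude / 2 * s2)
  set_y("right_elbow", -amplitude / 2 * s2)
  set_y("right_hip", amplitude * s)
  set_y("left_hip", -amplitude * s)
  set_y("right_knee", amplitude / 2 * s2)
  set_y("left_knee", -amplitude / 2 * s2)
  ang
}

#' Sample a synthetic pose
#'
#' Modes: `rest` (all angles zero), `gait` (sinusoidal limb-angle
#' oscillation of +/- 30 degrees at the given phase, diagonal limb
#' coupling), `random` (every angle uniform in +/- 45 degrees). Bone
#' lengths default to a single cohort draw under the same seed.
#'
#' @param skeleton a `skeleton_definition`.
#' @param mode one of "rest", "gait", "random".
#' @param phase gait phase in radians (gait mode).
#' @param seed integer RNG seed (random mode and cohort draw).
#' @param bone_lengths optional named 17-vector (mm).
#' @param root_translation root position, default 30 mm above the floor
#'   origin.
#' @param jitter_sd SD (radians) of Gaussian jitter added to all non-root
#'   angles (default 0, deterministic given mode/phase).
#' @return A `pose_state`.
#' @export
sample_pose <- function(skeleton, mode = c("rest", "gait", "random"),
                        phase = 0, seed = 1L, bone_lengths = NULL,
                        root_translation = c(0, 0, 30), jitter_sd = 0) {
  mode <- match.arg(mode)
  if (is.null(bone_lengths))
    bone_lengths <- sample_cohort_bone_lengths(1L, 1L, seed,
                                               skeleton)[1L, ]
  ang <- switch(mode,
    rest = rep(0, 3L * skeleton$n_joints),
    gait = gait_angles(skeleton, phase),
    random = withr::with_seed(seed,
      stats::runif(3L * skeleton$n_joints, -pi / 4, pi / 4)))
  if (jitter_sd > 0) {
    jit <- withr::with_seed(seed + 1L,
      stats::rnorm(3L * skeleton$n_joints, 0, jitter_sd))
    jit[(3L * skeleton$root_index - 2L):(3L * skeleton$root_index)] <- 0
    ang <- ang + jit
  }
  pose_state(ang, bone_lengths, root_translation, skeleton)
}

#' Sample a set of gait-cycle poses
#'
#' Poses spread over the gait cycle with small angle jitter and per-animal
#' bone lengths drawn from the synthetic cohort; the stock training set for
#' the pose prior. The default jitter (0.005 rad) models the measurement
#' noise of a multiview reconstruction around the canonical cycle, which is
#' what a pose-prior training set is in practice.
#'
#' @param skeleton a `skeleton_definition`.
#' @param n number of poses.
#' @param seed integer RNG seed.
#' @param jitter_sd angle jitter SD, radians (default 0.005).
#' @return List of `pose_state`.
#' @export
sample_gait_poses <- function(skeleton, n, seed = 1L, jitter_sd = 0.005) {
  phases <- withr::with_seed(seed, stats::runif(n, 0, 2 * pi))
  lapply(seq_len(n), function(i)
    sample_pose(skeleton, "gait", phase = phases[i], seed = seed + 13L * i,
                jitter_sd = jitter_sd))
}

#' Render a pose into multi-camera observations
#'
#' Projects the forward-kinematics keypoints into every camera, adds
#' i.i.d. Gaussian pixel noise, and marks floor(occlusion_fraction x 20)
#' randomly chosen keypoints as occluded (confidence 0) in every view.
#'
#' @param skeleton a `skeleton_definition`.
#' @param pose a `pose_state`.
#' @param cameras list of `camera_model`.
#' @param noise_sigma_px pixel noise SD (default 0).
#' @param occlusion_fraction fraction of the 20 keypoints occluded.
#' @param seed integer RNG seed.
#' @return Object of class `synthetic_scene`: list with the inputs, the
#'   true `keypoints3d`, and `observations` (one `observed_keypoints2d`
#'   per camera).
#' @export
render_scene <- function(skeleton, pose, cameras = default_camera_rig(),
                         noise_sigma_px = 0, occlusion_fraction = 0,
                         seed = 1L) {
  kp <- forward_kinematics(skeleton, pose)
  nk <- nrow(kp)
  n_occ <- floor(occlusion_fraction * nk)
  occluded <- withr::with_seed(seed,
    sample(rownames(kp), n_occ))
  obs <- withr::with_seed(seed + 1L, lapply(cameras, function(cm) {
    uv <- project(cm, unclass(kp))
    if (noise_sigma_px > 0)
      uv <- uv + matrix(stats::rnorm(length(uv), 0, noise_sigma_px),
                        nrow(uv), 2L)
    conf <- ifelse(rownames(uv) %in% occluded, 0, 1)
    observed_keypoints2d(uv, confidence = conf)
  }))
  structure(list(skeleton = skeleton, true_pose = pose, true_keypoints = kp,
                 cameras = cameras, observations = obs,
                 noise_sigma_px = noise_sigma_px, occluded_names = occluded,
                 seed = seed),
            class = "synthetic_scene")
}

#' Single-view recovery benchmark on synthetic gait scenes
#'
#' The package's stock correctness harness: fit the priors on the synthetic
#' cohort and gait manifold, render `n_scenes` single-view scenes of poses
#' drawn from the gait cycle with cohort bone lengths, lift each at the true
#' camera distance, and measure per-joint 3D errors against the ground
#' truth.
#'
#' @param n_scenes number of scenes (default 50).
#' @param noise_sigma_px pixel noise SD added to the observations.
#' @param occlusion_fraction fraction of keypoints occluded per scene.
#' @param seed integer RNG seed driving every draw.
#' @param skeleton skeleton to use.
#' @param config_args named list of [energy_config()] overrides
#'   (`fixed_distance` is set per scene to the true distance).
#' @param pose_prior,shape_prior optional pre-fit priors (fit from the
#'   stock generators under `seed` when omitted).
#' @return List with `errors` (n_scenes x n_joints matrix, mm),
#'   `median_error_mm` (pooled over all joints and scenes),
#'   `convergence_rate`, and `per_scene_median`.
#' @export
recovery_benchmark <- function(n_scenes = 50L, noise_sigma_px = 0,
                               occlusion_fraction = 0, seed = 1L,
                               skeleton = build_default_mouse_skeleton(),
                               config_args = list(),
                               pose_prior = NULL, shape_prior = NULL) {
  tab <- sample_cohort_bone_lengths(80L, 4L, seed = seed + 6L)
  if (is.null(shape_prior)) shape_prior <- fit_shape_prior(tab, seed = seed + 8L)
  if (is.null(pose_prior)) {
    train <- sample_gait_poses(skeleton, 200L, seed = seed + 10L)
    pose_prior <- suppressWarnings(fit_pose_prior(
      lapply(train, function(p) forward_kinematics(skeleton, p)),
      seed = seed + 4L))
  }
  camera <- default_camera_rig()$top
  errors <- matrix(NA_real_, n_scenes, skeleton$n_joints,
                   dimnames = list(NULL, skeleton$joint_names))
  converged <- logical(n_scenes)
  for (i in seq_len(n_scenes)) {
    draw <- withr::with_seed(seed + 100L * i, list(
      phase = stats::runif(1, 0, 2 * pi),
      row = sample.int(nrow(tab), 1L)))
    pose <- sample_pose(skeleton, "gait", phase = draw$phase,
                        bone_lengths = tab[draw$row, ])
    scene <- render_scene(skeleton, pose, list(camera),
                          noise_sigma_px = noise_sigma_px,
                          occlusion_fraction = occlusion_fraction,
                          seed = seed + 100L * i + 1L)
    D <- sqrt(sum((camera_center(camera) - pose$root_translation)^2))
    cfg <- do.call(energy_config, c(list(fixed_distance = D), config_args))
    fit <- tryCatch(
      optimize_pose(scene$observations[[1L]], camera, skeleton,
                    pose_prior, shape_prior, cfg),
      error = function(e) NULL)
    if (is.null(fit)) next
    converged[i] <- fit$converged
    errors[i, ] <- sqrt(rowSums(
      (unclass(fit$keypoints3d)[skeleton$joint_names, ] -
         unclass(scene$true_keypoints)[skeleton$joint_names, ])^2))
  }
  list(errors = errors,
       median_error_mm = stats::median(errors, na.rm = TRUE),
       convergence_rate = mean(converged),
       per_scene_median = apply(errors, 1L, stats::median))
}

#' Synthetic periodic foot trace
#'
#' amplitude x sin(2 pi f t) + drift x t + Gaussian noise, sampled at fps
#' for the given duration. Frequencies at or above the Nyquist rate are
#' rejected.
#'
#' @param frequency_hz stride frequency (< fps / 2).
#' @param fps frames per second.
#' @param duration_s trace length in seconds.
#' @param amplitude oscillation amplitude (default 1).
#' @param noise_sigma Gaussian noise SD (default 0).
#' @param drift_per_s linear drift per second (default 0).
#' @param seed integer RNG seed.
#' @return A `foot_trace` (not detrended).
#' @export
make_gait_trace <- function(frequency_hz, fps, duration_s, amplitude = 1,
                            noise_sigma = 0, drift_per_s = 0, seed = 1L) {
  if (frequency_hz >= fps / 2)
    stop("frequency at or above the Nyquist rate fps/2: aliasing")
  n <- round(fps * duration_s)
  t <- (seq_len(n) - 1L) / fps
  x <- amplitude * sin(2 * pi * frequency_hz * t) + drift_per_s * t
  if (noise_sigma > 0)
    x <- x + withr::with_seed(seed, stats::rnorm(n, 0, noise_sigma))
  foot_trace(x, fps)
}
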