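# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# two-joint toy chain: root -> tip along +x
toy_chain <- function(rest = c(1, 0, 0)) {
  skeleton_definition(joint_names = c("root", "tip"),
                      parent_index = c(NA, 1L),
                      rest_direction = matrix(rest / sqrt(sum(rest^2)), 1L, 3L,
                                              dimnames = list("tip", NULL)))
}

mouse_skeleton <- function() fixture("skeleton", build_default_mouse_skeleton)

cohort_table <- function() fixture("cohort", function()
  sample_cohort_bone_lengths(80, 4, seed = 7))

shape_prior_fixture <- function() fixture("shape_prior", function()
  fit_shape_prior(cohort_table(), seed = 9))

# pose prior trained on the synthetic gait manifold (small angle jitter)
pose_prior_fixture <- function() fixture("pose_prior", function() {
  sk <- mouse_skeleton()
  poses <- sample_gait_poses(sk, 200, seed = 11)
  suppressWarnings(fit_pose_prior(
    lapply(poses, function(p) forward_kinematics(sk, p)), seed = 5))
})

top_camera <- function() default_camera_rig()$top

# one synthetic single-view gait scene with its true distance
gait_scene <- function(i, noise_sigma_px = 0, occlusion_fraction = 0,
                       jitter_sd = 0) {
  sk <- mouse_skeleton()
  tab <- cohort_table()
  draw <- withr::with_seed(1000L + i,
    list(phase = stats::runif(1, 0, 2 * pi),
         row = sample.int(nrow(tab), 1L)))
  pose <- sample_pose(sk, "gait", phase = draw$phase,
                      bone_lengths = tab[draw$row, ],
                      jitter_sd = jitter_sd, seed = 2000L + i)
  scene <- render_scene(sk, pose, list(top_camera()),
                        noise_sigma_px = noise_sigma_px,
                        occlusion_fraction = occlusion_fraction, seed = i)
  scene$true_distance <- sqrt(sum((camera_center(top_camera()) -
                                     pose$root_translation)^2))
  scene
}

joint_errors_mm <- function(fit, scene) {
  sk <- scene$skeleton
  sqrt(rowSums((unclass(fit$keypoints3d)[sk$joint_names, ] -
                  unclass(scene$true_keypoints)[sk$joint_names, ])^2))
}
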