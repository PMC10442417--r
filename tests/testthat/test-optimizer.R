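noiseless_scene_config <- function(scene, ...) {
  energy_config(scene$true_distance, ...)
}

test_that("the energy matches closed forms and decomposes exactly", {
  sk <- mouse_skeleton()
  scene <- gait_scene(1)
  obs <- scene$observations[[1]]
  cfg0 <- noiseless_scene_config(scene, lambda_pose = 0, lambda_shape = 0)
  e0 <- energy(scene$true_pose, obs, top_camera(), NULL, NULL, sk, cfg0)
  expect_equal(e0$total, 0, tolerance = 1e-12)
  expect_equal(e0$reprojection, 0, tolerance = 1e-12)

  # one keypoint displaced by (3, 4) px adds exactly 25 to the energy
  obs2 <- obs
  obs2["nose", c("u", "v")] <- obs["nose", c("u", "v")] + c(3, 4)
  e1 <- energy(scene$true_pose, obs2, top_camera(), NULL, NULL, sk, cfg0)
  expect_equal(e1$total, 25, tolerance = 1e-9)

  # additivity: each term reported separately, summing to the total
  pp <- pose_prior_fixture(); sp <- shape_prior_fixture()
  cfg1 <- noiseless_scene_config(scene, lambda_pose = 1, lambda_shape = 0.5)
  e2 <- energy(scene$true_pose, obs2, top_camera(), pp, sp, sk, cfg1)
  expect_equal(e2$total,
               e2$reprojection + e2$pose_penalty + e2$shape_penalty,
               tolerance = 1e-9)
  expect_equal(e2$reprojection, 25, tolerance = 1e-9)
  kp <- forward_kinematics(sk, scene$true_pose)
  expect_equal(e2$pose_penalty,
               1 * neg_log_likelihood(pp, flatten_pose(normalize_pose(kp, sk))),
               tolerance = 1e-9)
  expect_equal(e2$shape_penalty,
               0.5 * neg_log_likelihood(sp,
                                        as.numeric(scene$true_pose$bone_lengths)),
               tolerance = 1e-9)
  # ears never contribute: perturbing an ear leaves the energy unchanged
  obs3 <- obs
  obs3["left_ear", c("u", "v")] <- obs["left_ear", c("u", "v")] + c(50, 50)
  expect_equal(energy(scene$true_pose, obs3, top_camera(), NULL, NULL, sk,
                      cfg0)$total, 0, tolerance = 1e-12)
})

test_that("initialization lands near the spine and tracks in-plane rotation", {
  sk <- mouse_skeleton()
  cam <- top_camera()
  pose <- rest_pose(sk, root_translation = c(0, 0, 30))
  D <- sqrt(sum((camera_center(cam) - pose$root_translation)^2))
  obs <- render_scene(sk, pose, list(cam), seed = 1)$observations[[1]]
  cfg <- energy_config(D)
  init <- initialize_pose(obs, cam, sk, cfg, shape_prior_fixture())
  expect_false(attr(init, "fallback"))
  spine <- c("lower_spine", "middle_spine", "upper_spine", "nose")
  uv <- project(cam, unclass(forward_kinematics(sk, init))[spine, ])
  rmse <- sqrt(mean(rowSums((uv - as.matrix(obs[spine, c("u", "v")]))^2)))
  expect_lt(rmse, 5)

  # rotating the observations 90 degrees in the image rotates the initial
  # yaw by 90 degrees about the optical axis
  uv0 <- as.matrix(obs[, c("u", "v")])
  rot90 <- cbind(cam$cx - (uv0[, 2] - cam$cy), cam$cy + (uv0[, 1] - cam$cx))
  rownames(rot90) <- rownames(uv0)
  obs90 <- observed_keypoints2d(rot90, confidence = obs$confidence)
  init90 <- initialize_pose(obs90, cam, sk, cfg, shape_prior_fixture())
  ri <- (3 * sk$root_index - 2):(3 * sk$root_index)
  R0 <- mouselift:::rotvec_to_matrix(init$angles[ri])
  R90 <- mouselift:::rotvec_to_matrix(init90$angles[ri])
  rel <- R90 %*% t(R0)
  angle <- acos(min(1, max(-1, (sum(diag(rel)) - 1) / 2)))
  expect_equal(angle, pi / 2, tolerance = 1e-6)
})

test_that("zero-confidence observations fall back and refuse to optimize", {
  sk <- mouse_skeleton()
  scene <- gait_scene(2)
  obs <- scene$observations[[1]]
  obs$confidence <- rep(0, nrow(obs))
  obs$visible <- rep(FALSE, nrow(obs))
  cfg <- noiseless_scene_config(scene)
  init <- initialize_pose(obs, top_camera(), sk, cfg)
  expect_true(attr(init, "fallback"))
  expect_error(optimize_pose(obs, top_camera(), sk, pose_prior_fixture(),
                             shape_prior_fixture(), cfg),
               "usable keypoints")
})

test_that("the true pose is a fixed point of the reprojection-only fit", {
  sk <- mouse_skeleton()
  scene <- gait_scene(3)
  cfg <- noiseless_scene_config(scene, lambda_pose = 0, lambda_shape = 0)
  fit <- optimize_pose(scene$observations[[1]], top_camera(), sk, NULL, NULL,
                       cfg, initial = scene$true_pose)
  expect_lt(fit$final_reprojection_rmse, 1e-6)
  expect_lt(max(joint_errors_mm(fit, scene)), 1e-6)
})

test_that("accepted energies never increase and match the reported energy", {
  sk <- mouse_skeleton()
  scene <- gait_scene(4, noise_sigma_px = 2, occlusion_fraction = 0.25)
  cfg <- noiseless_scene_config(scene)
  fit <- optimize_pose(scene$observations[[1]], top_camera(), sk,
                       pose_prior_fixture(), shape_prior_fixture(), cfg)
  expect_true(all(diff(fit$energy_trace) <= 1e-9))
  e <- energy(fit$pose, scene$observations[[1]], top_camera(),
              pose_prior_fixture(), shape_prior_fixture(), sk, cfg)
  expect_equal(fit$final_energy, e$total, tolerance = 1e-6)
  expect_setequal(fit$excluded_keypoints,
                  union(scene$occluded_names, c("left_ear", "right_ear")))
})

test_that("a misstated camera distance degrades accuracy smoothly", {
  sk <- mouse_skeleton()
  scene <- gait_scene(5)
  errs <- vapply(c(0.9, 1, 1.1), function(scale) {
    cfg <- energy_config(scale * scene$true_distance)
    fit <- optimize_pose(scene$observations[[1]], top_camera(), sk,
                         pose_prior_fixture(), shape_prior_fixture(), cfg)
    stats::median(joint_errors_mm(fit, scene))
  }, numeric(1))
  expect_true(all(is.finite(errs)))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], errs[3])
  # a 10% distance error shifts the body by roughly that depth, no blow-up
  expect_lt(max(errs), 60)
})

test_that("warm starts hold a constant pose fixed across a sequence", {
  sk <- mouse_skeleton()
  scene <- gait_scene(6)
  frames <- rep(list(scene$observations[[1]]), 4)
  cfg <- noiseless_scene_config(scene)
  fits <- lift_sequence(frames, top_camera(), sk, pose_prior_fixture(),
                        shape_prior_fixture(), cfg)
  kp2 <- unclass(fits[[2]]$keypoints3d)
  for (t in 3:4)
    expect_lt(max(abs(unclass(fits[[t]]$keypoints3d) - kp2)), 1e-6)
})

test_that("a dead frame mid-sequence is isolated and the next recovers", {
  sk <- mouse_skeleton()
  scene <- gait_scene(7)
  dead <- scene$observations[[1]]
  dead$confidence <- rep(0, nrow(dead))
  dead$visible <- rep(FALSE, nrow(dead))
  frames <- list(scene$observations[[1]], dead, scene$observations[[1]])
  cfg <- noiseless_scene_config(scene)
  fits <- lift_sequence(frames, top_camera(), sk, pose_prior_fixture(),
                        shape_prior_fixture(), cfg)
  expect_s3_class(fits[[1]], "pose_fit")
  expect_s3_class(fits[[2]], "lift_failure")
  expect_s3_class(fits[[3]], "pose_fit")
  expect_true(fits[[3]]$converged)
})
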