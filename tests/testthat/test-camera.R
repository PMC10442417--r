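test_that("pinhole projection matches closed forms", {
  cam <- camera_model(fx = 100, fy = 100, cx = 320, cy = 240)
  expect_equal(as.numeric(project(cam, c(0, 0, 50))), c(320, 240))
  cam0 <- camera_model(fx = 100, fy = 100, cx = 0, cy = 0)
  expect_equal(as.numeric(project(cam0, c(10, 0, 100))), c(10, 0))
  expect_error(project(cam0, c(0, 0, -5)), "behind")
})

test_that("zero distortion coefficients equal no distortion", {
  pts <- withr::with_seed(1, matrix(stats::runif(3000, -50, 50), ncol = 3))
  pts[, 3] <- pts[, 3] + 200
  c1 <- camera_model(fx = 500, fy = 510, cx = 320, cy = 240)
  c2 <- camera_model(fx = 500, fy = 510, cx = 320, cy = 240,
                     distortion = numeric(5))
  expect_identical(project(c1, pts), project(c2, pts))
  # and nonzero distortion actually changes off-axis points
  c3 <- camera_model(fx = 500, fy = 510, cx = 320, cy = 240,
                     distortion = c(0.1, 0, 0, 0, 0))
  expect_gt(max(abs(project(c3, pts) - project(c1, pts))), 0.1)
})

test_that("camera model validates intrinsics and rotation", {
  expect_error(camera_model(fx = -1, fy = 1, cx = 0, cy = 0), "positive")
  bad <- diag(c(1, 1, -1))  # reflection
  expect_error(camera_model(fx = 1, fy = 1, cx = 0, cy = 0, rotation = bad),
               "determinant")
})

test_that("triangulation recovers noiseless points and refuses one view", {
  rig <- default_camera_rig()
  pts <- withr::with_seed(2, matrix(stats::runif(30, -40, 40), ncol = 3))
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    obs <- lapply(rig, function(cm) as.numeric(project(cm, p)))
    tri <- triangulate(obs, rig)
    expect_lt(sqrt(sum((tri$point - p)^2)), 1e-6)
    expect_false(tri$ill_conditioned)
  }
  expect_error(triangulate(list(c(0, 0)), rig[1]), "at least 2")
})

test_that("refinement never worsens the DLT reprojection error", {
  rig <- default_camera_rig()
  withr::with_seed(3, {
    for (trial in 1:20) {
      p <- stats::runif(3, -40, 40)
      obs <- lapply(rig, function(cm)
        as.numeric(project(cm, p)) + stats::rnorm(2, 0, 2))
      tri <- triangulate(obs, rig)
      expect_lte(tri$rmse, tri$dlt_rmse + 1e-12)
    }
  })
})

test_that("near-parallel rays are flagged as ill conditioned", {
  cams <- list(look_at_camera(c(0, 0, 400), c(0, 0, 0)),
               look_at_camera(c(1, 0, 400), c(0, 0, 0)))
  p <- c(5, 5, 10)
  obs <- lapply(cams, function(cm) as.numeric(project(cm, p)))
  expect_true(triangulate(obs, cams)$ill_conditioned)
})

test_that("noisy triangulation is close to a brute-force grid oracle", {
  rig <- default_camera_rig()
  p <- c(12, -8, 20)
  h <- 0.5  # oracle grid spacing, mm
  grid1 <- seq(-5, 5, by = h)
  offsets <- as.matrix(expand.grid(x = grid1, y = grid1, z = grid1))
  grid_pts <- sweep(offsets, 2L, -p)
  # projections of all grid points per camera, computed once
  proj_grid <- lapply(rig, function(cm) project(cm, grid_pts))
  tri_err <- oracle_err <- numeric(10)
  withr::with_seed(4, {
    for (trial in 1:10) {
      obs <- lapply(rig, function(cm)
        as.numeric(project(cm, p)) + stats::rnorm(2, 0, 1))
      cost <- Reduce(`+`, Map(function(pg, o)
        (pg[, 1] - o[1])^2 + (pg[, 2] - o[2])^2, proj_grid, obs))
      oracle <- grid_pts[which.min(cost), ]
      tri <- triangulate(obs, rig)
      tri_err[trial] <- sqrt(sum((tri$point - p)^2))
      oracle_err[trial] <- sqrt(sum((oracle - p)^2))
    }
  })
  # the continuous minimizer should do at least as well as the best grid
  # point, up to one grid cell diagonal
  expect_lte(mean(tri_err), mean(oracle_err) + h * sqrt(3))
})

test_that("full multiview keypoint reconstruction handles partial visibility", {
  sk <- mouse_skeleton()
  rig <- default_camera_rig()
  scene <- render_scene(sk, sample_pose(sk, "gait", phase = 0.7), rig,
                        seed = 5)
  rec <- reconstruct_pose_multiview(scene$observations, rig)
  expect_true(all(attr(rec, "valid")))
  expect_lt(max(abs(unclass(rec)[rownames(scene$true_keypoints), ] -
                      unclass(scene$true_keypoints))), 1e-6)

  # knock one keypoint out of all but one view
  obs <- scene$observations
  for (k in 2:3) obs[[k]]["nose", c("confidence", "visible")] <- list(0, FALSE)
  rec2 <- reconstruct_pose_multiview(obs, rig)
  v <- attr(rec2, "valid"); names(v) <- rownames(rec2)
  expect_false(v[["nose"]])
  expect_true(all(v[setdiff(names(v), "nose")]))

  # name-keyed: permuting observation rows permutes nothing semantically
  perm <- lapply(scene$observations, function(o) o[rev(rownames(o)), ])
  rec3 <- reconstruct_pose_multiview(perm, rig)
  expect_equal(unclass(rec3)[rownames(rec), ], unclass(rec),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("calibration files round-trip losslessly and are validated", {
  cam <- look_at_camera(c(450, 0, 60), c(0, 0, 20), fx = 801.5, fy = 799.25,
                        cx = 321.125, cy = 239.5,
                        distortion = c(0.01, -0.002, 1e-4, -2e-4, 0.001),
                        image_size = c(640L, 480L))
  path <- withr::local_tempfile(fileext = ".yaml")
  save_calibration(cam, path)
  cam2 <- load_calibration(path)
  for (f in c("fx", "fy", "cx", "cy", "translation", "distortion"))
    expect_equal(cam2[[f]], cam[[f]], tolerance = 1e-12)
  expect_equal(cam2$rotation, cam$rotation, tolerance = 1e-12)

  # a reflecting rotation must be rejected
  obj <- yaml::read_yaml(path)
  obj$rotation <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, -1))
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(obj, bad)
  expect_error(load_calibration(bad), "rotation")

  # missing distortion block defaults to zeros
  obj2 <- yaml::read_yaml(path)
  obj2$distortion <- NULL
  nodist <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(obj2, nodist)
  expect_equal(load_calibration(nodist)$distortion, numeric(5))
})
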