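test_that("pose normalization pins the spine frame and is idempotent", {
  sk <- mouse_skeleton()
  kp <- forward_kinematics(sk, sample_pose(sk, "gait", phase = 0.9, seed = 2))
  np <- normalize_pose(kp, sk)
  expect_equal(unname(np["upper_spine", ]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(np["middle_spine", ]), c(1, 0, 0), tolerance = 1e-9)
  h <- (np["left_hip", ] + np["right_hip", ]) / 2
  expect_equal(unname(h[2]), 0, tolerance = 1e-9)
  expect_lt(h[3], 0)  # ventral side down, dorsal +z
  np2 <- normalize_pose(unclass(np), sk)
  expect_equal(unclass(np2), unclass(np), tolerance = 1e-9)
})

test_that("pose normalization is invariant to rigid motion and scale", {
  sk <- mouse_skeleton()
  kp <- unclass(forward_kinematics(sk, sample_pose(sk, "gait", phase = 2.4,
                                                   seed = 3)))
  np <- normalize_pose(kp, sk)
  withr::with_seed(4, {
    for (rep in 1:10) {
      Q <- mouselift:::rotvec_to_matrix(stats::rnorm(3))
      s <- stats::runif(1, 0.2, 5)
      t <- stats::rnorm(3, 0, 100)
      moved <- s * kp %*% t(Q) + matrix(t, nrow(kp), 3L, byrow = TRUE)
      rownames(moved) <- rownames(kp)
      expect_equal(unclass(normalize_pose(moved, sk)), unclass(np),
                   tolerance = 1e-9)
    }
  })
})

test_that("degenerate spines are rejected", {
  sk <- mouse_skeleton()
  kp <- unclass(forward_kinematics(sk, rest_pose(sk)))
  kp["middle_spine", ] <- kp["upper_spine", ]
  expect_error(normalize_pose(kp, sk), "degenerate")
})

test_that("single-Gaussian fits are consistent at n = 500", {
  X <- withr::with_seed(5, matrix(stats::rnorm(1000, sd = c(1, 2)),
                                  ncol = 2, byrow = TRUE))
  g <- fit_gmm(X, 1, seed = 6)
  se <- sqrt(diag(stats::cov(X)) / nrow(X))
  expect_lt(max(abs(g$means[1, ] - colMeans(X)) / se), 3)
  S <- stats::cov(X)
  expect_lt(norm(g$covariances[[1]] - S, "F") / norm(S, "F"), 0.2)
})

test_that("well separated clusters are recovered and preconditions hold", {
  X <- withr::with_seed(7, rbind(
    matrix(stats::rnorm(300, 0, 0.02), ncol = 2),
    matrix(stats::rnorm(300, 5, 0.02), ncol = 2)))
  g <- fit_gmm(X, 2, seed = 8)
  means <- g$means[order(g$means[, 1]), ]
  expect_lt(max(abs(means[1, ] - c(0, 0))), 0.1)
  expect_lt(max(abs(means[2, ] - c(5, 5))), 0.1)
  expect_error(fit_gmm(X[1:3, ], 5, seed = 1), "at least")
})

test_that("fits are bit-reproducible under a fixed seed", {
  X <- withr::with_seed(9, matrix(stats::rnorm(400), ncol = 4))
  g1 <- fit_gmm(X, 3, seed = 10)
  g2 <- fit_gmm(X, 3, seed = 10)
  expect_identical(g1$weights, g2$weights)
  expect_identical(g1$means, g2$means)
  expect_identical(g1$covariances, g2$covariances)
})

test_that("the mixture NLL matches closed forms and its lower bound", {
  std_normal <- structure(list(
    n_components = 1L, weights = 1, means = matrix(0, 1, 1),
    covariances = list(matrix(1, 1, 1)), dimension = 1L,
    fit_seed = 0L, loglik = NA_real_, floors = NULL, var_names = NULL),
    class = "gmm_prior")
  expect_equal(neg_log_likelihood(std_normal, 0), 0.5 * log(2 * pi),
               tolerance = 1e-9)
  # the mean is the mode
  for (d in c(-2, -0.5, 0.3, 4))
    expect_gt(neg_log_likelihood(std_normal, d),
              neg_log_likelihood(std_normal, 0))
  # symmetric two-component mixture scores its two means equally
  mix <- structure(list(
    n_components = 2L, weights = c(0.5, 0.5),
    means = matrix(c(-3, 3), 2, 1),
    covariances = list(matrix(1, 1, 1), matrix(1, 1, 1)), dimension = 1L,
    fit_seed = 0L, loglik = NA_real_, floors = NULL, var_names = NULL),
    class = "gmm_prior")
  expect_equal(neg_log_likelihood(mix, -3), neg_log_likelihood(mix, 3),
               tolerance = 1e-12)
  # bound holds everywhere
  b <- nll_lower_bound(mix)
  for (x in seq(-6, 6, by = 0.5))
    expect_gte(neg_log_likelihood(mix, x), b - 1e-12)
  expect_error(neg_log_likelihood(mix, c(1, 2)), "dimension")
})

test_that("the pose prior ranks gait poses far below random poses", {
  sk <- mouse_skeleton()
  pp <- pose_prior_fixture()
  expect_equal(pp$n_components, 5L)
  expect_equal(pp$dimension, 54L)
  wins <- 0L
  for (i in 1:20) {
    gait <- flatten_pose(normalize_pose(forward_kinematics(
      sk, sample_pose(sk, "gait", phase = i / 20 * 2 * pi,
                      seed = 300 + i, jitter_sd = 0.05)), sk))
    rand <- flatten_pose(normalize_pose(forward_kinematics(
      sk, sample_pose(sk, "random", seed = 400 + i)), sk))
    wins <- wins + (neg_log_likelihood(pp, gait) <
                      neg_log_likelihood(pp, rand))
  }
  expect_equal(wins, 20L)
  expect_error(fit_pose_prior(list(), seed = 1), "at least")
})

test_that("the pose prior is invariant to rigid motion of its training set", {
  sk <- mouse_skeleton()
  poses <- lapply(1:12, function(i) unclass(forward_kinematics(
    sk, sample_pose(sk, "gait", phase = i / 2, seed = i, jitter_sd = 0.03))))
  Q <- mouselift:::rotvec_to_matrix(c(0.4, -0.1, 0.8))
  moved <- lapply(poses, function(kp) {
    m <- 2.5 * kp %*% t(Q) + matrix(c(30, -10, 5), nrow(kp), 3, byrow = TRUE)
    rownames(m) <- rownames(kp); m
  })
  p1 <- suppressWarnings(fit_pose_prior(poses, seed = 21))
  p2 <- suppressWarnings(fit_pose_prior(moved, seed = 21))
  probe <- flatten_pose(normalize_pose(poses[[3]], sk))
  expect_equal(neg_log_likelihood(p1, probe), neg_log_likelihood(p2, probe),
               tolerance = 1e-6)
})

test_that("the shape prior prefers cohort means over rescaled bodies", {
  tab <- cohort_table()
  sp <- shape_prior_fixture()
  expect_equal(sp$n_components, 7L)
  groups <- attr(tab, "group")
  for (g in unique(groups)) {
    gm <- colMeans(tab[groups == g, , drop = FALSE])
    expect_lt(neg_log_likelihood(sp, gm), neg_log_likelihood(sp, 2 * gm))
  }
  bad <- tab; bad[1, 1] <- -5
  expect_error(fit_shape_prior(bad, seed = 1), "positive")
  expect_error(fit_shape_prior(tab[1:5, ], seed = 1), "at least")
})

test_that("priors serialize to JSON and back without changing the density", {
  sp <- shape_prior_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  save_prior(sp, path)
  sp2 <- load_prior(path)
  probes <- cohort_table()[c(1, 25, 60), ]
  expect_equal(neg_log_likelihood(sp2, probes), neg_log_likelihood(sp, probes),
               tolerance = 1e-9)
  expect_equal(sp2$weights, sp$weights, tolerance = 1e-12)
})

test_that("an agreeing mixture fit is found by an independent EM (mclust)", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust dispatches to unexported helpers
  X <- withr::with_seed(11, rbind(
    matrix(stats::rnorm(400, 0, 0.5), ncol = 2),
    matrix(stats::rnorm(400, 6, 0.5), ncol = 2),
    matrix(stats::rnorm(400, c(0, 6), 0.5), ncol = 2, byrow = TRUE)))
  ours <- fit_gmm(X, 3, seed = 12)
  ref <- mclust::Mclust(X, G = 3, modelNames = "VVV", verbose = FALSE)
  ord_ours <- order(ours$means[, 1], ours$means[, 2])
  ord_ref <- order(t(ref$parameters$mean)[, 1], t(ref$parameters$mean)[, 2])
  expect_equal(ours$means[ord_ours, ],
               unname(t(ref$parameters$mean)[ord_ref, ]), tolerance = 0.1)
  expect_equal(sort(ours$weights), sort(ref$parameters$pro), tolerance = 0.05)
})
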