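test_that("posterior mean/SD match the explicit small-matrix formulas", {
  ages <- c(25, 40, 55, 70, 85)
  sexes <- c(0, 1, 0, 1, 0)
  y <- c(5.2, 4.9, 4.8, 4.3, 4.1)
  theta <- log(c(0.5, 1.0, 0.7, 0.4, 0.1))
  m <- fitNormativeModel(y, ages, sexes,
                         normativeConfig(fixed_theta = theta), seed = 1)
  q_age <- c(30, 50, 80); q_sex <- c(1, 0, 0)
  pr <- predictNorm(m, q_age, q_sex)
  or <- gpOracle(theta, ages, sexes, y, q_age, q_sex)
  expect_equal(pr$mean, or$mean, tolerance = 1e-8)
  expect_equal(pr$sd, or$sd, tolerance = 1e-8)
})

test_that("a noiseless linear feature is interpolated to within 1e-3", {
  withr::with_seed(2, {
    ages <- runif(50, 20, 80)
    sexes <- rbinom(50, 1, 0.5)
    y <- 4 - 0.02 * ages
    m <- fitNormativeModel(y, ages, sexes, seed = 1)
    q <- c(25, 45, 70)
    pr <- predictNorm(m, q, c(0, 1, 0))
    expect_lt(max(abs(pr$mean - (4 - 0.02 * q))), 1e-3)
  })
})

test_that("constant and near-constant features behave sensibly", {
  ages <- seq(20, 80, length.out = 20)
  sexes <- rep(c(0, 1), 10)
  m0 <- fitNormativeModel(rep(3.3, 20), ages, sexes, seed = 1)
  expect_true(m0$degenerate)
  z <- suppressWarnings(predictNorm(m0, 50, 0))
  expect_equal(z$mean, 3.3)

  withr::with_seed(3, y <- 3.3 + rnorm(20, 0, 1e-3))
  m1 <- fitNormativeModel(y, ages, sexes, seed = 1)
  pr <- predictNorm(m1, 50, 0)
  expect_equal(pr$mean, 3.3, tolerance = 0.01)
  expect_lt(abs((3.3 - pr$mean) / pr$sd), 0.5)
})

test_that("refitting under the same seed yields identical hyperparameters", {
  withr::with_seed(4, {
    ages <- runif(60, 20, 85)
    sexes <- rbinom(60, 1, 0.5)
    y <- 5 - 0.03 * ages + 0.2 * sexes + rnorm(60, 0, 0.3)
  })
  m1 <- fitNormativeModel(y, ages, sexes, seed = 7)
  m2 <- fitNormativeModel(y, ages, sexes, seed = 7)
  expect_identical(m1$theta, m2$theta)
})

test_that("predictive uncertainty grows away from the training support", {
  withr::with_seed(5, {
    ages <- runif(80, 35, 60)
    sexes <- rbinom(80, 1, 0.5)
    y <- 5 - 0.03 * ages + rnorm(80, 0, 0.2)
  })
  m <- fitNormativeModel(y, ages, sexes, seed = 1)
  inside <- predictNorm(m, 47, 0)
  expect_warning(outside <- predictNorm(m, 95, 0), "outside")
  expect_true(outside$extrapolated)
  expect_false(inside$extrapolated)
  expect_gt(outside$sd, inside$sd)
})

test_that("Z-scores follow their definition and name missing models", {
  traj <- smallTrajectory()
  pop <- simulateNormativePopulation(120, traj, seed = 6)
  norms <- fitNormativeModelSet(pop$gm, normativeConfig(restarts = 1),
                                seed = 2)
  pd <- participantData(pop$gm)
  z <- computeZScores(norms, pop$gm)
  # rebuild one column from predictNorm directly
  f <- norms@features[1]
  pr <- predictNorm(norms@models[[f]], pd$age, pd$sex)
  expect_equal(z[, f], (featureValues(pop$gm)[, f] - pr$mean) / pr$sd)
  # observed == mean -> 0; mean + 2 sd -> 2
  synth <- featureValues(pop$gm)
  synth[, f] <- pr$mean + 2 * pr$sd
  ft2 <- FeatureTable(synth, featureDescriptors(pop$gm), pd)
  z2 <- computeZScores(norms, ft2)
  expect_equal(unname(z2[, f]), rep(2, 120))

  wm_sub <- simulateNormativePopulation(30, traj, seed = 7)$wm
  first_wm <- featureDescriptors(wm_sub)$name[1]
  expect_error(computeZScores(norms, wm_sub), first_wm, fixed = TRUE)
})

test_that("focal deviance is recovered while other features stay near zero", {
  traj <- smallTrajectory(8, 4)
  ref <- simulateNormativePopulation(250, traj, seed = 8)
  norms <- fitNormativeModelSet(ref$gm, seed = 3)
  target <- traj$gm$name[3]
  coh <- simulateClinicalCohort(
    clinicalCohortConfig("MSA", n = 200, pad_shift = 0, jitter_sd = 0,
                         deviant_features = setNames(2, target),
                         seed = 9),
    trajectory = traj)
  z <- suppressWarnings(computeZScores(norms, coh$gm))
  expect_gt(mean(z[, target]), 1.6)
  expect_lt(mean(z[, target]), 2.4)
  others <- setdiff(colnames(z), target)
  expect_true(all(abs(colMeans(z[, others])) < 0.3))
})

test_that("a serialized model set restores to identical Z-scores", {
  traj <- smallTrajectory(4, 4)
  pop <- simulateNormativePopulation(80, traj, seed = 10)
  norms <- fitNormativeModelSet(pop$wm, normativeConfig(restarts = 1),
                                seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  writeNormativeModelSet(norms, f)
  norms2 <- readNormativeModelSet(f)
  z1 <- computeZScores(norms, pop$wm)
  z2 <- computeZScores(norms2, pop$wm)
  expect_equal(z1, z2, tolerance = 1e-10)
})
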