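test_that("generated panels have the contracted shapes, ranges and domains", {
  pop <- simulateNormativePopulation(80, seed = 1)
  expect_s4_class(pop$gm, "FeatureTable")
  expect_equal(dim(featureValues(pop$gm)), c(80, 124))
  expect_equal(dim(featureValues(pop$wm)), c(80, 90))
  expect_equal(as.integer(table(featureDescriptors(pop$gm)$modality)[
    c("GM_volume", "GM_thickness")]), c(56L, 68L))
  expect_equal(as.integer(table(featureDescriptors(pop$wm)$modality)[
    c("WM_GFA", "WM_MD")]), c(45L, 45L))
  ages <- participantData(pop$gm)$age
  expect_true(all(ages >= 14 & ages <= 92))
  gfa <- featureValues(pop$wm)[, featureDescriptors(pop$wm)$modality ==
                                 "WM_GFA"]
  expect_true(all(gfa > 0 & gfa < 1))
  md <- featureValues(pop$wm)[, featureDescriptors(pop$wm)$modality ==
                                "WM_MD"]
  expect_true(all(md > 0))
  expect_true(all(featureValues(pop$gm)[,
    featureDescriptors(pop$gm)$modality == "GM_volume"] > 0))
})

test_that("identical seeds reproduce cohorts bit for bit, n = 0 is legal", {
  a <- simulateNormativePopulation(40, seed = 7)
  b <- simulateNormativePopulation(40, seed = 7)
  expect_identical(featureValues(a$gm), featureValues(b$gm))
  expect_identical(a$participants, b$participants)
  c2 <- simulateNormativePopulation(40, seed = 8)
  expect_false(identical(featureValues(a$gm), featureValues(c2$gm)))

  empty <- simulateNormativePopulation(0, seed = 1)
  expect_equal(nrow(empty$participants), 0L)
  expect_equal(dim(featureValues(empty$gm)), c(0L, 124L))
})

test_that("noiseless cohorts land exactly on the trajectory means", {
  cfg <- defaultTrajectoryConfig()
  cfg$gm$sigma[] <- 0; cfg$wm$sigma[] <- 0
  pop <- simulateNormativePopulation(10, cfg, seed = 7)
  pd <- pop$participants
  mu <- brainpad:::.trajectoryMean(cfg$gm, pd$age,
                                   as.numeric(pd$sex == "male"),
                                   cfg$ref_age)
  expect_equal(featureValues(pop$gm), mu, ignore_attr = TRUE)

  shifted <- simulateClinicalCohort(
    clinicalCohortConfig("MSA", n = 10, pad_shift = 9, jitter_sd = 0,
                         seed = 7),
    trajectory = cfg)
  pd2 <- shifted$participants
  mu9 <- brainpad:::.trajectoryMean(cfg$gm, pd2$age + 9,
                                    as.numeric(pd2$sex == "male"),
                                    cfg$ref_age)
  expect_equal(featureValues(shifted$gm), mu9, ignore_attr = TRUE)
  expect_equal(pd2$true_offset, rep(9, 10))
})

test_that("a null clinical config reproduces the normative draws", {
  cfg <- smallTrajectory()
  pop <- simulateNormativePopulation(25, cfg, seed = 42)
  null_cfg <- clinicalCohortConfig(
    "HC", n = 25, pad_shift = 0, jitter_sd = 0,
    age_mean = cfg$age_mean, age_sd = cfg$age_sd,
    education_mean = 12, education_sd = 4, clinical = list(), seed = 42)
  coh <- simulateClinicalCohort(null_cfg, cfg)
  expect_equal(unname(featureValues(coh$gm)),
               unname(featureValues(pop$gm)))
  expect_equal(coh$participants$age, pop$participants$age)
  expect_equal(coh$participants$sex, pop$participants$sex)
})

test_that("empirical residual SD matches the configured noise within 5%", {
  cfg <- smallTrajectory(8, 8)
  pop <- simulateNormativePopulation(2000, cfg, seed = 5)
  pd <- pop$participants
  sex_num <- as.numeric(pd$sex == "male")
  for (tag in c("gm", "wm")) {
    mu <- brainpad:::.trajectoryMean(cfg[[tag]], pd$age, sex_num,
                                     cfg$ref_age)
    res <- featureValues(pop[[tag]]) - mu
    ratio <- apply(res, 2, sd) / cfg[[tag]]$sigma
    expect_true(all(abs(ratio - 1) < 0.05))
  }
})

test_that("larger injected offsets shift age-declining features monotonically", {
  cfg <- smallTrajectory()
  cfg$gm$sigma[] <- 0; cfg$wm$sigma[] <- 0
  means <- sapply(c(0, 5, 10), function(shift) {
    coh <- simulateClinicalCohort(
      clinicalCohortConfig("MSA", n = 30, pad_shift = shift, jitter_sd = 0,
                           seed = 11),
      trajectory = cfg)
    colMeans(featureValues(coh$gm))
  })
  declining <- cfg$gm$beta1 < 0
  expect_true(all(diff(t(means[declining, , drop = FALSE])) < 0))
})

test_that("clinical scores track the realized offset at the configured strength", {
  coh <- simulateClinicalCohort(
    clinicalCohortConfig("MSA", n = 2000, pad_shift = 9, seed = 3),
    trajectory = smallTrajectory())
  p <- coh$participants
  expect_equal(cor(p$UPDRS_total, p$true_offset), 0.4, tolerance = 0.15)
  expect_lt(cor(p$MoCA, p$true_offset), 0)  # cognition couples negatively
})

test_that("invalid generator configs fail with descriptive errors", {
  cfg <- smallTrajectory()
  bad <- cfg; bad$gm$sigma[2] <- -1
  expect_error(simulateNormativePopulation(5, bad, seed = 1),
               "negative sigma")
  expect_error(
    simulateClinicalCohort(
      clinicalCohortConfig("MSA", n = 5,
                           deviant_features = c("No Such Region" = 2),
                           seed = 1),
      trajectory = cfg),
    "No Such Region")
})

test_that("cohort files round-trip losslessly and fail loudly when malformed", {
  coh <- simulateClinicalCohort(
    clinicalCohortConfig("PD", n = 8, pad_shift = 2, seed = 9),
    trajectory = smallTrajectory())
  d <- withr::local_tempdir()
  writeCohort(coh, d)
  back <- readCohort(d)
  expect_equal(unname(featureValues(back$gm)),
               unname(featureValues(coh$gm)))
  expect_equal(back$participants$age, coh$participants$age)
  expect_equal(back$participants$UPDRS_total, coh$participants$UPDRS_total)
  expect_equal(featureDescriptors(back$wm), featureDescriptors(coh$wm))

  # missing feature column is named
  gm <- read.csv(file.path(d, "gm.csv"), check.names = FALSE)
  dropped <- colnames(gm)[3]
  write.csv(gm[, -3], file.path(d, "gm.csv"), row.names = FALSE)
  expect_error(readCohort(d), dropped, fixed = TRUE)

  # non-numeric cell is located by row and column
  writeCohort(coh, d)
  gm <- read.csv(file.path(d, "gm.csv"), check.names = FALSE)
  gm[4, 2] <- "oops"
  write.csv(gm, file.path(d, "gm.csv"), row.names = FALSE)
  err <- tryCatch(readCohort(d), error = conditionMessage)
  expect_match(err, "row 4")
  expect_match(err, colnames(gm)[2], fixed = TRUE)
})
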