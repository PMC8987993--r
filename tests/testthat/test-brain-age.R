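test_that("prediction metrics match hand-computed values", {
  expect_equal(evaluatePredictions(c(10, 20, 30), c(10, 20, 30)),
               list(r = 1, mae = 0))
  expect_equal(evaluatePredictions(c(12, 22, 32), c(10, 20, 30)),
               list(r = 1, mae = 2))
  # (3,1,2) vs (1,2,3): deviations (1,-1,0) and (-1,0,1),
  # r = -0.5, MAE = (2+1+1)/3
  ev <- evaluatePredictions(c(3, 1, 2), c(1, 2, 3))
  expect_equal(ev$r, -0.5)
  expect_equal(ev$mae, 4 / 3)
  expect_error(evaluatePredictions(1:3, 1:4), "equal length")
  expect_warning(evaluatePredictions(c(1, 2, 3), c(5, 5, 5)),
                 "zero variance")
})

test_that("a constant network predicts its output bias everywhere", {
  m <- constantModel(b = 42.5, p = 3)
  X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, m@inputNames))
  expect_equal(predictAge(m, X, c(0, 1, 0, 1)), rep(42.5, 4))
})

test_that("prediction is a pure function: duplicated rows, strict name checks", {
  co <- linearAgeCohort(n = 60, p = 5, seed = 3)
  m <- trainBrainAgeModel(co$X, co$age, co$sex,
                          tinyHyper(layers = 2, width = 4, epochs = 150),
                          seed = 1, modality = "custom")
  Xdup <- co$X[c(1, 1, 2, 2), ]
  p <- predictAge(m, Xdup, co$sex[c(1, 1, 2, 2)])
  expect_equal(p[1], p[2])
  expect_equal(p[3], p[4])

  Xbad <- co$X; colnames(Xbad)[1] <- "not_a_feature"
  err <- tryCatch(predictAge(m, Xbad, co$sex), error = conditionMessage)
  expect_match(err, "f01")           # missing name is listed
  expect_match(err, "not_a_feature") # extra name is listed
})

test_that("training is deterministic under a fixed seed", {
  co <- linearAgeCohort(n = 80, p = 6, seed = 2)
  hp <- tinyHyper(layers = 2, width = 4, epochs = 100)
  m1 <- trainBrainAgeModel(co$X, co$age, co$sex, hp, seed = 5,
                           modality = "custom")
  m2 <- trainBrainAgeModel(co$X, co$age, co$sex, hp, seed = 5,
                           modality = "custom")
  expect_identical(m1@weights, m2@weights)
  m3 <- trainBrainAgeModel(co$X, co$age, co$sex, hp, seed = 6,
                           modality = "custom")
  expect_false(identical(m1@weights, m3@weights))
})

test_that("the cascade reaches sub-half-year error on noiseless linear data", {
  co <- linearAgeCohort(n = 400, p = 15, seed = 4)
  tr <- 1:300; te <- 301:400
  m <- trainBrainAgeModel(co$X[tr, ], co$age[tr], co$sex[tr],
                          tinyHyper(layers = 4, width = 8, epochs = 1500,
                                    patience = 500),
                          seed = 2, modality = "custom")
  pred <- predictAge(m, co$X[te, ], co$sex[te])
  expect_lt(mean(abs(pred - co$age[te])), 0.5)
})

test_that("predictions are invariant to affine rescaling of the inputs", {
  co <- linearAgeCohort(n = 100, p = 5, seed = 6)
  hp <- tinyHyper(layers = 2, width = 4, epochs = 120)
  m1 <- trainBrainAgeModel(co$X, co$age, co$sex, hp, seed = 3,
                           modality = "custom")
  scale_ <- runif(5, 0.5, 20); shift <- rnorm(5, 0, 100)
  X2 <- sweep(sweep(co$X, 2, scale_, "*"), 2, shift, "+")
  m2 <- trainBrainAgeModel(X2, co$age, co$sex, hp, seed = 3,
                           modality = "custom")
  expect_equal(predictAge(m1, co$X, co$sex), predictAge(m2, X2, co$sex),
               tolerance = 1e-8)
})

test_that("training rejects malformed inputs and modality mismatches", {
  co <- linearAgeCohort(n = 40, p = 5, seed = 1)
  hp <- tinyHyper(layers = 2, width = 2, epochs = 10)
  Xna <- co$X; Xna[1, 1] <- NA
  expect_error(trainBrainAgeModel(Xna, co$age, co$sex, hp, seed = 1,
                                  modality = "custom"), "finite")
  expect_error(trainBrainAgeModel(co$X[1:5, ], co$age[1:5], co$sex[1:5],
                                  hp, seed = 1, modality = "custom"),
               "at least")
  expect_error(trainBrainAgeModel(co$X, co$age, co$sex, hp, seed = 1,
                                  modality = "GM"), "124")
  expect_error(trainBrainAgeModel(co$X, co$age, co$sex, hp, seed = 1,
                                  modality = "WM"), "90")
})

test_that("cross-validation folds partition the sample; perfect features give r ~ 1", {
  co <- linearAgeCohort(n = 100, p = 4, seed = 8)
  cv <- crossValidate(co$X, co$age, co$sex, k = 10,
                      hyperparams = tinyHyper(layers = 2, width = 4,
                                              epochs = 250),
                      seed = 4, modality = "custom")
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_true(all(table(cv$folds) == 10))
  expect_gt(cv$r, 0.99)
  expect_lt(cv$mae, 1.5)
  expect_error(crossValidate(co$X, co$age, co$sex, k = 101,
                             modality = "custom"), "exceed")
})

test_that("leave-one-out cross-validation runs and pools its metrics", {
  co <- linearAgeCohort(n = 14, p = 2, seed = 9)
  cv <- crossValidate(co$X, co$age, co$sex, k = 14,
                      hyperparams = tinyHyper(layers = 1, width = 2,
                                              epochs = 60),
                      seed = 1, modality = "custom")
  expect_true(all(table(cv$folds) == 1))
  expect_true(is.finite(cv$r) && is.finite(cv$mae))
})

test_that("a serialized model restores to identical predictions", {
  co <- linearAgeCohort(n = 60, p = 5, seed = 10)
  m <- trainBrainAgeModel(co$X, co$age, co$sex,
                          tinyHyper(layers = 2, width = 3, epochs = 80),
                          seed = 2, modality = "custom")
  f <- withr::local_tempfile(fileext = ".json")
  writeBrainAgeModel(m, f)
  m2 <- readBrainAgeModel(f)
  expect_equal(predictAge(m2, co$X, co$sex), predictAge(m, co$X, co$sex))
})
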