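# shared fixtures: small nets and cohorts keep the unit tests fast;
# full-scale study conditions live in test-acceptance.R

tinyHyper <- function(layers = 3, width = 6, epochs = 400, patience = 150)
  brainAgeHyperparams(layers = layers, width = width, epochs = epochs,
                      patience = patience, min_n = 10)

# cohort whose age is an exact linear function of the features
linearAgeCohort <- function(n = 300, p = 15, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    beta <- rnorm(p)
    age <- 50 + drop(X %*% beta) * 15 / sd(drop(X %*% beta))
    sex <- rbinom(n, 1, 0.5)
    list(X = X, age = age, sex = sex, beta = beta)
  })
}

# a trajectory config restricted to a few features per panel (keeps GP and
# generator tests light while exercising the real descriptor structure)
smallTrajectory <- function(gm_k = 6, wm_k = 6) {
  cfg <- defaultTrajectoryConfig()
  cfg$gm <- cfg$gm[seq_len(gm_k), ]
  cfg$wm <- cfg$wm[seq_len(wm_k), ]
  cfg
}

# explicit GP posterior for a handful of points: k*' (K + s2n I)^-1 y etc.
# computed with dense linear algebra, mirroring the model's definition on
# its standardized scales
gpOracle <- function(theta, ages, sexes, y, q_age, q_sex) {
  a_c <- mean(ages); a_s <- sd(ages)
  y_c <- mean(y); y_s <- sd(y)
  a <- (ages - a_c) / a_s; aq <- (q_age - a_c) / a_s
  s2f <- exp(theta[1]); la <- exp(theta[2]); ls <- exp(theta[3])
  s2l <- exp(theta[4]); s2n <- exp(theta[5])
  k <- function(a1, s1, a2, s2)
    s2f * exp(-0.5 * ((a1 - a2)^2 / la^2 + (s1 - s2)^2 / ls^2)) +
      s2l * a1 * a2
  n <- length(a)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) k(a[i], sexes[i], a[j], sexes[j]))) +
    diag(s2n, n)
  ys <- (y - y_c) / y_s
  m <- length(aq)
  Ks <- outer(seq_len(n), seq_len(m),
              Vectorize(function(i, j) k(a[i], sexes[i], aq[j], q_sex[j])))
  Kinv <- solve(K)
  mu <- drop(t(Ks) %*% Kinv %*% ys)
  var_ <- vapply(seq_len(m), function(j)
    k(aq[j], q_sex[j], aq[j], q_sex[j]) + s2n -
      drop(t(Ks[, j]) %*% Kinv %*% Ks[, j]), numeric(1))
  list(mean = y_c + y_s * mu, sd = y_s * sqrt(var_))
}

# a BrainAgeModel that ignores its inputs and predicts a constant
constantModel <- function(b, p = 3) {
  feats <- sprintf("f%02d", seq_len(p))
  w <- brainpad:::.cascadeInit(p + 1, 2, 2)
  for (k in seq_along(w$hidden)) {
    w$hidden[[k]]$W[] <- 0
    w$hidden[[k]]$b[] <- 0
  }
  w$wo[] <- 0
  w$bo <- b
  methods::new("BrainAgeModel", modality = "custom", inputNames = feats,
               center = rep(0, p + 1), scale = rep(1, p + 1),
               yCenter = 0, yScale = 1, weights = w,
               hyperparams = brainAgeHyperparams(layers = 2, width = 2),
               metadata = list(seed = 0L, epochs_run = 0L))
}
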