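#' @include descriptors.R
NULL

# deterministic low-discrepancy spread in [0,1] used to vary baselines
# across regions without randomness
.spread <- function(i) (i * 0.6180339887498949) %% 1

.volumeBaseline <- function(names_) {
  base <- 6 + 16 * .spread(seq_along(names_))
  base[grepl("Cerebellum", names_)] <- 110
  base[grepl("Brainstem", names_)] <- 25
  base[grepl("Caudate", names_)] <- 4
  base[grepl("Putamen", names_)] <- 4.5
  base[grepl("Hippocampus", names_)] <- 3.5
  base
}

#' Default per-feature aging-trajectory configuration
#'
#' Defines the generative model of the synthetic cohorts: each feature
#' follows `mu(age, sex) = beta0 + beta1 * (age - ref_age) +
#' beta2 * (age - ref_age)^2 + beta_sex * sex` with additive Gaussian noise
#' of SD `sigma` (sex coded female = 0, male = 1). Default signs follow
#' biology: volumes, cortical thickness and GFA decline with age
#' (`beta1 < 0`), MD rises (`beta1 > 0`). Baselines vary deterministically
#' across regions within plausible physiological ranges (volumes in mL,
#' thickness in mm, GFA in (0,1), MD in 1e-3 mm^2/s).
#'
#' The reference population's age distribution defaults to a truncated
#' normal with mean 36.9, SD 19.1 on [14, 92] and 46.9% males.
#'
#' @param gm,wm descriptor data.frames (defaults:
#'   [gmFeatureDescriptors()], [wmFeatureDescriptors()]).
#' @return list with elements `gm` and `wm` (descriptor columns plus
#'   `beta0`, `beta1`, `beta2`, `beta_sex`, `sigma`), `ref_age`, and the
#'   age-distribution parameters `age_min`, `age_max`, `age_mean`,
#'   `age_sd`, `p_male`.
#' @examples
#' cfg <- defaultTrajectoryConfig()
#' head(cfg$gm[, c("name", "beta0", "beta1", "sigma")])
#' @export
defaultTrajectoryConfig <- function(gm = gmFeatureDescriptors(),
                                    wm = wmFeatureDescriptors()) {
  traj <- function(desc) {
    n <- nrow(desc)
    out <- desc
    out$beta0 <- NA_real_; out$beta1 <- NA_real_; out$beta2 <- 0
    out$beta_sex <- NA_real_; out$sigma <- NA_real_
    for (mod in unique(desc$modality)) {
      i <- which(desc$modality == mod)
      f <- .spread(seq_along(i))
      switch(mod,
        GM_volume = {
          b0 <- .volumeBaseline(desc$name[i])
          out$beta0[i] <- b0
          out$beta1[i] <- -0.0025 * b0
          out$beta_sex[i] <- 0.06 * b0
          out$sigma[i] <- 0.05 * b0
        },
        GM_thickness = {
          out$beta0[i] <- 2.2 + 0.7 * f
          out$beta1[i] <- -0.004
          out$beta_sex[i] <- -0.02
          out$sigma[i] <- 0.08
        },
        WM_GFA = {
          out$beta0[i] <- 0.35 + 0.2 * f
          out$beta1[i] <- -0.0008
          out$beta_sex[i] <- 0.008
          out$sigma[i] <- 0.015
        },
        WM_MD = {
          out$beta0[i] <- 0.70 + 0.15 * f
          out$beta1[i] <- 0.0015
          out$beta_sex[i] <- -0.004
          out$sigma[i] <- 0.025
        },
        stop("unknown modality: ", mod))
    }
    out
  }
  list(gm = traj(gm), wm = traj(wm),
       ref_age = 45,
       age_min = 14, age_max = 92, age_mean = 36.9, age_sd = 19.1,
       p_male = 0.469)
}

.validateTrajectoryConfig <- function(config) {
  .assert(is.list(config) && all(c("gm", "wm", "ref_age") %in% names(config)),
          "trajectory config must contain 'gm', 'wm' and 'ref_age'")
  for (tag in c("gm", "wm")) {
    tr <- config[[tag]]
    need <- c("name", "modality", "region_group", "hemisphere",
              "beta0", "beta1", "beta2", "beta_sex", "sigma")
    miss <- setdiff(need, colnames(tr))
    .assert(length(miss) == 0L, "trajectory table '%s' lacks column(s): %s",
            tag, paste(miss, collapse = ", "))
    .assert(!anyDuplicated(tr$name), "duplicate feature names in '%s'", tag)
    .assert(all(tr$sigma >= 0), "negative sigma for feature(s): %s",
            paste(tr$name[tr$sigma < 0], collapse = ", "))
    .checkFinite(tr$beta0, "beta0"); .checkFinite(tr$beta1, "beta1")
  }
  .assert(config$age_min < config$age_max, "age_min must be < age_max")
  invisible(TRUE)
}

# mu(age, sex) for every feature: returns participants x features matrix
.trajectoryMean <- function(traj, ages, sex_num, ref_age) {
  a <- ages - ref_age
  m <- outer(a, traj$beta1) + outer(a^2, traj$beta2) +
    outer(sex_num, traj$beta_sex)
  m <- sweep(m, 2, traj$beta0, "+")
  colnames(m) <- traj$name
  m
}
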