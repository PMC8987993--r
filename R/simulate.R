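#' @include trajectories.R featureTable.R
NULL

# truncated-normal sampler (simple rejection; acceptance is high for all
# configurations used here)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# keep generated values inside their physical domain; with the default
# noise levels these bounds are essentially never active
.clampToDomain <- function(values, traj) {
  for (mod in unique(traj$modality)) {
    j <- which(traj$modality == mod)
    if (mod == "WM_GFA") {
      values[, j] <- pmin(pmax(values[, j], 1e-4), 1 - 1e-4)
    } else if (mod %in% c("GM_volume", "WM_MD")) {
      values[, j] <- pmax(values[, j], 1e-6)
    }
  }
  values
}

.simulateCohort <- function(n, trajectory, seed, group,
                            age_mean, age_sd, education_mean, education_sd,
                            id_prefix, pad_shift = NULL, jitter_sd = 0,
                            deviant_features = NULL, clinical = NULL) {
  .validateTrajectoryConfig(trajectory)
  .assert(n >= 0, "n must be non-negative")
  if (!is.null(deviant_features)) {
    known <- c(trajectory$gm$name, trajectory$wm$name)
    bad <- setdiff(names(deviant_features), known)
    .assert(length(bad) == 0L,
            "deviant feature(s) not in descriptor list: %s",
            paste(bad, collapse = ", "))
  }
  withr::with_seed(seed, {
    ages <- .rtruncnorm(n, age_mean, age_sd, trajectory$age_min,
                        trajectory$age_max)
    sex_num <- stats::rbinom(n, 1L, trajectory$p_male)
    education <- round(pmax(.rtruncnorm(n, education_mean, education_sd,
                                        0, 25), 0), 1)
    tables <- list()
    noise <- list()
    for (tag in c("gm", "wm")) {
      tr <- trajectory[[tag]]
      noise[[tag]] <- sweep(matrix(stats::rnorm(n * nrow(tr)), n, nrow(tr)),
                            2, tr$sigma, "*")
    }
    delta <- rep(0, n)
    if (!is.null(pad_shift)) delta <- pad_shift + stats::rnorm(n, 0, jitter_sd)
    participants <- data.frame(
      id = sprintf("%s%04d", id_prefix, seq_len(n)),
      age = ages,
      sex = c("female", "male")[sex_num + 1L],
      education = education,
      group = rep(group, n),
      true_offset = delta,
      stringsAsFactors = FALSE)
    if (!is.null(clinical) && length(clinical) && n > 0) {
      zd <- if (jitter_sd > 0) (delta - pad_shift) / jitter_sd else rep(0, n)
      for (score in names(clinical)) {
        cs <- clinical[[score]]
        rho <- cs[["coupling"]]
        eps <- stats::rnorm(n)
        participants[[score]] <- round(
          cs[["mean"]] + cs[["sd"]] * (rho * zd + sqrt(1 - rho^2) * eps), 1)
      }
    }
    for (tag in c("gm", "wm")) {
      tr <- trajectory[[tag]]
      mu <- .trajectoryMean(tr, ages + delta, sex_num, trajectory$ref_age)
      vals <- mu + noise[[tag]]
      if (!is.null(deviant_features)) {
        hit <- intersect(names(deviant_features), tr$name)
        for (f in hit) {
          j <- match(f, tr$name)
          vals[, j] <- vals[, j] + deviant_features[[f]] * tr$sigma[j]
        }
      }
      vals <- .clampToDomain(vals, tr)
      tables[[tag]] <- FeatureTable(
        vals, tr[, c("name", "modality", "region_group", "hemisphere")],
        participants)
    }
    list(participants = participants, gm = tables$gm, wm = tables$wm)
  })
}

#' Simulate a normative (reference) population
#'
#' Draws `n` cognitively normal participants with ages from a truncated
#' normal distribution, sex, and education, then generates the 124-feature
#' gray-matter and 90-feature white-matter tables from the per-feature
#' aging trajectories with independent Gaussian noise. Identical
#' `(n, trajectory, seed)` give bit-identical output.
#'
#' @param n number of participants (`n = 0` gives empty tables).
#' @param trajectory a trajectory configuration
#'   (default [defaultTrajectoryConfig()]).
#' @param seed integer RNG seed.
#' @param group group label recorded for every participant.
#' @return list with `participants` (data.frame), `gm` and `wm`
#'   ([FeatureTable-class]).
#' @examples
#' pop <- simulateNormativePopulation(20, seed = 1)
#' dim(featureValues(pop$gm))
#' @export
simulateNormativePopulation <- function(n, trajectory = defaultTrajectoryConfig(),
                                        seed, group = "TRAIN") {
  .simulateCohort(n, trajectory, seed, group = group,
                  age_mean = trajectory$age_mean, age_sd = trajectory$age_sd,
                  education_mean = 12, education_sd = 4,
                  id_prefix = "norm")
}

.CLINICAL_DEFAULTS <- list(
  MSA = list(
    UPDRS_I = c(mean = 2.5, sd = 1.8, coupling = 0.4),
    UPDRS_II = c(mean = 17.4, sd = 8.5, coupling = 0.4),
    UPDRS_III = c(mean = 26.3, sd = 16.3, coupling = 0.4),
    UPDRS_total = c(mean = 46.2, sd = 24.4, coupling = 0.4),
    UMSARS_I = c(mean = 19.5, sd = 8.2, coupling = 0.4),
    UMSARS_II = c(mean = 20.5, sd = 9.8, coupling = 0.4),
    UMSARS_total = c(mean = 40.0, sd = 16.8, coupling = 0.4),
    HY = c(mean = 3.4, sd = 1.0, coupling = 0.4),
    MMSE = c(mean = 26.8, sd = 4.0, coupling = -0.3),
    MoCA = c(mean = 20.1, sd = 5.0, coupling = -0.3)),
  PD = list(
    UPDRS_I = c(mean = 2.3, sd = 1.7, coupling = 0.4),
    UPDRS_II = c(mean = 5.4, sd = 4.2, coupling = 0.4),
    UPDRS_III = c(mean = 9.7, sd = 5.9, coupling = 0.4),
    UPDRS_total = c(mean = 17.4, sd = 9.9, coupling = 0.4),
    HY = c(mean = 1.7, sd = 0.7, coupling = 0.4),
    MMSE = c(mean = 27.6, sd = 2.0, coupling = -0.3),
    MoCA = c(mean = 25.1, sd = 3.5, coupling = -0.3)),
  HC = list(
    MMSE = c(mean = 29.4, sd = 1.0, coupling = -0.3),
    MoCA = c(mean = 28.3, sd = 1.5, coupling = -0.3)))

.GROUP_AGE_DEFAULTS <- list(
  MSA = c(mean = 64.6, sd = 5.2, education_mean = 10.6, education_sd = 4.2),
  PD = c(mean = 70.0, sd = 8.0, education_mean = 11.1, education_sd = 4.8),
  HC = c(mean = 65.1, sd = 5.6, education_mean = 15.0, education_sd = 4.2))

#' Configuration for a simulated clinical cohort
#'
#' Defines the ground truth of a clinical group: its size, demographic
#' distribution, brain-age offset, focal regional deviance, and the
#' coupling of clinical scores to the realized offset. The brain-age
#' offset is implemented as an effective-age shift: every feature is
#' evaluated at `age + delta_i` where
#' `delta_i = pad_shift + N(0, jitter_sd^2)`, so the injected mean PAD is
#' recoverable by construction. Demographic and clinical-score defaults
#' follow typical clinic-based MSA/PD/control cohorts (severity scores
#' couple positively to the offset, cognitive scores negatively).
#'
#' @param group one of `"HC"`, `"PD"`, `"MSA"` (or any label; defaults for
#'   unknown labels fall back to the HC demographics and no clinical
#'   scores).
#' @param n group size.
#' @param pad_shift mean brain-age offset delta in years.
#' @param jitter_sd SD of the per-subject offset jitter (years).
#' @param age_mean,age_sd group age distribution (years).
#' @param education_mean,education_sd education distribution (years).
#' @param deviant_features named numeric vector: extra shift added to the
#'   named features, in units of each feature's noise SD.
#' @param clinical named list of `c(mean, sd, coupling)` per score;
#'   `coupling` is the correlation of the score with the realized offset.
#' @param seed integer RNG seed used when the cohort is generated.
#' @return list of class `"clinicalCohortConfig"`.
#' @export
clinicalCohortConfig <- function(group = "HC", n = 30, pad_shift = 0,
                                 jitter_sd = 2,
                                 age_mean = NULL, age_sd = NULL,
                                 education_mean = NULL, education_sd = NULL,
                                 deviant_features = NULL,
                                 clinical = NULL, seed = 1L) {
  defaults <- .GROUP_AGE_DEFAULTS[[group]]
  if (is.null(defaults)) defaults <- .GROUP_AGE_DEFAULTS[["HC"]]
  if (is.null(age_mean)) age_mean <- defaults[["mean"]]
  if (is.null(age_sd)) age_sd <- defaults[["sd"]]
  if (is.null(education_mean)) education_mean <- defaults[["education_mean"]]
  if (is.null(education_sd)) education_sd <- defaults[["education_sd"]]
  if (is.null(clinical)) clinical <- .CLINICAL_DEFAULTS[[group]]
  .assert(n >= 0, "n must be non-negative")
  .assert(jitter_sd >= 0, "jitter_sd must be non-negative")
  structure(list(group = group, n = n, pad_shift = pad_shift,
                 jitter_sd = jitter_sd, age_mean = age_mean, age_sd = age_sd,
                 education_mean = education_mean,
                 education_sd = education_sd,
                 deviant_features = deviant_features,
                 clinical = clinical, seed = as.integer(seed)),
            class = "clinicalCohortConfig")
}

#' Simulate a clinical cohort with known brain-age ground truth
#'
#' Generates a group whose feature values are drawn from
#' `mu(age + delta_i, sex) + deviance + noise`, where `delta_i` is the
#' per-subject brain-age offset defined by the configuration. The realized
#' offsets are returned as `true_offset` in the participant table, so
#' downstream recovery of the injected PAD can be checked exactly.
#' Clinical scores are generated with the configured linear coupling to
#' the realized offset.
#'
#' With `pad_shift = 0`, `jitter_sd = 0`, no deviant features, no clinical
#' scores and the reference demographics, the output reproduces
#' [simulateNormativePopulation()] draws exactly under the same seed.
#'
#' @param config a [clinicalCohortConfig()].
#' @param trajectory a trajectory configuration.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `participants`, `gm`, `wm` as in
#'   [simulateNormativePopulation()].
#' @examples
#' cfg <- clinicalCohortConfig("MSA", n = 10, pad_shift = 9, seed = 3)
#' coh <- simulateClinicalCohort(cfg)
#' mean(coh$participants$true_offset)
#' @export
simulateClinicalCohort <- function(config,
                                   trajectory = defaultTrajectoryConfig(),
                                   seed = config$seed) {
  .assert(inherits(config, "clinicalCohortConfig"),
          "config must come from clinicalCohortConfig()")
  .simulateCohort(config$n, trajectory, seed, group = config$group,
                  age_mean = config$age_mean, age_sd = config$age_sd,
                  education_mean = config$education_mean,
                  education_sd = config$education_sd,
                  id_prefix = paste0(tolower(config$group), "-"),
                  pad_shift = config$pad_shift,
                  jitter_sd = config$jitter_sd,
                  deviant_features = config$deviant_features,
                  clinical = config$clinical)
}
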