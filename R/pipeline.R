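#' @include simulate.R brainAge.R pad.R groupStats.R normative.R contribution.R
NULL

#' Default end-to-end pipeline configuration
#'
#' Bundles every stage of the analysis — cohort synthesis, brain-age model
#' training and cross-validation, PAD computation and bias correction,
#' normative modeling, Z-scores, robust contribution profiles, and the
#' group statistics — into one declarative config. Every stochastic stage
#' carries an explicit seed derived from `seed`. The default study
#' conditions mirror a clinic-scale three-group comparison (HC/PD/MSA of
#' 34/33/23 participants with brain-age offsets of 0/1.5/9 years) against
#' a 500-participant reference population.
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param train_n reference-population size for brain-age training.
#' @param group_n named group sizes.
#' @param pad_shifts named ground-truth brain-age offsets (years).
#' @param normative_ref_n reference subsample size for the per-feature
#'   normative fits.
#' @param modalities which panels to analyse.
#' @param run_cv whether to cross-validate the brain-age models.
#' @param cv_folds folds for cross-validation.
#' @param hyperparams [brainAgeHyperparams()].
#' @param normative [normativeConfig()].
#' @param mm [mmConfig()].
#' @param covariates covariates of the group statistics.
#' @param reference_group group the bias correction is fitted on.
#' @param delta_groups two groups contrasted in the delta-ES table.
#' @param delta_threshold selection threshold on `|delta_es|`.
#' @param trajectory trajectory configuration of the generator.
#' @param output_dir optional directory for stage outputs.
#' @return config list of class `"brainpadPipelineConfig"`.
#' @export
defaultPipelineConfig <- function(seed = 1L, train_n = 500,
                                  group_n = c(HC = 34, PD = 33, MSA = 23),
                                  pad_shifts = c(HC = 0, PD = 1.5, MSA = 9),
                                  normative_ref_n = 500,
                                  modalities = c("gm", "wm"),
                                  run_cv = TRUE, cv_folds = 10,
                                  hyperparams = brainAgeHyperparams(),
                                  normative = normativeConfig(),
                                  mm = mmConfig(),
                                  covariates = c("age", "sex", "education"),
                                  reference_group = "HC",
                                  delta_groups = c("MSA", "PD"),
                                  delta_threshold = 0.3,
                                  trajectory = defaultTrajectoryConfig(),
                                  output_dir = NULL) {
  groups <- names(group_n)
  seeds <- list(
    train_cohort = .deriveSeed(seed, 1),
    brain_age = stats::setNames(
      lapply(seq_along(modalities), function(i) .deriveSeed(seed, 10 + i)),
      modalities),
    cv = .deriveSeed(seed, 20),
    groups = stats::setNames(
      lapply(seq_along(groups), function(i) .deriveSeed(seed, 30 + i)),
      groups),
    normative = .deriveSeed(seed, 40),
    mm = .deriveSeed(seed, 50))
  structure(list(seed = as.integer(seed), seeds = seeds,
                 train_n = train_n, group_n = group_n,
                 pad_shifts = pad_shifts,
                 normative_ref_n = normative_ref_n,
                 modalities = modalities,
                 run_cv = run_cv, cv_folds = cv_folds,
                 hyperparams = hyperparams, normative = normative,
                 mm = mm, covariates = covariates,
                 reference_group = reference_group,
                 delta_groups = delta_groups,
                 delta_threshold = delta_threshold,
                 trajectory = trajectory, output_dir = output_dir),
            class = "brainpadPipelineConfig")
}

#' Validate a pipeline configuration
#'
#' @param config a pipeline config (see [defaultPipelineConfig()]).
#' @return character vector of issues; empty when the config is runnable.
#' @export
validatePipelineConfig <- function(config) {
  issues <- character(0)
  note <- function(msg) issues <<- c(issues, msg)
  if (!is.list(config)) return("config must be a list")
  for (f in c("seed", "seeds", "train_n", "group_n", "pad_shifts",
              "modalities", "covariates", "reference_group"))
    if (is.null(config[[f]])) note(sprintf("missing field '%s'", f))
  if (!is.null(config$train_n) && config$train_n < 0)
    note("train_n must be non-negative")
  if (!is.null(config$group_n)) {
    if (any(config$group_n < 0)) note("group_n entries must be non-negative")
    if (is.null(names(config$group_n))) note("group_n must be named")
  }
  if (!is.null(config$seeds)) {
    for (f in c("train_cohort", "brain_age", "cv", "groups", "normative",
                "mm"))
      if (is.null(config$seeds[[f]]))
        note(sprintf("missing seed for stage '%s'", f))
    if (!is.null(config$seeds$groups) && !is.null(config$group_n)) {
      ug <- setdiff(names(config$group_n), names(config$seeds$groups))
      if (length(ug))
        note(sprintf("missing seed for group(s): %s",
                     paste(ug, collapse = ", ")))
    }
  }
  known_cov <- c("age", "sex", "education")
  bad_cov <- setdiff(config$covariates, known_cov)
  if (length(bad_cov))
    note(sprintf("unknown covariate(s): %s", paste(bad_cov, collapse = ", ")))
  if (!is.null(config$reference_group) && !is.null(config$group_n) &&
      !config$reference_group %in% names(config$group_n))
    note(sprintf("reference_group '%s' is not among the groups",
                 config$reference_group))
  if (!is.null(config$delta_groups) && !is.null(config$group_n)) {
    dg <- setdiff(config$delta_groups, names(config$group_n))
    if (length(dg))
      note(sprintf("delta group(s) not simulated: %s",
                   paste(dg, collapse = ", ")))
  }
  bad_mod <- setdiff(config$modalities, c("gm", "wm"))
  if (length(bad_mod))
    note(sprintf("unknown modality(ies): %s", paste(bad_mod, collapse = ", ")))
  issues
}

#' Run the full brain-age analysis pipeline
#'
#' Executes, in dependency order: reference-population synthesis,
#' brain-age model training (and optional cross-validation) per modality,
#' clinical-cohort synthesis, age prediction, PAD computation, linear age
#' bias correction fitted on the reference group, normative model fitting
#' and Z-scores, robust contribution profiles with top-feature ranking and
#' the between-group delta-ES table, ANCOVA group comparison with
#' BH-adjusted post-hoc tests, GM-PAD/WM-PAD partial correlations per
#' group with Fisher r-to-z comparisons, and clinical-score associations.
#' Identical configs (including seeds) give identical reports.
#'
#' @param config a pipeline config from [defaultPipelineConfig()].
#' @return report list with per-stage results (`cv`, `pad`, `bias`,
#'   `group_comparison`, `pad_correlations`, `clinical`, `contributions`,
#'   `top_features`, `delta_es`, `warnings`).
#' @export
runPipeline <- function(config) {
  issues <- validatePipelineConfig(config)
  .assert(length(issues) == 0L, "invalid config:\n- %s",
          paste(issues, collapse = "\n- "))
  warn <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  train_pop <- stage("simulate_training",
    simulateNormativePopulation(config$train_n, config$trajectory,
                                seed = config$seeds$train_cohort))

  models <- list(); cv <- list()
  for (mod in config$modalities) {
    models[[mod]] <- stage(paste0("train_", mod),
      trainBrainAgeModel(train_pop[[mod]],
                         hyperparams = config$hyperparams,
                         seed = config$seeds$brain_age[[mod]]))
    if (isTRUE(config$run_cv))
      cv[[mod]] <- stage(paste0("cv_", mod),
        crossValidate(train_pop[[mod]], k = config$cv_folds,
                      hyperparams = config$hyperparams,
                      seed = config$seeds$cv))
  }

  cohorts <- list()
  for (g in names(config$group_n)) {
    cohorts[[g]] <- stage(paste0("simulate_", g),
      simulateClinicalCohort(
        clinicalCohortConfig(g, n = config$group_n[[g]],
                             pad_shift = config$pad_shifts[[g]],
                             seed = config$seeds$groups[[g]]),
        trajectory = config$trajectory))
  }
  participants <- do.call(rbind, lapply(cohorts, function(co) {
    p <- co$participants
    for (sc in .CLINICAL_SCORES) if (is.null(p[[sc]])) p[[sc]] <- NA_real_
    p[, c("id", "age", "sex", "education", "group", "true_offset",
          .CLINICAL_SCORES)]
  }))
  rownames(participants) <- NULL

  pad_tab <- NULL; bias <- list()
  for (mod in config$modalities) {
    pred <- unlist(lapply(names(cohorts), function(g)
      predictAge(models[[mod]], cohorts[[g]][[mod]])))
    pads <- computePAD(pred, participants$age)
    ref <- participants$group == config$reference_group
    bias[[mod]] <- fitBiasCorrection(pads[ref], participants$age[ref],
                                     reference = config$reference_group)
    corrected <- applyBiasCorrection(pads, participants$age, bias[[mod]])
    pad_tab <- rbind(pad_tab, data.frame(
      id = participants$id, group = participants$group,
      age = participants$age, modality = toupper(mod),
      predicted = pred, pad = pads, pad_corrected = corrected,
      stringsAsFactors = FALSE))
  }

  ref_idx <- withr::with_seed(config$seeds$normative, {
    sample.int(config$train_n, min(config$normative_ref_n, config$train_n))
  })
  norms <- list(); zscores <- list(); contributions <- list()
  top_features <- list(); delta_es <- list()
  for (mod in config$modalities) {
    norms[[mod]] <- stage(paste0("normative_", mod),
      fitNormativeModelSet(train_pop[[mod]][, ref_idx],
                           config$normative,
                           seed = config$seeds$normative))
    ztabs <- lapply(cohorts, function(co)
      suppressWarnings(computeZScores(norms[[mod]], co[[mod]])))
    zscores[[mod]] <- do.call(rbind, ztabs)
    padm <- pad_tab[pad_tab$modality == toupper(mod), ]
    profs <- list()
    for (g in names(cohorts)) {
      sel <- padm$group == g
      profs[[g]] <- stage(paste0("contribution_", mod, "_", g),
        contributionProfile(ztabs[[g]], padm$pad_corrected[sel], group = g,
                            config = config$mm))
      top_features[[mod]][[g]] <- rankTop(profs[[g]])
    }
    contributions[[mod]] <- profs
    a <- config$delta_groups[1]; b <- config$delta_groups[2]
    refg <- config$reference_group
    delta_es[[mod]] <- deltaEffectSize(profs[[a]], profs[[b]],
                                       profs[[refg]],
                                       threshold = config$delta_threshold)
  }

  covar <- participants[, config$covariates, drop = FALSE]
  group_comparison <- list()
  for (mod in config$modalities) {
    padm <- pad_tab[pad_tab$modality == toupper(mod), ]
    group_comparison[[mod]] <- ancovaCompare(padm$pad_corrected,
                                             padm$group, covar)
  }

  pad_correlations <- NULL
  if (all(c("gm", "wm") %in% config$modalities)) {
    gm <- pad_tab[pad_tab$modality == "GM", "pad_corrected"]
    wm <- pad_tab[pad_tab$modality == "WM", "pad_corrected"]
    per_group <- lapply(names(cohorts), function(g) {
      sel <- participants$group == g
      pc <- partialCorrelation(gm[sel], wm[sel],
                               covar[sel, , drop = FALSE])
      data.frame(group = g, rho = pc$rho, p = pc$p, n = pc$n)
    })
    per_group <- do.call(rbind, per_group)
    pairs <- utils::combn(per_group$group, 2)
    comparisons <- do.call(rbind, apply(pairs, 2, function(pr) {
      i <- match(pr, per_group$group)
      cc <- compareCorrelations(per_group$rho[i[1]], per_group$n[i[1]],
                                per_group$rho[i[2]], per_group$n[i[2]])
      data.frame(group1 = pr[1], group2 = pr[2], z = cc$z, p = cc$p)
    }))
    pad_correlations <- list(per_group = per_group,
                             comparisons = comparisons)
  }

  clinical <- list()
  for (mod in config$modalities) {
    padm <- pad_tab[pad_tab$modality == toupper(mod), ]
    clinical[[mod]] <- do.call(rbind, lapply(names(cohorts), function(g) {
      sel <- participants$group == g
      scores <- .CLINICAL_SCORES[colSums(!is.na(
        participants[sel, .CLINICAL_SCORES, drop = FALSE])) > 0]
      if (!length(scores)) return(NULL)
      res <- clinicalAssociations(padm$pad_corrected[sel],
                                  participants[sel, , drop = FALSE],
                                  covar[sel, , drop = FALSE],
                                  scores = scores)
      cbind(group = g, modality = toupper(mod), res)
    }))
  }

  report <- list(config = config, participants = participants,
                 models = models, norms = norms,
                 cv = cv, bias = bias, pad = pad_tab,
                 group_comparison = group_comparison,
                 pad_correlations = pad_correlations,
                 clinical = clinical,
                 zscores = zscores,
                 contributions = contributions,
                 top_features = top_features,
                 delta_es = delta_es,
                 warnings = warn)
  if (!is.null(config$output_dir)) .writeRunReport(report, config$output_dir)
  report
}

.writeRunReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$pad, file.path(dir, "pad.csv"))
  data.table::fwrite(report$participants, file.path(dir, "participants.csv"))
  for (mod in names(report$delta_es))
    data.table::fwrite(report$delta_es[[mod]],
                       file.path(dir, paste0("delta_es_", mod, ".csv")))
  summary_ <- list(
    cv = lapply(report$cv, function(x) x[c("r", "mae", "k")]),
    bias = lapply(report$bias, function(b)
      list(slope = b@slope, intercept = b@intercept,
           reference = b@reference)),
    group_comparison = report$group_comparison,
    pad_correlations = report$pad_correlations,
    warnings = report$warnings)
  jsonlite::write_json(summary_, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [defaultPipelineConfig()]; the
#' master `seed` (re)derives all stage seeds unless explicit stage seeds
#' are given in the file.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return config list of class `"brainpadPipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  .assert(file.exists(path), "config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (f in c("seed", "train_n", "normative_ref_n", "run_cv", "cv_folds",
              "reference_group", "delta_threshold", "modalities",
              "covariates", "delta_groups", "output_dir"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$group_n)) args$group_n <- unlist(raw$group_n)
  if (!is.null(raw$pad_shifts)) args$pad_shifts <- unlist(raw$pad_shifts)
  if (!is.null(raw$hyperparams))
    args$hyperparams <- do.call(brainAgeHyperparams, raw$hyperparams)
  if (!is.null(raw$normative))
    args$normative <- do.call(normativeConfig, raw$normative)
  if (!is.null(raw$mm)) args$mm <- do.call(mmConfig, raw$mm)
  config <- do.call(defaultPipelineConfig, args)
  if (!is.null(raw$seeds)) config$seeds <- utils::modifyList(config$seeds,
                                                             raw$seeds)
  config
}
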