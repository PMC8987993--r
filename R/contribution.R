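#' @include utils.R
#' @importFrom MASS rlm psi.bisquare
NULL

#' Configuration of the robust MM effect-size estimator
#'
#' @param c_tuning bisquare tuning constant of the final M-step; the
#'   default 3.443689 gives ~85% efficiency at the normal. The initial
#'   S-stage keeps its 50% breakdown point.
#' @param maxit IWLS iteration cap.
#' @param seed seed for the subsampling in the S-estimation stage.
#' @return named list.
#' @export
mmConfig <- function(c_tuning = 3.443689, maxit = 100, seed = 1L) {
  list(c_tuning = c_tuning, maxit = as.integer(maxit),
       seed = as.integer(seed))
}

#' Robust effect size of the Z-vs-PAD association
#'
#' Both variables are standardized by robust location/scale (median, MAD);
#' the effect size is the slope of an MM-type robust regression of
#' standardized PAD on standardized Z, clipped to `[-1, 1]`. This scores
#' how strongly a feature's structural deviance tracks the brain-age gap
#' while resisting gross outliers (50% breakdown S-stage, ~85%-efficient
#' redescending M-step).
#'
#' @param z_values feature Z-scores.
#' @param pad_values PAD scores, aligned with `z_values`.
#' @param config an [mmConfig()].
#' @return list with `es` (signed, clipped), `converged`, `n`, and
#'   `degenerate` (TRUE when either variable has zero MAD, in which case
#'   `es` is NA).
#' @export
robustEffectSize <- function(z_values, pad_values, config = mmConfig()) {
  n <- length(z_values)
  .assert(length(pad_values) == n,
          "z_values and pad_values must have equal length")
  .assert(n >= 10, "need at least 10 observations, got %d", n)
  .checkFinite(z_values, "z_values"); .checkFinite(pad_values, "pad_values")
  mad_z <- stats::mad(z_values); mad_p <- stats::mad(pad_values)
  if (mad_z < 1e-12 || mad_p < 1e-12)
    return(list(es = NA_real_, converged = FALSE, n = n, degenerate = TRUE))
  zs <- (z_values - stats::median(z_values)) / mad_z
  ps <- (pad_values - stats::median(pad_values)) / mad_p
  # exact linear relation: the robust scale is 0 and IWLS is ill-defined
  ols <- stats::lm.fit(cbind(1, zs), ps)
  if (sqrt(mean(ols$residuals^2)) < 1e-10) {
    es <- max(min(unname(ols$coefficients[2]), 1), -1)
    return(list(es = es, converged = TRUE, n = n, degenerate = FALSE))
  }
  fit <- withr::with_seed(config$seed, {
    MASS::rlm(ps ~ zs, method = "MM", psi = MASS::psi.bisquare,
              c = config$c_tuning, maxit = config$maxit)
  })
  es <- max(min(unname(stats::coef(fit)[2]), 1), -1)
  list(es = es, converged = isTRUE(fit$converged), n = n,
       degenerate = FALSE)
}

#' Per-feature contribution profile of a group
#'
#' Applies [robustEffectSize()] to every feature's Z-score column against
#' the group's (bias-corrected) PAD scores.
#'
#' @param zscores matrix of Z-scores, participants x features (from
#'   [computeZScores()]).
#' @param pads PAD scores aligned with the rows of `zscores`.
#' @param group group label recorded in the output.
#' @param config an [mmConfig()].
#' @return data.frame with one row per feature: `feature`, `group`, `es`,
#'   `converged`, `degenerate`, `n`.
#' @export
contributionProfile <- function(zscores, pads, group = "group",
                                config = mmConfig()) {
  zscores <- as.matrix(zscores)
  .assert(nrow(zscores) == length(pads),
          "zscores rows and pads must be aligned (%d vs %d)",
          nrow(zscores), length(pads))
  .assert(!is.null(colnames(zscores)), "zscores must have feature names")
  rows <- lapply(seq_len(ncol(zscores)), function(j) {
    r <- robustEffectSize(zscores[, j], pads, config)
    data.frame(feature = colnames(zscores)[j], group = group,
               es = r$es, converged = r$converged,
               degenerate = r$degenerate, n = r$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Top-k features by absolute effect size
#'
#' @param profile data.frame from [contributionProfile()].
#' @param k how many features (default 20); `k` larger than the feature
#'   count returns all.
#' @return character vector of feature names, |ES| non-increasing; ties
#'   broken lexicographically by feature name.
#' @export
rankTop <- function(profile, k = 20) {
  .assert(all(c("feature", "es") %in% colnames(profile)),
          "profile must have 'feature' and 'es' columns")
  ord <- order(-abs(profile$es), profile$feature)
  profile$feature[ord][seq_len(min(k, nrow(profile)))]
}

#' Between-group difference in contribution effect sizes
#'
#' Signed difference `delta_es = es_A - es_B` per feature, with features
#' whose `|delta_es|` exceeds the threshold (0.3, a medium effect-size
#' difference) flagged as markedly different. A reference-group profile
#' (e.g. healthy controls) can be carried along for context.
#'
#' @param profile_a,profile_b contribution profiles of the two groups
#'   (same feature set).
#' @param profile_ref optional reference profile.
#' @param threshold selection threshold on `|delta_es|`.
#' @return data.frame with `feature`, `es_a`, `es_b`, `es_ref`,
#'   `delta_es`, `selected`; the threshold is recorded as an attribute.
#' @examples
#' a <- data.frame(feature = "f", group = "A", es = 0.527)
#' b <- data.frame(feature = "f", group = "B", es = 0.106)
#' deltaEffectSize(a, b)$delta_es  # 0.421
#' @export
deltaEffectSize <- function(profile_a, profile_b, profile_ref = NULL,
                            threshold = 0.3) {
  .assert(setequal(profile_a$feature, profile_b$feature) &&
            nrow(profile_a) == nrow(profile_b),
          "profiles must cover the same feature set")
  b <- profile_b[match(profile_a$feature, profile_b$feature), ]
  out <- data.frame(feature = profile_a$feature,
                    es_a = profile_a$es, es_b = b$es,
                    es_ref = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(profile_ref)) {
    .assert(setequal(profile_ref$feature, profile_a$feature),
            "reference profile must cover the same feature set")
    out$es_ref <- profile_ref$es[match(out$feature, profile_ref$feature)]
  }
  out$delta_es <- out$es_a - out$es_b
  out$selected <- abs(out$delta_es) > threshold
  attr(out, "threshold") <- threshold
  out
}

#' Aggregate contributions by region group
#'
#' Percent contribution of each region group (lobe for gray matter, fiber
#' system for white matter) within each feature type:
#' `100 * sum(|es|) in region group / sum(|es|) over the feature type`.
#' Percentages sum to 100 within each feature type.
#'
#' @param profile contribution profile data.frame.
#' @param descriptors descriptor data.frame covering all profiled
#'   features (`name`, `modality`, `region_group`, `hemisphere`).
#' @param by descriptor column to aggregate over (`"region_group"` or
#'   `"hemisphere"`).
#' @return data.frame with `modality`, the `by` column, `sum_abs_es`,
#'   `percent`.
#' @export
aggregateByRegion <- function(profile, descriptors, by = "region_group") {
  .assert(by %in% colnames(descriptors), "unknown descriptor column '%s'", by)
  missing_ <- setdiff(profile$feature, descriptors$name)
  .assert(length(missing_) == 0L, "descriptors do not cover feature(s): %s",
          paste(missing_, collapse = ", "))
  idx <- match(profile$feature, descriptors$name)
  df <- data.frame(modality = descriptors$modality[idx],
                   grp = descriptors[[by]][idx],
                   abs_es = abs(profile$es))
  .assert(!anyNA(df$abs_es), "profile contains undefined effect sizes")
  out <- do.call(rbind, lapply(split(df, df$modality), function(d) {
    tot <- sum(d$abs_es)
    .assert(tot > 0,
            "all effect sizes are zero for modality '%s'; percentages undefined",
            d$modality[1])
    agg <- stats::aggregate(abs_es ~ grp, d, sum)
    data.frame(modality = d$modality[1], group = agg$grp,
               sum_abs_es = agg$abs_es,
               percent = 100 * agg$abs_es / tot,
               stringsAsFactors = FALSE)
  }))
  names(out)[names(out) == "group"] <- by
  rownames(out) <- NULL
  out
}
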