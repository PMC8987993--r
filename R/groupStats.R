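#' @include utils.R
NULL

.covariateMatrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), n, 0))
  cm <- as.data.frame(covariates)
  .assert(nrow(cm) == n, "covariates must have %d rows", n)
  out <- do.call(cbind, lapply(seq_along(cm), function(j) {
    v <- cm[[j]]
    if (is.numeric(v)) v else .sexToNumeric(v)
  }))
  colnames(out) <- colnames(cm)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' clipped at 1. Input validation aside, this is `p.adjust(p, "BH")`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))
#' @export
bhAdjust <- function(pvalues) {
  .checkFinite(pvalues, "pvalues")
  .assert(all(pvalues >= 0 & pvalues <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' ANCOVA comparison of a score across groups
#'
#' Omnibus F test of the group factor from nested linear models (full:
#' group dummies + covariates; reduced: covariates only), followed by
#' post-hoc pairwise two-group ANCOVAs with the same covariates,
#' BH-adjusted across the pairs. With 3 groups, n participants and k
#' covariates the omnibus df are `(2, n - 3 - k)`.
#'
#' @param values numeric response (e.g. corrected PAD).
#' @param groups group factor (>= 2 levels).
#' @param covariates data.frame of covariates (e.g. age, sex, education);
#'   non-numeric sex is recoded 0/1.
#' @param posthoc run pairwise comparisons (default TRUE).
#' @return list with `F`, `df1`, `df2`, `p`, `adjusted_means` (per-group
#'   means at the covariate means), and `posthoc` (data.frame with raw and
#'   BH-adjusted p per pair).
#' @export
ancovaCompare <- function(values, groups, covariates = NULL,
                          posthoc = TRUE) {
  values <- as.numeric(values)
  groups <- droplevels(factor(groups))
  n <- length(values)
  .assert(length(groups) == n, "values and groups must have equal length")
  .assert(nlevels(groups) >= 2, "need at least 2 groups")
  cm <- .covariateMatrix(covariates, n)
  G <- stats::model.matrix(~groups)[, -1, drop = FALSE]
  X_full <- cbind(1, G, cm)
  X_red <- cbind(1, cm)
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    dropped <- colnames(X_full)[qr_full$pivot[(qr_full$rank + 1):ncol(X_full)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  rss <- function(X) sum(stats::lm.fit(X, values)$residuals^2)
  df1 <- nlevels(groups) - 1L
  df2 <- n - nlevels(groups) - ncol(cm)
  rss_red <- rss(X_red); rss_full <- rss(X_full)
  scale0 <- max(sum(values^2), 1) * 1e-12
  Fstat <- if (rss_red - rss_full <= scale0) 0  # group adds nothing
           else ((rss_red - rss_full) / df1) / (rss_full / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  fit_full <- stats::lm.fit(X_full, values)
  cov_means <- if (ncol(cm)) colMeans(cm) else numeric(0)
  lv <- levels(groups)
  adj <- vapply(lv, function(g) {
    gd <- as.numeric(lv[-1] == g)
    sum(c(1, gd, cov_means) * fit_full$coefficients)
  }, numeric(1))

  ph <- NULL
  if (posthoc && nlevels(groups) > 2) {
    pairs <- utils::combn(lv, 2)
    praw <- apply(pairs, 2, function(pr) {
      sel <- groups %in% pr
      sub <- ancovaCompare(values[sel], groups[sel],
                           if (ncol(cm)) as.data.frame(cm[sel, , drop = FALSE])
                           else NULL,
                           posthoc = FALSE)
      sub$p
    })
    ph <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     p = praw, p_adj = bhAdjust(praw))
  }
  list(F = Fstat, df1 = df1, df2 = df2, p = p,
       adjusted_means = adj, posthoc = ph, n = n)
}

#' Partial correlation adjusting for covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on the
#' covariates (plus intercept); the p-value uses the t distribution with
#' `n - 2 - k` degrees of freedom for `k` covariates. With no covariates
#' this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame of covariates or NULL.
#' @return list with `rho`, `p`, `n`, `df`.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  .assert(length(y) == n, "x and y must have equal length")
  cm <- .covariateMatrix(covariates, n)
  .assert(n > ncol(cm) + 2, "need n > covariates + 2 (n=%d, k=%d)",
          n, ncol(cm))
  X <- cbind(1, cm)
  rx <- stats::lm.fit(X, as.numeric(x))$residuals
  ry <- stats::lm.fit(X, as.numeric(y))$residuals
  rho <- stats::cor(rx, ry)
  df <- n - 2L - ncol(cm)
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df)
}

#' Compare two independent correlation coefficients (Fisher r-to-z)
#'
#' Two-sided z test of `rho1 - rho2` after Fisher's variance-stabilizing
#' transform, with standard error `sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param rho1,rho2 sample correlations, `|rho| < 1`.
#' @param n1,n2 sample sizes, `> 3`.
#' @return list with `z` and two-sided `p` from the standard normal.
#' @examples
#' compareCorrelations(0.409, 33, -0.013, 34)$p  # ~0.081
#' @export
compareCorrelations <- function(rho1, n1, rho2, n2) {
  .assert(abs(rho1) < 1 && abs(rho2) < 1,
          "|rho| must be < 1 (z-transform is infinite at 1)")
  .assert(n1 > 3 && n2 > 3, "sample sizes must exceed 3")
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Associations between PAD and clinical scores
#'
#' One partial correlation per clinical score, with pairwise deletion of
#' missing score values. Scores that are entirely missing (or leave too
#' few observations) are flagged rather than silently dropped.
#'
#' @param pad numeric PAD scores.
#' @param clinical data.frame of clinical scores (participants in rows).
#' @param covariates data.frame of covariates or NULL.
#' @param scores which columns of `clinical` to analyse (default: all).
#' @return data.frame with one row per score: `score`, `n_used`, `rho`,
#'   `p`, `flag`.
#' @export
clinicalAssociations <- function(pad, clinical, covariates = NULL,
                                 scores = colnames(clinical)) {
  clinical <- as.data.frame(clinical)
  n <- length(pad)
  .assert(nrow(clinical) == n, "clinical must have %d rows", n)
  k <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  out <- lapply(scores, function(sc) {
    v <- clinical[[sc]]
    keep <- !is.na(v) & !is.na(pad)
    if (sum(keep) <= k + 2)
      return(data.frame(score = sc, n_used = sum(keep), rho = NA_real_,
                        p = NA_real_, flag = "insufficient non-missing data"))
    cv <- if (is.null(covariates)) NULL else
      as.data.frame(covariates)[keep, , drop = FALSE]
    pc <- partialCorrelation(pad[keep], v[keep], cv)
    data.frame(score = sc, n_used = pc$n, rho = pc$rho, p = pc$p, flag = "")
  })
  do.call(rbind, out)
}

#' Mask out the lowest observations per group
#'
#' For an outlier-exclusion re-analysis: marks, within each group, the
#' stated number of smallest values as excluded. Ties are broken by
#' first-occurrence order (stable).
#'
#' @param values numeric vector.
#' @param groups group labels aligned with `values`.
#' @param counts named vector: how many of the lowest values to exclude
#'   per group (groups not named are kept intact).
#' @return logical inclusion mask (TRUE = keep).
#' @examples
#' excludeLowest(c(1, 2, 3), c("a", "a", "a"), c(a = 2))
#' @export
excludeLowest <- function(values, groups, counts) {
  n <- length(values)
  .assert(length(groups) == n, "values and groups must have equal length")
  mask <- rep(TRUE, n)
  for (g in names(counts)) {
    idx <- which(groups == g)
    cnt <- counts[[g]]
    .assert(cnt <= length(idx),
            "cannot exclude %d from group '%s' of size %d",
            cnt, g, length(idx))
    if (cnt > 0)
      mask[idx[order(values[idx])[seq_len(cnt)]]] <- FALSE
  }
  mask
}
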