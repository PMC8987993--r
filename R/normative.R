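#' @include AllClasses.R featureTable.R
NULL

#' Configuration of the Gaussian-process normative models
#'
#' The kernel over inputs (age, sex) is a sum of three terms: a squared
#' exponential `s2f * exp(-0.5 * ((da/la)^2 + (ds/ls)^2))` capturing smooth
#' nonlinear age trends (with its own length-scale `ls` for the binary sex
#' dimension), a linear kernel `s2l * a * a'` over centred standardized
#' age capturing the dominant linear decline/rise, and white noise `s2n`.
#' Hyperparameters are optimized on the log scale by maximizing the exact
#' log marginal likelihood (analytic gradients, L-BFGS-B) from `restarts`
#' seeded starting points.
#'
#' @param restarts number of optimizer restarts.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param opt_subsample hyperparameters are optimized on a seeded random
#'   subsample of at most this many reference points (the exact posterior
#'   then conditions on the full reference sample). Hyperparameter
#'   estimates stabilize quickly with n, so this caps the cubic
#'   optimization cost without changing the predictive equations.
#' @param fixed_theta optional numeric(5) of log-hyperparameters
#'   `log(c(s2f, la, ls, s2l, s2n))`; when given, optimization is skipped
#'   (used for closed-form validation).
#' @return named list.
#' @export
normativeConfig <- function(restarts = 3, maxit = 50, opt_subsample = 300,
                            fixed_theta = NULL) {
  .assert(restarts >= 1, "restarts must be >= 1")
  list(restarts = as.integer(restarts), maxit = as.integer(maxit),
       opt_subsample = as.integer(opt_subsample),
       fixed_theta = fixed_theta)
}

.gpKernel <- function(theta, Da2, Ds2, Alin, n) {
  s2f <- exp(theta[1]); la <- exp(theta[2]); ls <- exp(theta[3])
  s2l <- exp(theta[4]); s2n <- exp(theta[5])
  Kse <- s2f * exp(-0.5 * (Da2 / la^2 + Ds2 / ls^2))
  Kse + s2l * Alin + diag(s2n, n)
}

# negative log marginal likelihood and its gradient wrt log-hyperparameters
.gpNll <- function(theta, y, Da2, Ds2, Alin) {
  n <- length(y)
  s2f <- exp(theta[1]); la <- exp(theta[2]); ls <- exp(theta[3])
  s2l <- exp(theta[4]); s2n <- exp(theta[5])
  Kse <- s2f * exp(-0.5 * (Da2 / la^2 + Ds2 / ls^2))
  K <- Kse + s2l * Alin + diag(s2n, n)
  U <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(U)) return(list(value = 1e10, gradient = rep(0, 5)))
  alpha <- backsolve(U, forwardsolve(t(U), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(U))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(U)
  # d(nll)/d(theta_j) = 0.5 * sum((Kinv - alpha alpha') * dK/dtheta_j)
  M <- Kinv - tcrossprod(alpha)
  g <- c(
    0.5 * sum(M * Kse),
    0.5 * sum(M * (Kse * Da2 / la^2)),
    0.5 * sum(M * (Kse * Ds2 / ls^2)),
    0.5 * sum(M * (s2l * Alin)),
    0.5 * s2n * sum(diag(M)))
  list(value = nll, gradient = g)
}

.GP_LOWER <- log(c(1e-6, 0.05, 0.05, 1e-8, 1e-5))
.GP_UPPER <- log(c(50, 50, 50, 50, 50))

#' Fit a Gaussian-process normative model for one feature
#'
#' Regresses a single regional feature on age and sex in a reference
#' population by exact GP regression (see [normativeConfig()] for the
#' kernel). Inputs and targets are standardized internally; the stored
#' model predicts on the original scales. Deterministic given `seed`.
#'
#' @param y feature values in the reference sample (`n >= 10`).
#' @param ages chronological ages (years).
#' @param sexes sex as "male"/"female" or 1/0.
#' @param config a [normativeConfig()].
#' @param seed integer seed for the restart initialization.
#' @param feature name stored with the model.
#' @return a fitted model (list) with hyperparameters `theta`, the log
#'   marginal likelihood `lml`, and a `degenerate` flag for zero-variance
#'   targets.
#' @export
fitNormativeModel <- function(y, ages, sexes, config = normativeConfig(),
                              seed = 1L, feature = "feature") {
  n <- length(y)
  min_n <- if (is.null(config$fixed_theta)) 10L else 2L
  .assert(n >= min_n, "need at least %d reference observations, got %d",
          min_n, n)
  .assert(length(ages) == n && length(sexes) == n,
          "y, ages and sexes must have equal length")
  .checkFinite(y, "y"); .checkFinite(ages, "ages")
  s <- .sexToNumeric(sexes)
  a_c <- mean(ages); a_s <- stats::sd(ages)
  if (a_s < 1e-12) a_s <- 1
  a <- (ages - a_c) / a_s
  y_c <- mean(y); y_s <- stats::sd(y)
  if (y_s < 1e-12) {
    return(structure(list(feature = feature, degenerate = TRUE,
                          y_center = y_c, y_scale = 0,
                          age_center = a_c, age_scale = a_s,
                          age_range = range(ages)),
                     class = "normativeModel"))
  }
  ys <- (y - y_c) / y_s
  Da2 <- outer(a, a, "-")^2
  Ds2 <- outer(s, s, "-")^2
  Alin <- tcrossprod(a)

  base <- log(c(0.3, 1, 1.5, 0.5, 0.5))
  theta <- withr::with_seed(seed, {
    if (!is.null(config$fixed_theta)) {
      pmin(pmax(config$fixed_theta, .GP_LOWER), .GP_UPPER)
    } else {
      sub <- if (n > config$opt_subsample)
        sort(sample.int(n, config$opt_subsample)) else seq_len(n)
      yo <- ys[sub]
      Da2o <- Da2[sub, sub]; Ds2o <- Ds2[sub, sub]; Alino <- Alin[sub, sub]
      # memoise: optim calls fn and gr at the same point back to back
      cache_th <- NULL; cache <- NULL
      eval_ <- function(th) {
        if (is.null(cache_th) || !identical(th, cache_th)) {
          cache <<- .gpNll(th, yo, Da2o, Ds2o, Alino)
          cache_th <<- th
        }
        cache
      }
      fits <- lapply(seq_len(config$restarts), function(r) {
        init <- if (r == 1) base else base + stats::rnorm(5, 0, 0.7)
        init <- pmin(pmax(init, .GP_LOWER), .GP_UPPER)
        stats::optim(init, fn = function(th) eval_(th)$value,
                     gr = function(th) eval_(th)$gradient,
                     method = "L-BFGS-B",
                     lower = .GP_LOWER, upper = .GP_UPPER,
                     control = list(maxit = config$maxit))
      })
      vals <- vapply(fits, `[[`, numeric(1), "value")
      .assert(any(is.finite(vals) & vals < 1e9),
              "GP optimization failed to converge for feature '%s'", feature)
      fits[[which.min(vals)]]$par
    }
  })
  K <- .gpKernel(theta, Da2, Ds2, Alin, n)
  U <- chol(K)
  alpha <- backsolve(U, forwardsolve(t(U), ys))
  lml <- -(0.5 * sum(ys * alpha) + sum(log(diag(U))) +
             0.5 * n * log(2 * pi))
  # predictive-SD recalibration: hyperparameters come from a (possibly
  # subsampled) marginal-likelihood fit, so the absolute noise scale can
  # be off by a few percent; rescale so the leave-one-out standardized
  # residuals of the full reference sample have unit SD (GP LOO
  # identities: mu_-i = y_i - alpha_i / Kinv_ii, var_-i = 1 / Kinv_ii).
  # Skipped when hyperparameters are hand-fixed.
  sd_scale <- 1
  if (is.null(config$fixed_theta)) {
    dKinv <- diag(chol2inv(U))
    loo_z <- alpha / sqrt(dKinv)
    if (stats::sd(loo_z) > 1e-8) sd_scale <- stats::sd(loo_z)
  }
  structure(list(feature = feature, degenerate = FALSE,
                 theta = theta, lml = lml, sd_scale = sd_scale,
                 alpha = alpha, a = a, s = s, y = y,
                 age_center = a_c, age_scale = a_s,
                 y_center = y_c, y_scale = y_s,
                 age_range = range(ages)),
            class = "normativeModel")
}

#' Posterior predictive mean and SD of a normative model
#'
#' Exact GP posterior at new (age, sex) inputs. The predictive SD includes
#' the noise variance, i.e. it is the SD of a new observation, which is
#' what standardizes held-out reference values to ~N(0, 1). Queries
#' outside the training age range are returned with an extrapolation
#' warning and flag.
#'
#' @param model a fitted model from [fitNormativeModel()].
#' @param ages,sexes query inputs.
#' @return list with `mean`, `sd` (original feature units) and
#'   `extrapolated` (logical per query).
#' @export
predictNorm <- function(model, ages, sexes) {
  .assert(inherits(model, "normativeModel"),
          "model must come from fitNormativeModel()")
  s_new <- .sexToNumeric(sexes)
  .assert(length(ages) == length(s_new),
          "ages and sexes must have equal length")
  extra <- ages < model$age_range[1] | ages > model$age_range[2]
  if (any(extra))
    warning(sprintf("%d quer%s outside the training age range [%g, %g]",
                    sum(extra), if (sum(extra) == 1) "y lies" else "ies lie",
                    model$age_range[1], model$age_range[2]))
  if (model$degenerate) {
    return(list(mean = rep(model$y_center, length(ages)),
                sd = rep(1e-8, length(ages)), extrapolated = extra))
  }
  a_new <- (ages - model$age_center) / model$age_scale
  th <- model$theta
  s2f <- exp(th[1]); la <- exp(th[2]); ls <- exp(th[3])
  s2l <- exp(th[4]); s2n <- exp(th[5])
  Da2 <- outer(model$a, a_new, "-")^2
  Ds2 <- outer(model$s, s_new, "-")^2
  Kstar <- s2f * exp(-0.5 * (Da2 / la^2 + Ds2 / ls^2)) +
    s2l * tcrossprod(model$a, a_new)
  mean_std <- drop(crossprod(Kstar, model$alpha))
  n <- length(model$a)
  K <- .gpKernel(th, outer(model$a, model$a, "-")^2,
                 outer(model$s, model$s, "-")^2, tcrossprod(model$a), n)
  U <- chol(K)
  V <- forwardsolve(t(U), Kstar)
  kss <- s2f + s2l * a_new^2
  var_std <- pmax(kss + s2n - colSums(V^2), 1e-12)
  scl <- if (is.null(model$sd_scale)) 1 else model$sd_scale
  list(mean = model$y_center + model$y_scale * mean_std,
       sd = model$y_scale * scl * sqrt(var_std),
       extrapolated = extra)
}

#' Fit normative models for every feature of a table
#'
#' @param reference a [FeatureTable-class] of the reference population.
#' @param config a [normativeConfig()].
#' @param seed integer; per-feature seeds are derived from it.
#' @return a [NormativeModelSet-class].
#' @export
fitNormativeModelSet <- function(reference, config = normativeConfig(),
                                 seed = 1L) {
  .assert(is(reference, "FeatureTable"), "reference must be a FeatureTable")
  vals <- featureValues(reference)
  pd <- participantData(reference)
  feats <- colnames(vals)
  models <- lapply(seq_along(feats), function(j) {
    fitNormativeModel(vals[, j], pd$age, pd$sex, config,
                      seed = .deriveSeed(seed, j), feature = feats[j])
  })
  names(models) <- feats
  new("NormativeModelSet", models = models, features = feats,
      config = config)
}

setMethod("show", "NormativeModelSet", function(object) {
  ndeg <- sum(vapply(object@models, `[[`, logical(1), "degenerate"))
  cat(sprintf("NormativeModelSet: %d feature model%s (%d degenerate)\n",
              length(object@features),
              if (length(object@features) == 1) "" else "s", ndeg))
  invisible(NULL)
})

#' Standardized deviance (Z-score) profiles
#'
#' Converts each participant's feature values into Z-scores against the
#' per-feature normative models: `Z = (observed - predictive mean) /
#' predictive SD` at the participant's age and sex. Z-scores quantify
#' regional structural deviance independent of age and sex.
#'
#' @param modelSet a [NormativeModelSet-class] covering every feature of
#'   the table.
#' @param table a [FeatureTable-class].
#' @param warn_extrapolation warn when participants fall outside the
#'   normative age range.
#' @return numeric matrix of Z-scores, participants x features.
#' @export
computeZScores <- function(modelSet, table, warn_extrapolation = TRUE) {
  .assert(is(modelSet, "NormativeModelSet"),
          "modelSet must be a NormativeModelSet")
  vals <- featureValues(table)
  pd <- participantData(table)
  missing_ <- setdiff(colnames(vals), modelSet@features)
  .assert(length(missing_) == 0L,
          "no normative model for feature(s): %s",
          paste(missing_, collapse = ", "))
  z <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = dimnames(vals))
  run <- function() {
    for (j in seq_len(ncol(vals))) {
      pr <- predictNorm(modelSet@models[[colnames(vals)[j]]],
                        pd$age, pd$sex)
      z[, j] <<- (vals[, j] - pr$mean) / pr$sd
    }
  }
  if (warn_extrapolation) run() else suppressWarnings(run())
  z
}

#' Serialize / restore a normative model set as JSON
#'
#' Training inputs, targets and hyperparameters are stored at full
#' precision; the posterior weight vector is rebuilt on read, so restored
#' predictions are reproducible.
#'
#' @param modelSet a [NormativeModelSet-class].
#' @param path file path.
#' @export
writeNormativeModelSet <- function(modelSet, path) {
  obj <- list(
    config = modelSet@config[c("restarts", "maxit")],
    features = modelSet@features,
    models = lapply(modelSet@models, function(m) {
      if (m$degenerate)
        list(feature = m$feature, degenerate = TRUE,
             y_center = m$y_center,
             age_center = m$age_center, age_scale = m$age_scale,
             age_range = m$age_range)
      else
        list(feature = m$feature, degenerate = FALSE,
             theta = m$theta, lml = m$lml, sd_scale = m$sd_scale,
             ages = m$a * m$age_scale + m$age_center,
             sexes = m$s, y = m$y,
             age_center = m$age_center, age_scale = m$age_scale,
             y_center = m$y_center, y_scale = m$y_scale,
             age_range = m$age_range)
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeNormativeModelSet
#' @export
readNormativeModelSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- as.character(obj$features)
  models <- lapply(feats, function(f) {
    m <- obj$models[[f]]
    if (isTRUE(m$degenerate)) {
      structure(list(feature = m$feature, degenerate = TRUE,
                     y_center = m$y_center, y_scale = 0,
                     age_center = m$age_center, age_scale = m$age_scale,
                     age_range = as.numeric(m$age_range)),
                class = "normativeModel")
    } else {
      ages <- as.numeric(m$ages); s <- as.numeric(m$sexes)
      y <- as.numeric(m$y); theta <- as.numeric(m$theta)
      a <- (ages - m$age_center) / m$age_scale
      ys <- (y - m$y_center) / m$y_scale
      K <- .gpKernel(theta, outer(a, a, "-")^2, outer(s, s, "-")^2,
                     tcrossprod(a), length(a))
      U <- chol(K)
      structure(list(feature = m$feature, degenerate = FALSE,
                     theta = theta, lml = m$lml,
                     sd_scale = if (is.null(m$sd_scale)) 1
                                else as.numeric(m$sd_scale),
                     alpha = backsolve(U, forwardsolve(t(U), ys)),
                     a = a, s = s, y = y,
                     age_center = m$age_center, age_scale = m$age_scale,
                     y_center = m$y_center, y_scale = m$y_scale,
                     age_range = as.numeric(m$age_range)),
                class = "normativeModel")
    }
  })
  names(models) <- feats
  new("NormativeModelSet", models = models, features = feats,
      config = normativeConfig(restarts = obj$config$restarts,
                               maxit = obj$config$maxit))
}
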