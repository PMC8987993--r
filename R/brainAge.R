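#' @include AllClasses.R AllGenerics.R featureTable.R cascade.R
NULL

#' Hyperparameters for the cascade brain-age network
#'
#' @param layers number of hidden layers (12 by default).
#' @param width units per hidden layer.
#' @param epochs maximum full-batch training epochs.
#' @param lr Adam base learning rate (cosine-decayed over `epochs`).
#' @param val_fraction fraction of the training sample held out to monitor
#'   early stopping (0 disables the split and monitors training loss).
#' @param patience epochs without improvement before stopping.
#' @param tol minimum loss improvement counted as progress.
#' @param weight_decay L2 penalty on the hidden-layer weights and on the
#'   output weights of the hidden units. The direct input-to-output skip
#'   connections are never penalized, so a purely linear age-feature
#'   relationship remains exactly representable at zero penalty cost.
#' @param min_n minimum number of training participants.
#' @return named list of settings.
#' @export
brainAgeHyperparams <- function(layers = 12, width = 16, epochs = 1500,
                                lr = 0.01, val_fraction = 0.1,
                                patience = 200, tol = 1e-6,
                                weight_decay = 1e-3, min_n = 20) {
  .assert(layers >= 1 && width >= 1, "layers and width must be >= 1")
  list(layers = as.integer(layers), width = as.integer(width),
       epochs = as.integer(epochs), lr = lr,
       val_fraction = val_fraction, patience = as.integer(patience),
       tol = tol, weight_decay = weight_decay, min_n = as.integer(min_n))
}

.resolveInputs <- function(features, sexes) {
  if (is(features, "FeatureTable")) {
    x <- featureValues(features)
    if (is.null(sexes)) sexes <- participantData(features)$sex
  } else {
    x <- as.matrix(features)
    .assert(!is.null(colnames(x)), "feature matrix must have column names")
    .assert(!is.null(sexes), "sexes must be given with a plain matrix")
  }
  list(x = x, sex = .sexToNumeric(sexes))
}

.checkModalityContract <- function(x, modality) {
  if (modality == "GM")
    .assert(ncol(x) == 124L,
            "GM model requires 124 features (56 volumes + 68 thicknesses), got %d",
            ncol(x))
  if (modality == "WM")
    .assert(ncol(x) == 90L,
            "WM model requires 90 features (45 GFA + 45 MD), got %d", ncol(x))
}

#' Train a modality-specific brain-age model
#'
#' Fits the cascade feed-forward network to predict chronological age from
#' the regional features plus sex. Inputs are standardized to zero
#' mean/unit SD on the training sample (stored in the model); the age
#' target is standardized internally and predictions are returned in
#' years. Training minimizes mean squared error with full-batch Adam and
#' early stopping; it is deterministic given `seed`.
#'
#' @param features [FeatureTable-class] or numeric matrix
#'   (participants x features with column names).
#' @param ages chronological ages in years (taken from the table's
#'   `colData` when omitted and `features` is a `FeatureTable`).
#' @param sexes participant sex; see [predictAge()].
#' @param hyperparams list from [brainAgeHyperparams()].
#' @param seed integer seed governing weight initialization and the
#'   validation split.
#' @param modality `"auto"` infers GM/WM from the descriptors and enforces
#'   the 124/90 feature contract; `"custom"` accepts any feature set.
#' @return a [BrainAgeModel-class].
#' @export
trainBrainAgeModel <- function(features, ages = NULL, sexes = NULL,
                               hyperparams = brainAgeHyperparams(),
                               seed = 1L, modality = "auto") {
  inp <- .resolveInputs(features, sexes)
  if (is.null(ages) && is(features, "FeatureTable"))
    ages <- participantData(features)$age
  .assert(!is.null(ages), "ages must be supplied")
  ages <- as.numeric(ages)
  .assert(nrow(inp$x) == length(ages) && length(ages) == length(inp$sex),
          "features, ages and sexes must have matching lengths")
  .checkFinite(inp$x, "feature values")
  .checkFinite(ages, "ages")
  .assert(length(unique(ages)) >= 2, "at least 2 distinct ages required")
  .assert(length(ages) >= hyperparams$min_n,
          "need at least %d participants, got %d", hyperparams$min_n,
          length(ages))
  if (modality == "auto") {
    modality <- if (is(features, "FeatureTable")) modality(features)
                else "custom"
    # auto-tag GM/WM only when the full panel is present; reduced panels
    # are treated as custom models rather than contract violations
    if ((modality == "GM" && ncol(inp$x) != 124L) ||
        (modality == "WM" && ncol(inp$x) != 90L)) modality <- "custom"
  }
  .checkModalityContract(inp$x, modality)

  X <- cbind(inp$x, sex = inp$sex)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1  # constant inputs carry no information
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  y_c <- mean(ages); y_s <- stats::sd(ages)
  fit <- .cascadeTrain(Xs, (ages - y_c) / y_s, hyperparams, seed)

  new("BrainAgeModel",
      modality = modality,
      inputNames = colnames(inp$x),
      center = center, scale = scale_,
      yCenter = y_c, yScale = y_s,
      weights = fit$weights,
      hyperparams = hyperparams,
      metadata = list(seed = as.integer(seed), n_train = length(ages),
                      epochs_run = fit$epochs_run,
                      train_curve = fit$train_curve,
                      val_curve = fit$val_curve))
}

#' @rdname predictAge
#' @export
setMethod("predictAge", "BrainAgeModel", function(model, features,
                                                  sexes = NULL) {
  inp <- .resolveInputs(features, sexes)
  .assert(nrow(inp$x) == length(inp$sex),
          "features and sexes must have matching lengths")
  got <- colnames(inp$x)
  want <- model@inputNames
  if (!identical(got, want)) {
    missing_ <- setdiff(want, got)
    extra <- setdiff(got, want)
    if (length(missing_) || length(extra))
      stop("feature mismatch; missing: [",
           paste(missing_, collapse = ", "), "], extra: [",
           paste(extra, collapse = ", "), "]", call. = FALSE)
    inp$x <- inp$x[, want, drop = FALSE]  # same set, different order
  }
  .checkFinite(inp$x, "feature values")
  X <- cbind(inp$x, sex = inp$sex)
  Xs <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  drop(.cascadeForward(model@weights, Xs)) * model@yScale + model@yCenter
})

#' @rdname modality
#' @export
setMethod("modality", "BrainAgeModel", function(x) x@modality)

setMethod("show", "BrainAgeModel", function(object) {
  cat(sprintf("BrainAgeModel (%s): %d features + sex\n", object@modality,
              length(object@inputNames)))
  cat(sprintf("  cascade net: %d layers x %d units; trained %d epochs (seed %d)\n",
              object@hyperparams$layers, object@hyperparams$width,
              object@metadata$epochs_run, object@metadata$seed))
  invisible(NULL)
})

#' Pearson r and mean absolute error of age predictions
#'
#' @param predicted,chronological numeric vectors of equal length (>= 2).
#' @return list with `r` (Pearson correlation; `NA` with a warning when
#'   the chronological ages have zero variance) and `mae` (years).
#' @examples
#' evaluatePredictions(c(3, 1, 2), c(1, 2, 3))
#' @export
evaluatePredictions <- function(predicted, chronological) {
  .assert(length(predicted) == length(chronological),
          "predicted and chronological must have equal length")
  .assert(length(predicted) >= 2, "need at least 2 observations")
  .checkFinite(predicted, "predicted"); .checkFinite(chronological,
                                                     "chronological")
  mae <- mean(abs(predicted - chronological))
  if (stats::sd(chronological) < 1e-12) {
    warning("chronological age has zero variance; r is undefined")
    return(list(r = NA_real_, mae = mae))
  }
  list(r = stats::cor(predicted, chronological), mae = mae)
}

#' k-fold cross-validation of the brain-age model
#'
#' Participants are partitioned into `k` folds of sizes differing by at
#' most one via a seeded random permutation. Each participant is predicted
#' exactly once out-of-fold; pooled Pearson r and MAE are computed over the
#' concatenated out-of-fold predictions.
#'
#' @inheritParams trainBrainAgeModel
#' @param k number of folds (10 by default; `k = n` gives leave-one-out).
#' @return list with `folds` (assignment per participant), `predictions`
#'   (out-of-fold, years), `per_fold` (data.frame of per-fold r/MAE),
#'   `r` and `mae` (pooled).
#' @export
crossValidate <- function(features, ages = NULL, sexes = NULL, k = 10,
                          hyperparams = brainAgeHyperparams(), seed = 1L,
                          modality = "auto") {
  inp <- .resolveInputs(features, sexes)
  if (is.null(ages) && is(features, "FeatureTable"))
    ages <- participantData(features)$age
  ages <- as.numeric(ages)
  n <- length(ages)
  .assert(k >= 2, "k must be >= 2")
  .assert(k <= n, "k (%d) cannot exceed n (%d)", k, n)
  folds <- withr::with_seed(seed, {
    sample(rep(seq_len(k), length.out = n))
  })
  preds <- numeric(n)
  per_fold <- data.frame(fold = seq_len(k), n = NA_integer_,
                         r = NA_real_, mae = NA_real_)
  for (f in seq_len(k)) {
    hold <- which(folds == f)
    model <- trainBrainAgeModel(inp$x[-hold, , drop = FALSE], ages[-hold],
                                inp$sex[-hold], hyperparams,
                                seed = .deriveSeed(seed, f),
                                modality = modality)
    preds[hold] <- predictAge(model, inp$x[hold, , drop = FALSE],
                              inp$sex[hold])
    per_fold$n[f] <- length(hold)
    per_fold$mae[f] <- mean(abs(preds[hold] - ages[hold]))
    per_fold$r[f] <- if (length(hold) >= 2 && stats::sd(ages[hold]) > 0)
      stats::cor(preds[hold], ages[hold]) else NA_real_
  }
  pooled <- evaluatePredictions(preds, ages)
  list(folds = folds, predictions = preds, per_fold = per_fold,
       r = pooled$r, mae = pooled$mae, k = k)
}

#' Serialize / restore a brain-age model as JSON
#'
#' @param model a [BrainAgeModel-class].
#' @param path file path.
#' @return `readBrainAgeModel()` returns the restored model; predictions
#'   from the restored model are identical to the original.
#' @export
writeBrainAgeModel <- function(model, path) {
  obj <- list(
    modality = model@modality,
    inputNames = model@inputNames,
    center = model@center, scale = model@scale,
    yCenter = model@yCenter, yScale = model@yScale,
    hyperparams = model@hyperparams,
    metadata = model@metadata[c("seed", "n_train", "epochs_run")],
    weights = list(
      d = model@weights$d, layers = model@weights$layers,
      width = model@weights$width,
      hidden = lapply(model@weights$hidden, function(l)
        list(W = l$W, b = l$b)),
      wo = model@weights$wo, bo = model@weights$bo))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeBrainAgeModel
#' @export
readBrainAgeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  w <- obj$weights
  layers <- as.integer(w$layers)
  hidden <- lapply(seq_len(layers), function(k) {
    rows <- w$hidden[[k]]$W
    list(W = do.call(rbind, lapply(rows, function(r) unlist(r))),
         b = as.numeric(unlist(w$hidden[[k]]$b)))
  })
  num <- function(x) as.numeric(unlist(x))
  center <- num(obj$center); names(center) <- names(obj$center)
  scale_ <- num(obj$scale); names(scale_) <- names(obj$scale)
  hp <- obj$hyperparams
  new("BrainAgeModel",
      modality = obj$modality,
      inputNames = as.character(unlist(obj$inputNames)),
      center = center, scale = scale_,
      yCenter = num(obj$yCenter), yScale = num(obj$yScale),
      weights = list(hidden = hidden, wo = num(w$wo), bo = num(w$bo),
                     d = as.integer(w$d), layers = layers,
                     width = as.integer(w$width)),
      hyperparams = brainAgeHyperparams(
        layers = hp$layers, width = hp$width, epochs = hp$epochs,
        lr = hp$lr, val_fraction = hp$val_fraction,
        patience = hp$patience, tol = hp$tol,
        weight_decay = hp$weight_decay, min_n = hp$min_n),
      metadata = lapply(obj$metadata, unlist))
}
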