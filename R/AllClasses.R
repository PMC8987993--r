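#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.MODALITY_LEVELS <- c("GM_volume", "GM_thickness", "WM_GFA", "WM_MD")
.HEMISPHERE_LEVELS <- c("left", "right", "midline")
.GROUP_LEVELS <- c("TRAIN", "TEST", "HC", "MSA", "PD")
.CLINICAL_SCORES <- c("UPDRS_I", "UPDRS_II", "UPDRS_III", "UPDRS_total",
                      "UMSARS_I", "UMSARS_II", "UMSARS_total",
                      "HY", "MMSE", "MoCA")

#' FeatureTable: participants x regional MRI features
#'
#' A `FeatureTable` is a [SummarizedExperiment::SummarizedExperiment] whose
#' rows are regional imaging features (gray-matter volumes and cortical
#' thicknesses, or white-matter tract GFA and MD) and whose columns are
#' participants. `rowData()` holds the feature descriptors (`modality`,
#' `region_group`, `hemisphere`); `colData()` holds the participant table
#' (`id`, `age` in years, `sex`, `education`, `group`, optional clinical
#' scores and, for simulated cohorts, the ground-truth brain-age offset
#' `true_offset`).
#'
#' Units: volumes in mL, cortical thickness in mm, GFA unitless in (0, 1),
#' MD in 1e-3 mm^2/s.
#'
#' @seealso [FeatureTable()] for construction, [featureValues()],
#'   [featureDescriptors()], [participantData()] for access.
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!"features" %in% assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  rd <- rowData(object)
  needed <- c("modality", "region_group", "hemisphere")
  missing_rd <- setdiff(needed, colnames(rd))
  if (length(missing_rd))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(missing_rd, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature names must be unique")
  cd <- colData(object)
  missing_cd <- setdiff(c("id", "age", "sex"), colnames(cd))
  if (length(missing_cd))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missing_cd, collapse = ", ")))
  if (ncol(object) > 0 && anyDuplicated(cd$id))
    msg <- c(msg, "participant ids must be unique")
  m <- assay(object, "features")
  if (anyNA(m))
    msg <- c(msg, "feature values must not contain missing values")
  if (length(m) && !all(is.finite(m)))
    msg <- c(msg, "feature values must be finite")
  if (!length(missing_rd) && nrow(object) > 0 && ncol(object) > 0) {
    if (!all(rd$modality %in% .MODALITY_LEVELS))
      msg <- c(msg, paste0("modality must be one of: ",
                           paste(.MODALITY_LEVELS, collapse = ", ")))
    gfa <- rd$modality == "WM_GFA"
    if (any(gfa) && (any(m[gfa, ] <= 0) || any(m[gfa, ] >= 1)))
      msg <- c(msg, "GFA values must lie strictly within (0, 1)")
    pos <- rd$modality %in% c("GM_volume", "WM_MD")
    if (any(pos) && any(m[pos, ] <= 0))
      msg <- c(msg, "volume and MD values must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' Trained brain-age prediction model
#'
#' A cascade feed-forward network regressing chronological age on a fixed,
#' ordered set of standardized regional features plus sex. Every hidden
#' layer receives the raw inputs concatenated with all previous layers'
#' outputs, and the linear output unit again sees the raw inputs, so the
#' architecture contains an exact linear model as a special case.
#'
#' @slot modality character tag ("GM", "WM" or "custom").
#' @slot inputNames ordered feature names the model consumes (sex is
#'   appended internally as the last input).
#' @slot center,scale per-input standardization parameters estimated on the
#'   training sample (the last entry standardizes the sex indicator).
#' @slot yCenter,yScale standardization of the age target in years.
#' @slot weights list of per-layer weight matrices/bias vectors plus the
#'   output weight vector and bias.
#' @slot hyperparams list of architecture/optimizer settings
#'   (see [brainAgeHyperparams()]).
#' @slot metadata list with the training seed, epoch count, and the
#'   training/validation loss curves.
#' @export
setClass("BrainAgeModel",
         representation(modality = "character",
                        inputNames = "character",
                        center = "numeric",
                        scale = "numeric",
                        yCenter = "numeric",
                        yScale = "numeric",
                        weights = "list",
                        hyperparams = "list",
                        metadata = "list"))

setValidity("BrainAgeModel", function(object) {
  msg <- character()
  if (length(object@modality) != 1L)
    msg <- c(msg, "modality must be a single string")
  npar <- length(object@inputNames) + 1L  # + sex
  if (length(object@center) != npar || length(object@scale) != npar)
    msg <- c(msg, "standardization parameters must cover all inputs + sex")
  if (!all(is.finite(object@center)) || !all(is.finite(object@scale)))
    msg <- c(msg, "standardization parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' Linear age-bias correction for PAD scores
#'
#' Slope/intercept of the ordinary least-squares regression of uncorrected
#' PAD on chronological age, fitted on a designated reference sample.
#' Corrected PAD is `pad - (slope * age + intercept)`.
#'
#' @slot slope,intercept regression coefficients (years per year, years).
#' @slot reference label of the sample the correction was fitted on.
#' @export
setClass("BiasCorrection",
         representation(slope = "numeric", intercept = "numeric",
                        reference = "character"))

setValidity("BiasCorrection", function(object) {
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    "slope and intercept must be finite" else TRUE
})

#' A set of per-feature Gaussian-process normative models
#'
#' One exact GP regression per regional feature, fitted on a reference
#' population with age and sex as inputs. The kernel is a sum of a squared
#' exponential over (age, sex) with separate length-scales, a linear kernel
#' over centred age, and white noise; hyperparameters are optimized by
#' maximizing the log marginal likelihood. Predictive SD includes the noise
#' term, so held-out reference Z-scores are calibrated to ~N(0, 1).
#'
#' @slot models named list, one fitted model per feature (hyperparameters,
#'   training inputs/targets, precomputed weight vector, diagnostics).
#' @slot features feature names covered, in table order.
#' @slot config kernel/optimizer configuration used
#'   (see [normativeConfig()]).
#' @export
setClass("NormativeModelSet",
         representation(models = "list", features = "character",
                        config = "list"))

setValidity("NormativeModelSet", function(object) {
  if (!identical(names(object@models), object@features))
    "model list names must match the feature vector" else TRUE
})
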