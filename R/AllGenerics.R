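#' @include AllClasses.R
NULL

#' Predict brain age for new participants
#'
#' @param model a [BrainAgeModel-class].
#' @param features a [FeatureTable-class] or a numeric matrix
#'   (participants x features) whose column names match the model's
#'   `inputNames` exactly.
#' @param sexes participant sex ("male"/"female" or 1/0); taken from the
#'   table's `colData` when `features` is a `FeatureTable`.
#' @return numeric vector of predicted ages in years.
#' @export
setGeneric("predictAge", function(model, features, sexes = NULL)
  standardGeneric("predictAge"))

#' Access the feature value matrix of a FeatureTable
#'
#' @param x a [FeatureTable-class].
#' @return numeric matrix, participants in rows, features in columns.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Access the feature descriptors of a FeatureTable
#'
#' @param x a [FeatureTable-class].
#' @return data.frame with columns `name`, `modality`, `region_group`,
#'   `hemisphere`.
#' @export
setGeneric("featureDescriptors", function(x)
  standardGeneric("featureDescriptors"))

#' Access the participant table of a FeatureTable
#'
#' @param x a [FeatureTable-class].
#' @return data.frame, one row per participant.
#' @export
setGeneric("participantData", function(x) standardGeneric("participantData"))

#' Modality tag of a model or table
#'
#' @param x a [BrainAgeModel-class] or [FeatureTable-class].
#' @return single character string ("GM", "WM" or "custom").
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
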