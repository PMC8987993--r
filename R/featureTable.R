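#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a FeatureTable
#'
#' Bundles a participants-by-features value matrix with its feature
#' descriptors and participant metadata into a validated
#' [FeatureTable-class] (a `SummarizedExperiment` with features in rows and
#' participants in columns).
#'
#' @param values numeric matrix, participants in rows and features in
#'   columns; column names must match `descriptors$name`.
#' @param descriptors data.frame with columns `name`, `modality` (one of
#'   `GM_volume`, `GM_thickness`, `WM_GFA`, `WM_MD`), `region_group` (lobe
#'   for gray matter, fiber system for white matter) and `hemisphere`
#'   (`left`, `right`, `midline`).
#' @param participants data.frame with at least `id`, `age` (years) and
#'   `sex` (`"male"`/`"female"`); optional `education`, `group`, clinical
#'   scores, and `true_offset` for simulated cohorts.
#' @return a [FeatureTable-class].
#' @examples
#' desc <- gmFeatureDescriptors()[1:3, ]
#' part <- data.frame(id = c("s1", "s2"), age = c(30, 60),
#'                    sex = c("male", "female"))
#' vals <- matrix(5 + abs(rnorm(6)), 2, 3,
#'                dimnames = list(part$id, desc$name))
#' ft <- FeatureTable(vals, desc, part)
#' dim(featureValues(ft))
#' @export
FeatureTable <- function(values, descriptors, participants) {
  values <- as.matrix(values)
  .assert(is.numeric(values) || length(values) == 0L,
          "feature values must be numeric")
  descriptors <- as.data.frame(descriptors)
  participants <- as.data.frame(participants)
  .assert(ncol(values) == nrow(descriptors),
          "values has %d feature columns but %d descriptors given",
          ncol(values), nrow(descriptors))
  .assert(nrow(values) == nrow(participants),
          "values has %d rows but %d participants given",
          nrow(values), nrow(participants))
  if (!is.null(colnames(values)))
    .assert(identical(colnames(values), descriptors$name),
            "column names of values must match descriptor names")
  mat <- t(values)
  rownames(mat) <- descriptors$name
  colnames(mat) <- as.character(participants$id)
  se <- SummarizedExperiment(
    assays = list(features = mat),
    rowData = S4Vectors::DataFrame(descriptors, row.names = descriptors$name),
    colData = S4Vectors::DataFrame(participants,
                                   row.names = as.character(participants$id)))
  new("FeatureTable", se)
}

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureTable", function(x) {
  t(assay(x, "features"))
})

#' @rdname featureDescriptors
#' @export
setMethod("featureDescriptors", "FeatureTable", function(x) {
  as.data.frame(rowData(x))
})

#' @rdname participantData
#' @export
setMethod("participantData", "FeatureTable", function(x) {
  as.data.frame(colData(x))
})

#' @rdname modality
#' @export
setMethod("modality", "FeatureTable", function(x) {
  mods <- unique(rowData(x)$modality)
  if (all(mods %in% c("GM_volume", "GM_thickness"))) "GM"
  else if (all(mods %in% c("WM_GFA", "WM_MD"))) "WM"
  else "custom"
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable (%s): %d features x %d participants\n",
              modality(object), nrow(object), ncol(object)))
  tab <- table(rowData(object)$modality)
  cat("  features:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
  if (ncol(object) > 0) {
    a <- colData(object)$age
    cat(sprintf("  age: %.1f-%.1f years (mean %.1f)\n",
                min(a), max(a), mean(a)))
    if ("group" %in% colnames(colData(object))) {
      g <- table(colData(object)$group)
      cat("  groups:", paste(sprintf("%s=%d", names(g), g),
                             collapse = ", "), "\n")
    }
  }
  invisible(NULL)
})
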