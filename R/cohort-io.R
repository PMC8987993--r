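#' @include featureTable.R
NULL

#' Write / read a cohort as delimited text
#'
#' A cohort directory holds `participants.csv` plus, per modality, a
#' feature value file (`gm.csv` / `wm.csv`, one row per participant keyed
#' by `id`) and a descriptor file (`gm_descriptors.csv` /
#' `wm_descriptors.csv`). Values are written at full precision so that a
#' write/read round trip is lossless.
#'
#' @param cohort list with `participants`, `gm`, `wm` as returned by
#'   [simulateNormativePopulation()] or [simulateClinicalCohort()].
#' @param path directory to create/use.
#' @param sep field separator (comma default).
#' @return `writeCohort()` returns `path` invisibly; `readCohort()`
#'   returns a cohort list of the same shape.
#' @examples
#' coh <- simulateNormativePopulation(5, seed = 1)
#' d <- file.path(tempdir(), "cohort-demo")
#' writeCohort(coh, d)
#' coh2 <- readCohort(d)
#' all.equal(featureValues(coh$gm), featureValues(coh2$gm))
#' @export
writeCohort <- function(cohort, path, sep = ",") {
  .assert(all(c("participants", "gm", "wm") %in% names(cohort)),
          "cohort must contain 'participants', 'gm' and 'wm'")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fwrite_ <- function(df, file)
    data.table::fwrite(df, file.path(path, file), sep = sep)
  fwrite_(cohort$participants, "participants.csv")
  for (tag in c("gm", "wm")) {
    ft <- cohort[[tag]]
    vals <- as.data.frame(featureValues(ft))
    vals <- cbind(id = participantData(ft)$id, vals)
    fwrite_(vals, paste0(tag, ".csv"))
    fwrite_(featureDescriptors(ft), paste0(tag, "_descriptors.csv"))
  }
  invisible(path)
}

.readNumericColumns <- function(df, cols, file) {
  for (cn in cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      .assert(length(bad) == 0L,
              "non-numeric value in %s, column '%s', row %d",
              file, cn, if (length(bad)) bad[1] else 0L)
      df[[cn]] <- num
    }
    na <- which(is.na(df[[cn]]))
    .assert(length(na) == 0L, "missing value in %s, column '%s', row %d",
            file, cn, if (length(na)) na[1] else 0L)
  }
  df
}

#' @rdname writeCohort
#' @export
readCohort <- function(path, sep = ",") {
  .assert(dir.exists(path), "cohort directory not found: %s", path)
  fread_ <- function(file, has_id = TRUE) {
    f <- file.path(path, file)
    .assert(file.exists(f), "missing cohort file: %s", f)
    cc <- if (has_id) list(character = "id") else NULL
    as.data.frame(data.table::fread(f, sep = sep, header = TRUE,
                                    colClasses = cc))
  }
  participants <- fread_("participants.csv")
  miss <- setdiff(c("id", "age", "sex"), colnames(participants))
  .assert(length(miss) == 0L, "participants.csv lacks column(s): %s",
          paste(miss, collapse = ", "))
  out <- list(participants = participants)
  for (tag in c("gm", "wm")) {
    desc <- fread_(paste0(tag, "_descriptors.csv"), has_id = FALSE)
    vals <- fread_(paste0(tag, ".csv"))
    .assert("id" %in% colnames(vals), "%s.csv lacks an 'id' column", tag)
    missing_feats <- setdiff(desc$name, colnames(vals))
    .assert(length(missing_feats) == 0L,
            "%s.csv is missing feature column(s): %s", tag,
            paste(missing_feats, collapse = ", "))
    vals <- .readNumericColumns(vals, desc$name, paste0(tag, ".csv"))
    .assert(identical(vals$id, participants$id),
            "%s.csv ids do not match participants.csv", tag)
    m <- as.matrix(vals[, desc$name, drop = FALSE])
    rownames(m) <- vals$id
    out[[tag]] <- FeatureTable(m, desc, participants)
  }
  out
}
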