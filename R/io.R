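# Plain-text readers/writers for the pipeline's file contracts.

#' Write / read an abundance matrix as TSV
#'
#' Layout: first column `protein_id`, remaining columns one per sample
#' (linear-scale abundances, empty cells for missing). Group labels travel
#' in a separate two-column metadata CSV (`sample_id,group`).
#'
#' @param x an [AbundanceExperiment-class].
#' @param path output TSV path.
#' @param metaPath optional path for the sample metadata CSV.
#' @return `path`, invisibly.
#' @export
writeAbundanceTsv <- function(x, path, metaPath = NULL) {
  stopifnot(is(x, "AbundanceExperiment"))
  df <- data.frame(protein_id = rownames(x), abundance(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metaPath)) {
    utils::write.csv(data.frame(sample_id = colnames(x),
                                group = as.character(sampleGroups(x))),
                     metaPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname writeAbundanceTsv
#' @param matrixPath TSV written by [writeAbundanceTsv()] (or any matrix
#'   with the same layout).
#' @param groups named group vector, or path to a `sample_id,group` CSV.
#' @export
readAbundanceTsv <- function(matrixPath, groups) {
  df <- utils::read.delim(matrixPath, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "protein_id")
    stop("first column must be 'protein_id'", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$protein_id
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    meta <- utils::read.csv(groups, stringsAsFactors = FALSE)
    groups <- stats::setNames(meta$group, meta$sample_id)
  }
  AbundanceExperiment(m, groups)
}

#' Write / read a survival cohort as CSV
#'
#' Header contract: `subject_id,time_months,event,<biomarkers...>,age,sex,
#' tc,hdl,sbp,smoker,diabetes`.
#'
#' @param cohort a [SurvivalCohort-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  stopifnot(is(cohort, "SurvivalCohort"))
  d <- cohortData(cohort)
  cols <- c("subject_id", "time_months", "event",
            biomarkerNames(cohort), .FRAMINGHAM_COVARIATES)
  utils::write.csv(d[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @param biomarkers biomarker column names; by default every column
#'   between `event` and `age`.
#' @export
readCohortCsv <- function(path, biomarkers = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(biomarkers)) {
    fixed <- c("subject_id", "time_months", "event", .FRAMINGHAM_COVARIATES)
    biomarkers <- setdiff(names(d), fixed)
  }
  SurvivalCohort(d, biomarkerNames = biomarkers)
}

write_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
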