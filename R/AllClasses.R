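#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
NULL

#' Protein abundance matrix with event / non-event sample groups
#'
#' `AbundanceExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] and holds a quantified
#' protein relative-abundance matrix (linear scale, proteins in rows,
#' plasma samples in columns; entries may be `NA`). `colData()` carries a
#' `group` factor with levels `"event"` and `"non_event"`; when the object
#' was simulated, `metadata()$truth` records the identifiers of the
#' proteins that carry a planted differential signal.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [AbundanceExperiment()], [simulateDiscovery()], [depTable()]
#' @exportClass AbundanceExperiment
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "protein identifiers (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  grp <- colData(object)$group
  if (is.null(grp)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    grp <- as.factor(grp)
    if (!setequal(levels(grp), c("event", "non_event")))
      msg <- c(msg, "group levels must be exactly 'event' and 'non_event'")
    else if (any(table(grp) == 0L) || anyNA(grp))
      msg <- c(msg, "both groups must be non-empty and labels complete")
  }
  tr <- metadata(object)$truth
  if (!is.null(tr) && !all(tr %in% rownames(object)))
    msg <- c(msg, "metadata()$truth must be a subset of the protein ids")
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceExperiment
#'
#' @param values numeric matrix, proteins x samples, linear-scale relative
#'   abundances; `NA` marks a missing quantification. Must carry unique
#'   rownames (protein accessions) and colnames (sample ids).
#' @param groups character or factor of length `ncol(values)` with values
#'   `"event"` / `"non_event"`, or a named vector mapping sample id to group.
#' @param truth optional character vector of planted differential protein
#'   ids (used by the simulators; empty for real data).
#' @return an [AbundanceExperiment-class] object.
#' @examples
#' m <- matrix(2^rnorm(20, 20), 4, 5,
#'             dimnames = list(paste0("P", 1:4), paste0("S", 1:5)))
#' ae <- AbundanceExperiment(m, c("event", "event", "event",
#'                                "non_event", "non_event"))
#' sampleGroups(ae)
#' @export
AbundanceExperiment <- function(values, groups, truth = character()) {
  values <- as.matrix(values)
  if (!is.null(names(groups)) && !is.null(colnames(values))) {
    groups <- groups[colnames(values)]
  }
  grp <- factor(as.character(groups), levels = c("event", "non_event"))
  se <- SummarizedExperiment(
    assays = SimpleList(abundance = values),
    colData = DataFrame(group = grp, row.names = colnames(values))
  )
  obj <- new("AbundanceExperiment", se)
  metadata(obj)$truth <- as.character(truth)
  validObject(obj)
  obj
}

#' Synthetic survival cohort for biomarker validation
#'
#' One row per subject: follow-up time in months, MACE event indicator,
#' plasma biomarker levels, and the seven Framingham covariates
#' (`age`, `sex`, `tc`, `hdl`, `sbp`, `smoker`, `diabetes`). `truth` keeps
#' the generating parameters when the cohort was simulated.
#'
#' @slot data data.frame with columns `subject_id`, `time_months`, `event`,
#'   one column per biomarker, then the covariates.
#' @slot biomarkerNames character, the biomarker column names.
#' @slot truth list of generating parameters (empty for real data).
#' @seealso [SurvivalCohort()], [simulateValidation()], [fitCox()]
#' @exportClass SurvivalCohort
setClass("SurvivalCohort",
  representation(data = "data.frame", biomarkerNames = "character",
                 truth = "list"))

.FRAMINGHAM_COVARIATES <- c("age", "sex", "tc", "hdl", "sbp",
                            "smoker", "diabetes")

setValidity("SurvivalCohort", function(object) {
  d <- object@data
  msg <- character()
  need <- c("subject_id", "time_months", "event",
            object@biomarkerNames, .FRAMINGHAM_COVARIATES)
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(sprintf("missing cohort columns: %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$subject_id))
    msg <- c(msg, "subject ids must be unique")
  if (any(!is.finite(d$time_months)) || any(d$time_months <= 0))
    msg <- c(msg, "all follow-up times must be positive")
  if (!all(d$event %in% c(0, 1)))
    msg <- c(msg, "event indicator must be 0/1")
  cov <- d[, .FRAMINGHAM_COVARIATES, drop = FALSE]
  if (anyNA(cov))
    msg <- c(msg, "covariates must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' Construct a SurvivalCohort
#'
#' @param data data.frame with columns `subject_id`, `time_months`, `event`,
#'   biomarker levels and the Framingham covariates
#'   `age, sex, tc, hdl, sbp, smoker, diabetes`.
#' @param biomarkerNames character vector naming the biomarker columns.
#' @param truth optional list of generating parameters.
#' @return a [SurvivalCohort-class] object.
#' @export
SurvivalCohort <- function(data, biomarkerNames = character(), truth = list()) {
  obj <- new("SurvivalCohort", data = as.data.frame(data),
             biomarkerNames = as.character(biomarkerNames), truth = truth)
  validObject(obj)
  obj
}

#' Incremental feature selection curve
#'
#' The sequence of (subset size k, cross-validated Matthews coefficient)
#' produced by scoring nested top-k subsets of a feature ranking, and the
#' selected size: the smallest k attaining the curve maximum (the
#' "first-maximum" rule).
#'
#' @slot points data.frame with columns `k` and `mcc`.
#' @slot selectedK integer, smallest k with maximal MCC.
#' @slot featureIds character, the ranked feature identifiers scored.
#' @slot seed integer seed the cross-validation was run under.
#' @seealso [ifsSelect()]
#' @exportClass IFSCurve
setClass("IFSCurve",
  representation(points = "data.frame", selectedK = "integer",
                 featureIds = "character", seed = "integer"))

setValidity("IFSCurve", function(object) {
  p <- object@points
  if (!all(c("k", "mcc") %in% names(p)))
    return("points needs columns 'k' and 'mcc'")
  if (nrow(p) == 0L) return("empty curve")
  first_max <- p$k[which.max(p$mcc)]  # which.max returns the first maximum
  if (object@selectedK != first_max)
    return("selectedK must be the smallest k attaining the maximal MCC")
  TRUE
})

#' Fitted Cox proportional-hazards summary
#'
#' Wraps a [survival::coxph] fit with the per-term table the validation
#' stage reports: log hazard ratio, standard error, HR with Wald 95% CI,
#' Wald p-value, plus the overall score (log-rank) test.
#'
#' @slot fit the underlying `coxph` object.
#' @slot table data.frame with one row per term: `term`, `beta`, `se`,
#'   `hr`, `ci_lower`, `ci_upper`, `p`.
#' @slot logrankP numeric, overall score-test p-value.
#' @slot n,nEvents integers: subjects and observed events.
#' @seealso [fitCox()], [rescaleHR()]
#' @exportClass CoxFit
setClass("CoxFit",
  representation(fit = "ANY", table = "data.frame", logrankP = "numeric",
                 n = "integer", nEvents = "integer"))
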