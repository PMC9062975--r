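#' Accessors for ProteoMACE containers
#'
#' @param x an [AbundanceExperiment-class], [SurvivalCohort-class],
#'   [IFSCurve-class] or [CoxFit-class] object, as documented per method.
#' @name accessors
NULL

#' @describeIn accessors linear-scale abundance matrix (proteins x samples).
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @describeIn accessors factor of sample group labels, named by sample id.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @describeIn accessors ids of proteins carrying a planted differential
#'   signal (empty character for real data).
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' @describeIn accessors the per-subject cohort data.frame.
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @describeIn accessors biomarker column names of a cohort.
#' @export
setGeneric("biomarkerNames", function(x) standardGeneric("biomarkerNames"))

#' @describeIn accessors the (k, MCC) points of an IFS curve.
#' @export
setGeneric("ifsPoints", function(x) standardGeneric("ifsPoints"))

#' @describeIn accessors the selected subset size (first-maximum rule).
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @describeIn accessors ids of the selected top-k features.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @describeIn accessors per-term Cox coefficient table.
#' @export
setGeneric("coxTable", function(x) standardGeneric("coxTable"))

setMethod("abundance", "AbundanceExperiment",
          function(x) assay(x, "abundance"))

setMethod("sampleGroups", "AbundanceExperiment", function(x) {
  g <- colData(x)$group
  names(g) <- colnames(x)
  g
})

setMethod("plantedTruth", "AbundanceExperiment", function(x) {
  tr <- metadata(x)$truth
  if (is.null(tr)) character() else tr
})

setMethod("cohortData", "SurvivalCohort", function(x) x@data)
setMethod("biomarkerNames", "SurvivalCohort", function(x) x@biomarkerNames)

setMethod("ifsPoints", "IFSCurve", function(x) x@points)
setMethod("selectedK", "IFSCurve", function(x) x@selectedK)
setMethod("selectedFeatures", "IFSCurve",
          function(x) x@featureIds[seq_len(x@selectedK)])

setMethod("coxTable", "CoxFit", function(x) x@table)

#' @export
setMethod("show", "AbundanceExperiment", function(object) {
  cat("AbundanceExperiment:", nrow(object), "proteins x",
      ncol(object), "samples\n")
  tab <- table(colData(object)$group)
  cat("  groups: event =", tab[["event"]],
      ", non_event =", tab[["non_event"]], "\n")
  nmiss <- sum(is.na(assay(object, "abundance")))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(assay(object, "abundance"))))
  tr <- plantedTruth(object)
  if (length(tr)) cat("  planted differential proteins:", length(tr), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "SurvivalCohort", function(object) {
  d <- object@data
  cat("SurvivalCohort:", nrow(d), "subjects,",
      sum(d$event), sprintf("events (%.1f%%)\n", 100 * mean(d$event)))
  cat("  follow-up (months): median", round(stats::median(d$time_months), 1),
      "max", round(max(d$time_months), 1), "\n")
  cat("  biomarkers:", paste(object@biomarkerNames, collapse = ", "), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "IFSCurve", function(object) {
  cat("IFSCurve over k = 1..", nrow(object@points), "\n", sep = "")
  cat(sprintf("  selected k = %d (first maximum, MCC = %.4f)\n",
              object@selectedK,
              object@points$mcc[object@points$k == object@selectedK]))
  cat("  selected features:",
      paste(selectedFeatures(object), collapse = ", "), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "CoxFit", function(object) {
  cat("CoxFit:", object@n, "subjects,", object@nEvents, "events\n")
  tab <- object@table
  tab$hr <- sprintf("%.3f (%.3f-%.3f)", tab$hr, tab$ci_lower, tab$ci_upper)
  print(tab[, c("term", "beta", "se", "hr", "p")], row.names = FALSE,
        digits = 4)
  cat(sprintf("  overall score (log-rank) p = %.4g\n", object@logrankP))
  invisible(NULL)
})
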