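#' @importFrom survival coxph Surv survdiff
NULL

cohort_or_df <- function(cohort) {
  if (is(cohort, "SurvivalCohort")) cohortData(cohort)
  else as.data.frame(cohort)
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood fit (Efron tie handling by default) of
#' `Surv(time_months, event) ~ terms` via [survival::coxph], with per-term
#' Wald statistics and the overall score test — which for a single binary
#' covariate coincides with the log-rank test, the pairing used when hazard
#' ratios are reported with log-rank p-values.
#'
#' @param cohort a [SurvivalCohort-class] or a data.frame with
#'   `time_months` and `event` columns.
#' @param terms character vector of covariate column names.
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return a [CoxFit-class].
#' @examples
#' sc <- simulateValidation(nSubjects = 300, seed = 3)
#' fitCox(sc, c("EPCR", "CETP"))
#' @export
fitCox <- function(cohort, terms, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  d <- cohort_or_df(cohort)
  miss <- setdiff(c("time_months", "event", terms), names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (sum(d$event) < 2L) stop("need at least 2 events", call. = FALSE)
  if (any(d$time_months <= 0)) stop("times must be positive", call. = FALSE)
  const <- terms[vapply(terms, function(tm) length(unique(d[[tm]])) < 2L,
                        logical(1))]
  if (length(const))
    stop("constant covariate(s): ", paste(const, collapse = ", "),
         call. = FALSE)

  fml <- stats::as.formula(paste("Surv(time_months, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- coxph(fml, data = d, ties = ties)
  if (!is.null(fit$info) || anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; aliased term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(fit$iter) && !is.null(fit$iter[1]) &&
      fit$iter[1] >= 100L)
    stop("Cox fit did not converge after ", fit$iter[1], " iterations",
         call. = FALSE)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- 1.959963984540054
  tab <- data.frame(term = names(beta), beta = unname(beta),
                    se = unname(se), hr = exp(unname(beta)),
                    ci_lower = exp(unname(beta) - z * unname(se)),
                    ci_upper = exp(unname(beta) + z * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
                    stringsAsFactors = FALSE)
  sc <- summary(fit)$sctest
  new("CoxFit", fit = fit, table = tab,
      logrankP = unname(sc["pvalue"]),
      n = as.integer(fit$n), nEvents = as.integer(fit$nevent))
}

#' Rescale a hazard ratio to per-k-units
#'
#' Converts a Cox coefficient fitted on raw measurement units into the
#' hazard ratio per `k` units: `hr_k = exp(k * beta)` with Wald CI
#' `exp(k * (beta +/- 1.96 * se))` — the convention under which, e.g., a
#' biomarker HR is reported "per 10" or "per 100" units. `k = 1` is the
#' identity and `hr_k = hr_1^k` exactly.
#'
#' @param fit a [CoxFit-class].
#' @param term covariate name present in the fit.
#' @param k positive units multiplier.
#' @return named numeric: `hr`, `ci_lower`, `ci_upper`.
#' @examples
#' sc <- simulateValidation(nSubjects = 300, seed = 3)
#' fit <- fitCox(sc, "EPCR")
#' rescaleHR(fit, "EPCR", 10)
#' @export
rescaleHR <- function(fit, term, k) {
  stopifnot(is(fit, "CoxFit"))
  if (!(length(k) == 1L && is.finite(k) && k > 0))
    stop("'k' must be a positive number", call. = FALSE)
  row <- fit@table[fit@table$term == term, ]
  if (nrow(row) != 1L)
    stop("unknown term '", term, "'; fitted terms: ",
         paste(fit@table$term, collapse = ", "), call. = FALSE)
  z <- 1.959963984540054
  c(hr = exp(k * row$beta),
    ci_lower = exp(k * (row$beta - z * row$se)),
    ci_upper = exp(k * (row$beta + z * row$se)))
}

#' Log-rank test between survival groups
#'
#' Standard log-rank chi-square comparing the survival distributions of two
#' or more groups, via [survival::survdiff].
#'
#' @param cohort a [SurvivalCohort-class] or data.frame with
#'   `time_months`, `event` and the grouping column.
#' @param groupVar name of the grouping column.
#' @return list with `chi2`, `df`, `p`.
#' @export
logrankTest <- function(cohort, groupVar) {
  d <- cohort_or_df(cohort)
  if (!groupVar %in% names(d))
    stop("no column '", groupVar, "' in cohort", call. = FALSE)
  g <- d[[groupVar]]
  if (length(unique(g)) < 2L)
    stop("log-rank test needs at least 2 groups", call. = FALSE)
  fml <- stats::as.formula(paste("Surv(time_months, event) ~", groupVar))
  sd <- survdiff(fml, data = d)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox linear-predictor risk score
#'
#' Refits a Cox model on the cohort with the given terms and returns the
#' centered linear predictor as a per-subject risk score. With the seven
#' Framingham covariates this is the baseline CHD risk model; adding the
#' candidate biomarkers gives the combined model compared by
#' [delongTest()].
#'
#' @inheritParams fitCox
#' @return numeric vector of scores (one per subject, cohort order), with
#'   the [CoxFit-class] attached as attribute `fit`.
#' @seealso [framinghamCovariates()]
#' @export
buildRiskScore <- function(cohort, terms) {
  d <- cohort_or_df(cohort)
  fit <- fitCox(d, terms)
  lp <- stats::predict(fit@fit, type = "lp")  # centered by coxph
  score <- as.numeric(lp)
  attr(score, "fit") <- fit
  score
}

#' Names of the seven Framingham CHD covariates
#'
#' Age, sex, total cholesterol, HDL cholesterol, systolic blood pressure,
#' current smoking, and diabetes status — the confounder set of the
#' baseline risk model.
#'
#' @return character vector of cohort column names.
#' @export
framinghamCovariates <- function() .FRAMINGHAM_COVARIATES
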