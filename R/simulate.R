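#' Simulate a discovery proteome matrix
#'
#' Generates a quantified plasma-proteome relative-abundance matrix with the
#' statistical structure the downstream analysis assumes: a two-group
#' case/control design (`event` vs `non_event`), log-normal abundances,
#' a planted subset of differential proteins whose event-group log2 mean is
#' shifted by `log2Effect` with a random sign per protein, and
#' missing-completely-at-random dropouts. Defaults mirror the emulated study
#' design: 19 + 19 samples, 783 quantified proteins, 57 planted
#' differential proteins.
#'
#' @param nPerGroup samples per group.
#' @param nProteins number of quantified proteins.
#' @param nDep number of planted differential proteins (`<= nProteins`).
#' @param log2Effect mean |log2 fold change| of planted proteins.
#' @param baseLog2Mean grand mean of per-protein baseline log2 abundance.
#' @param baseLog2Sd between-protein SD of baseline log2 abundances.
#' @param noiseSd within-group measurement SD on the log2 scale.
#' @param missingRate probability in `[0, 1)` that any entry is missing.
#' @param seed integer seed; identical arguments give bit-identical output.
#' @return an [AbundanceExperiment-class]; `plantedTruth()` lists the
#'   differential protein ids.
#' @examples
#' ae <- simulateDiscovery(nPerGroup = 10, nProteins = 50, nDep = 5, seed = 1)
#' ae
#' @export
simulateDiscovery <- function(nPerGroup = 19, nProteins = 783, nDep = 57,
                              log2Effect = 0.6, baseLog2Mean = 20,
                              baseLog2Sd = 1.5, noiseSd = 0.5,
                              missingRate = 0.1, seed = 1) {
  assert_positive_int(nPerGroup, "nPerGroup")
  assert_positive_int(nProteins, "nProteins")
  if (nDep < 0 || nDep != floor(nDep))
    stop("'nDep' must be a non-negative integer", call. = FALSE)
  if (nDep > nProteins)
    stop(sprintf("invalid spec: nDep (%d) exceeds nProteins (%d)",
                 nDep, nProteins), call. = FALSE)
  if (log2Effect <= 0 && nDep > 0)
    stop("'log2Effect' must be positive", call. = FALSE)
  if (noiseSd <= 0 || baseLog2Sd <= 0)
    stop("'noiseSd' and 'baseLog2Sd' must be positive", call. = FALSE)
  assert_fraction(missingRate, "missingRate", open = FALSE)

  with_seed(seed, {
    protein_ids <- sprintf("P%04d", seq_len(nProteins))
    sample_ids <- c(sprintf("EV%02d", seq_len(nPerGroup)),
                    sprintf("NE%02d", seq_len(nPerGroup)))
    groups <- rep(c("event", "non_event"), each = nPerGroup)

    base_mu <- stats::rnorm(nProteins, baseLog2Mean, baseLog2Sd)
    log2vals <- matrix(stats::rnorm(nProteins * 2L * nPerGroup, mean = base_mu,
                                    sd = noiseSd),
                       nrow = nProteins, ncol = 2L * nPerGroup,
                       dimnames = list(protein_ids, sample_ids))

    truth <- character()
    if (nDep > 0) {
      dep_idx <- sort(sample.int(nProteins, nDep))
      truth <- protein_ids[dep_idx]
      sign <- sample(c(-1, 1), nDep, replace = TRUE)
      shift <- sign * log2Effect
      log2vals[dep_idx, groups == "event"] <-
        log2vals[dep_idx, groups == "event"] + shift
      attr(truth, "log2fc") <- stats::setNames(shift, truth)
    }

    values <- 2^log2vals
    if (missingRate > 0) {
      values[stats::runif(length(values)) < missingRate] <- NA_real_
    }
    ae <- AbundanceExperiment(values, stats::setNames(groups, sample_ids),
                              truth = truth)
    metadata(ae)$planted_log2fc <- attr(truth, "log2fc")
    metadata(ae)$spec <- list(nPerGroup = nPerGroup, nProteins = nProteins,
                              nDep = nDep, log2Effect = log2Effect,
                              baseLog2Mean = baseLog2Mean,
                              baseLog2Sd = baseLog2Sd, noiseSd = noiseSd,
                              missingRate = missingRate, seed = seed)
    ae
  })
}

# Default biomarker panel: synthetic levels loosely on an ELISA ng/mL scale.
.DEFAULT_BIOMARKERS <- list(
  EPCR = c(mean = 100, sd = 25),
  CETP = c(mean = 1500, sd = 400),
  CPB2 = c(mean = 900, sd = 250)
)

# Default covariate effects (log HR per SD for continuous terms, per level
# for binary terms): plausible epidemiological magnitudes so the Framingham
# baseline model carries real but moderate signal.
.DEFAULT_COVARIATE_EFFECTS <- c(age = 0.35, sex = 0.25, tc = 0.10,
                                hdl = -0.20, sbp = 0.15, smoker = 0.30,
                                diabetes = 0.25)

#' Simulate a prospective validation cohort
#'
#' Draws subjects with Framingham covariates and biomarker levels, then
#' generates MACE event times from an exponential proportional-hazards model
#' whose linear predictor combines per-SD biomarker log hazard ratios and
#' covariate effects. The baseline rate is calibrated by bisection so the
#' expected realized event fraction under administrative censoring matches
#' `targetEventFraction`. Defaults emulate the validation design: 352
#' subjects, 24.3% event rate, ~42-month average follow-up (censoring at 48
#' months), biomarkers EPCR / CETP / CPB2.
#'
#' Covariate distributions follow the reported validation cohort: age ~
#' N(81, 9.3) years (truncated at 65), total cholesterol ~ N(4.0, 0.78)
#' mmol/L, HDL-C ~ N(1.37, 0.48) mmol/L, systolic BP ~ N(133, 17) mmHg,
#' smoking 12%, diabetes 37%. Sex is mixed (70% male) so the covariate is
#' non-degenerate in the refit baseline model.
#'
#' @param nSubjects cohort size.
#' @param targetEventFraction target event fraction in `(0, 1)`.
#' @param logHrPerSd named numeric: true log hazard ratio per 1 SD of each
#'   biomarker. Names define the biomarker panel; names present in
#'   `.DEFAULT_BIOMARKERS` (EPCR, CETP, CPB2) use those level
#'   distributions, others default to mean 100, sd 25.
#' @param covariateEffects named numeric of log HRs for the seven Framingham
#'   covariates (per SD for continuous, per level for binary); zero for
#'   omitted names.
#' @param adminCensorTime administrative censoring time in months.
#' @param seed integer seed.
#' @return a [SurvivalCohort-class]; `@truth` stores the generating
#'   parameters including the calibrated baseline rate.
#' @examples
#' sc <- simulateValidation(nSubjects = 200, seed = 1)
#' sc
#' @export
simulateValidation <- function(nSubjects = 352, targetEventFraction = 0.243,
                               logHrPerSd = c(EPCR = 0.4, CETP = 0.3,
                                              CPB2 = 0.0),
                               covariateEffects = .DEFAULT_COVARIATE_EFFECTS,
                               adminCensorTime = 48, seed = 1) {
  assert_positive_int(nSubjects, "nSubjects")
  if (!(length(targetEventFraction) == 1L && is.finite(targetEventFraction) &&
        targetEventFraction > 0 && targetEventFraction < 1))
    stop("invalid spec: 'targetEventFraction' must lie in (0, 1)",
         call. = FALSE)
  if (adminCensorTime <= 0)
    stop("'adminCensorTime' must be positive", call. = FALSE)
  if (is.null(names(logHrPerSd)) || any(!nzchar(names(logHrPerSd))))
    stop("'logHrPerSd' must be a named vector", call. = FALSE)
  bad <- setdiff(names(covariateEffects), .FRAMINGHAM_COVARIATES)
  if (length(bad))
    stop("unknown covariate effect(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  with_seed(seed, {
    n <- as.integer(nSubjects)
    cov <- data.frame(
      age = pmax(65, stats::rnorm(n, 81, 9.3)),
      sex = stats::rbinom(n, 1L, 0.7),
      tc = pmax(1.5, stats::rnorm(n, 4.0, 0.78)),
      hdl = pmax(0.4, stats::rnorm(n, 1.37, 0.48)),
      sbp = pmax(85, stats::rnorm(n, 133, 17)),
      smoker = stats::rbinom(n, 1L, 0.12),
      diabetes = stats::rbinom(n, 1L, 0.37)
    )

    bm_names <- names(logHrPerSd)
    bm_params <- lapply(bm_names, function(nm) {
      if (nm %in% names(.DEFAULT_BIOMARKERS)) .DEFAULT_BIOMARKERS[[nm]]
      else c(mean = 100, sd = 25)
    })
    names(bm_params) <- bm_names
    bm <- vapply(bm_names, function(nm) {
      stats::rnorm(n, bm_params[[nm]][["mean"]], bm_params[[nm]][["sd"]])
    }, numeric(n))
    bm <- matrix(bm, nrow = n, dimnames = list(NULL, bm_names))

    # linear predictor: biomarkers per true SD; continuous covariates per SD
    # of their generating distribution; binary covariates per level
    eta <- numeric(n)
    for (nm in bm_names) {
      z <- (bm[, nm] - bm_params[[nm]][["mean"]]) / bm_params[[nm]][["sd"]]
      eta <- eta + logHrPerSd[[nm]] * z
    }
    cov_scale <- c(age = 9.3, sex = 1, tc = 0.78, hdl = 0.48, sbp = 17,
                   smoker = 1, diabetes = 1)
    cov_center <- c(age = 81, sex = 0, tc = 4.0, hdl = 1.37, sbp = 133,
                    smoker = 0, diabetes = 0)
    for (nm in names(covariateEffects)) {
      z <- (cov[[nm]] - cov_center[[nm]]) / cov_scale[[nm]]
      eta <- eta + covariateEffects[[nm]] * z
    }

    # calibrate baseline exponential rate: expected event fraction under
    # administrative censoring is mean(1 - exp(-lambda0 * e^eta * C)),
    # monotone increasing in lambda0 -> bisection on log10(lambda0)
    frac_at <- function(log10_lambda0) {
      mean(1 - exp(-10^log10_lambda0 * exp(eta) * adminCensorTime))
    }
    lo <- -12; hi <- 4
    for (i in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (frac_at(mid) < targetEventFraction) lo <- mid else hi <- mid
    }
    lambda0 <- 10^((lo + hi) / 2)

    u <- stats::runif(n)
    t_event <- -log(u) / (lambda0 * exp(eta))
    event <- as.integer(t_event <= adminCensorTime)
    time <- pmin(t_event, adminCensorTime)
    time <- pmax(time, 1e-6)  # guard against a zero from underflow

    d <- data.frame(subject_id = sprintf("V%04d", seq_len(n)),
                    time_months = time, event = event)
    d <- cbind(d, as.data.frame(bm), cov)
    SurvivalCohort(d, biomarkerNames = bm_names,
                   truth = list(logHrPerSd = logHrPerSd,
                                covariateEffects = covariateEffects,
                                biomarkerParams = bm_params,
                                baselineRate = lambda0,
                                targetEventFraction = targetEventFraction,
                                adminCensorTime = adminCensorTime,
                                seed = seed))
  })
}
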