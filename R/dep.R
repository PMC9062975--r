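#' Welch's unequal-variance t-test with untestable-input handling
#'
#' Two-sided Welch test via [stats::t.test]. Missing values are dropped per
#' group first. A protein is *untestable* — rather than an error — when a
#' group retains fewer than two observations or both groups have zero
#' variance; untestable inputs return `NA` statistics and
#' `testable = FALSE` so matrix-wide scans keep going.
#'
#' @param a,b numeric vectors of (possibly log-transformed) abundances for
#'   the two groups; `NA`s are removed.
#' @return list with `t` (statistic, sign of `mean(a) - mean(b)`), `df`
#'   (Welch-Satterthwaite), `p` (two-sided), `n_a`, `n_b` (observations
#'   used) and `testable`.
#' @examples
#' welchTTest(c(2.1, 2.0, 1.9), c(1.0, 1.1, 0.9))
#' welchTTest(c(5, 5, 5), c(3, 3, 3))$testable  # degenerate: FALSE
#' @export
welchTTest <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  untestable <- list(t = NA_real_, df = NA_real_, p = NA_real_,
                     n_a = length(a), n_b = length(b), testable = FALSE)
  if (length(a) < 2L || length(b) < 2L) return(untestable)
  if (stats::var(a) == 0 && stats::var(b) == 0) return(untestable)
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_a = length(a), n_b = length(b), testable = TRUE)
}

#' Differential-abundance table (fold change + Welch's t)
#'
#' For every protein, computes the event / non-event fold change on
#' linear-scale group means of the non-missing entries and a two-sided
#' Welch t-test (by default on log2-transformed abundances), then flags
#' differentially expressed proteins by the joint criterion
#' `(FC > fcHi | FC < fcLo) & p < alpha`. Proteins with fewer than two
#' observations in a group (or zero variance in both) are reported with
#' `testable = FALSE` and never selected.
#'
#' @param x an [AbundanceExperiment-class].
#' @param fcHi,fcLo upper / lower fold-change thresholds
#'   (`0 < fcLo < 1 < fcHi`); defaults 1.2 and 0.8.
#' @param alpha p-value threshold, default 0.05.
#' @param logTransformTest logical; test log2 abundances (default) or raw
#'   linear values.
#' @return a [S4Vectors::DataFrame] with one row per protein:
#'   `protein_id`, `mean_event`, `mean_nonevent`, `fold_change`, `t_stat`,
#'   `df_welch`, `p_value`, `selected`, `testable`, `n_event_obs`,
#'   `n_nonevent_obs`. The number of untestable proteins is recorded in
#'   `metadata()$n_untestable`.
#' @examples
#' ae <- simulateDiscovery(nPerGroup = 10, nProteins = 40, nDep = 5,
#'                         log2Effect = 1.5, seed = 2)
#' dt <- depTable(ae)
#' sum(dt$selected)
#' @export
depTable <- function(x, fcHi = 1.2, fcLo = 0.8, alpha = 0.05,
                     logTransformTest = TRUE) {
  stopifnot(is(x, "AbundanceExperiment"))
  if (!(fcLo > 0 && fcLo < 1 && fcHi > 1))
    stop("thresholds must satisfy 0 < fcLo < 1 < fcHi", call. = FALSE)
  vals <- abundance(x)
  grp <- sampleGroups(x)
  ev <- vals[, grp == "event", drop = FALSE]
  ne <- vals[, grp == "non_event", drop = FALSE]

  res <- lapply(seq_len(nrow(vals)), function(i) {
    a <- ev[i, ]; b <- ne[i, ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    me <- if (length(a)) mean(a) else NA_real_
    mn <- if (length(b)) mean(b) else NA_real_
    fc <- if (length(a) && length(b) && mn > 0) me / mn else NA_real_
    wt <- if (logTransformTest) welchTTest(log2(a), log2(b))
          else welchTTest(a, b)
    c(mean_event = me, mean_nonevent = mn, fold_change = fc,
      t_stat = wt$t, df_welch = wt$df, p_value = wt$p,
      testable = as.numeric(wt$testable),
      n_event_obs = length(a), n_nonevent_obs = length(b))
  })
  m <- do.call(rbind, res)
  testable <- m[, "testable"] == 1
  selected <- testable & !is.na(m[, "fold_change"]) &
    (m[, "fold_change"] > fcHi | m[, "fold_change"] < fcLo) &
    m[, "p_value"] < alpha
  out <- DataFrame(
    protein_id = rownames(vals),
    mean_event = m[, "mean_event"],
    mean_nonevent = m[, "mean_nonevent"],
    fold_change = m[, "fold_change"],
    t_stat = m[, "t_stat"],
    df_welch = m[, "df_welch"],
    p_value = m[, "p_value"],
    selected = unname(selected),
    testable = unname(testable),
    n_event_obs = as.integer(m[, "n_event_obs"]),
    n_nonevent_obs = as.integer(m[, "n_nonevent_obs"])
  )
  metadata(out)$n_untestable <- sum(!testable)
  metadata(out)$thresholds <- c(fcHi = fcHi, fcLo = fcLo, alpha = alpha)
  out
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' Thin wrapper over [stats::p.adjust] (`method = "BH"`) that rejects
#' p-values outside `[0, 1]`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values, each `>= p` and `<= 1`.
#' @examples
#' adjustPvalues(c(0.01, 0.02, 0.03))
#' @export
adjustPvalues <- function(p) {
  pp <- p[!is.na(p)]
  if (any(pp < 0 | pp > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
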