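#' Univariate feature ranking by two-group ANOVA F
#'
#' Scores each candidate protein's ability to separate the event and
#' non-event groups with a one-way ANOVA F test on log2 abundances (for two
#' groups, F equals the squared pooled-variance t statistic). Features are
#' ordered by ascending p-value, ties broken by descending F then
#' lexicographic id, so the ranking is total and deterministic. Candidates
#' with fewer than two non-missing observations in a group are dropped with
#' a warning.
#'
#' @param x an [AbundanceExperiment-class].
#' @param candidateIds protein ids to rank (e.g. the selected rows of
#'   [depTable()]); defaults to all proteins.
#' @return a [S4Vectors::DataFrame] ordered by rank: `protein_id`,
#'   `f_score`, `p_value`, `rank`.
#' @examples
#' ae <- simulateDiscovery(nPerGroup = 10, nProteins = 30, nDep = 3,
#'                         log2Effect = 1.5, seed = 4)
#' head(rankFeatures(ae))
#' @export
rankFeatures <- function(x, candidateIds = rownames(x)) {
  stopifnot(is(x, "AbundanceExperiment"))
  candidateIds <- unique(as.character(candidateIds))
  if (!length(candidateIds)) stop("no candidate features", call. = FALSE)
  miss <- setdiff(candidateIds, rownames(x))
  if (length(miss))
    stop("unknown candidate id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  vals <- log2(abundance(x)[candidateIds, , drop = FALSE])
  grp <- sampleGroups(x)
  a <- vals[, grp == "event", drop = FALSE]
  b <- vals[, grp == "non_event", drop = FALSE]

  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  testable <- n1 >= 2L & n2 >= 2L
  if (any(!testable)) {
    warning(sum(!testable), " candidate(s) untestable (fewer than 2 ",
            "observations in a group) and excluded from the ranking")
  }
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- apply(a, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(b, 1L, stats::var, na.rm = TRUE)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  f <- (m1 - m2)^2 / (sp2 * (1 / n1 + 1 / n2))
  f[sp2 == 0 & (m1 == m2)] <- 0
  f[sp2 == 0 & (m1 != m2)] <- Inf
  p <- stats::pf(f, 1, n1 + n2 - 2, lower.tail = FALSE)

  keep <- which(testable)
  ord <- keep[order(p[keep], -f[keep], candidateIds[keep])]
  DataFrame(protein_id = candidateIds[ord],
            f_score = unname(f[ord]),
            p_value = unname(p[ord]),
            rank = seq_along(ord))
}

#' Incremental feature selection by cross-validated Matthews coefficient
#'
#' Walks the feature ranking, scoring the top-k subset for k = 1..`kMax`
#' with [cvMcc()], and selects the smallest k whose MCC attains the curve
#' maximum ("first maximum" rule).
#'
#' @param x an [AbundanceExperiment-class] or samples x features matrix.
#' @param ranking a [rankFeatures()] result, or a character vector of
#'   feature ids already in rank order.
#' @param kMax largest subset size to score; default 30 (the ranking-depth
#'   convention used for display); truncated to the ranking length.
#' @param spec a [classifierSpec()].
#' @param folds CV folds, default 10.
#' @param labels group labels when `x` is a plain matrix.
#' @return an [IFSCurve-class].
#' @examples
#' ae <- simulateDiscovery(nPerGroup = 10, nProteins = 20, nDep = 2,
#'                         log2Effect = 2, missingRate = 0, seed = 5)
#' curve <- ifsSelect(ae, rankFeatures(ae), kMax = 4)
#' selectedK(curve)
#' @export
ifsSelect <- function(x, ranking, kMax = 30, spec = classifierSpec(),
                      folds = 10, labels = NULL) {
  ids <- if (is.character(ranking)) ranking else ranking$protein_id
  if (!length(ids)) stop("empty ranking", call. = FALSE)
  kMax <- min(as.integer(kMax), length(ids))
  if (kMax < 1L) stop("kMax must be at least 1", call. = FALSE)
  mcc <- vapply(seq_len(kMax), function(k) {
    as.numeric(cvMcc(x, labels = labels, featureIds = ids[seq_len(k)],
                     spec = spec, folds = folds))
  }, numeric(1))
  new("IFSCurve",
      points = data.frame(k = seq_len(kMax), mcc = mcc),
      selectedK = which.max(mcc),  # first index attaining the maximum
      featureIds = ids[seq_len(kMax)],
      seed = spec$seed)
}
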