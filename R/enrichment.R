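# Two-tailed Fisher exact p for one 2x2 enrichment table, by the
# minimum-likelihood convention: sum hypergeometric point probabilities of
# all tables (same margins) no more likely than the observed one. The small
# relative tolerance absorbs floating-point ties, matching the convention of
# standard exact-test implementations.
fisher_two_tail <- function(k_hit, n_dep, K_term, N_bg) {
  support <- max(0L, n_dep + K_term - N_bg):min(n_dep, K_term)
  probs <- stats::dhyper(support, K_term, N_bg - K_term, n_dep)
  p_obs <- stats::dhyper(k_hit, K_term, N_bg - K_term, n_dep)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-07)]))
}

#' Functional enrichment of selected proteins by Fisher's exact test
#'
#' Tests each annotation term for over/under-representation of the
#' differential proteins against the full set of identified proteins, using
#' the two-tailed Fisher exact test on the 2x2 table (term membership x
#' differential status). Term member lists are intersected with the
#' background before testing; terms with no background members are dropped.
#' P-values are Benjamini-Hochberg adjusted.
#'
#' @param depIds character, selected (differential) protein ids; must be a
#'   subset of `backgroundIds`.
#' @param backgroundIds character, all identified proteins.
#' @param annotation named list mapping term id to a character vector of
#'   member protein ids, e.g. from [readGmt()]. An optional
#'   `attr(annotation, "term_names")` named character vector supplies
#'   descriptions.
#' @return a [S4Vectors::DataFrame], one row per tested term, ordered by
#'   p-value: `term_id`, `term_name`, `k_hit`, `n_dep`, `K_term`, `N_bg`,
#'   `fold_enrichment`, `p_value`, `p_adjusted`.
#' @examples
#' bg <- sprintf("P%02d", 1:40)
#' ann <- list(T1 = bg[1:8], T2 = bg[30:40])
#' fisherEnrichment(bg[1:6], bg, ann)
#' @export
fisherEnrichment <- function(depIds, backgroundIds, annotation) {
  depIds <- unique(as.character(depIds))
  backgroundIds <- unique(as.character(backgroundIds))
  stray <- setdiff(depIds, backgroundIds)
  if (length(stray))
    stop("depIds not in background: ", paste(stray, collapse = ", "),
         call. = FALSE)
  if (!length(annotation)) stop("empty annotation", call. = FALSE)

  N_bg <- length(backgroundIds)
  n_dep <- length(depIds)
  term_names <- attr(annotation, "term_names")

  rows <- lapply(names(annotation), function(term) {
    members <- intersect(unique(as.character(annotation[[term]])),
                         backgroundIds)
    K_term <- length(members)
    if (K_term == 0L) return(NULL)
    k_hit <- length(intersect(members, depIds))
    fe <- if (n_dep > 0) (k_hit / n_dep) / (K_term / N_bg) else NA_real_
    data.frame(term_id = term,
               term_name = if (!is.null(term_names) && term %in%
                               names(term_names)) term_names[[term]] else term,
               k_hit = k_hit, n_dep = n_dep, K_term = K_term, N_bg = N_bg,
               fold_enrichment = fe,
               p_value = fisher_two_tail(k_hit, n_dep, K_term, N_bg),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no term has background members", call. = FALSE)
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- adjustPvalues(tab$p_value)
  tab <- tab[order(tab$p_value, tab$term_id), ]
  rownames(tab) <- NULL
  DataFrame(tab)
}

#' Read a GMT annotation file
#'
#' One term per line: term id, description, then tab-separated member ids.
#'
#' @param path path to a GMT file.
#' @return named list of member-id vectors with a `term_names` attribute,
#'   ready for [fisherEnrichment()].
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  ann <- lapply(parts, function(f) unique(f[-(1:2)]))
  names(ann) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(ann)))
    stop("duplicate term ids in GMT", call. = FALSE)
  attr(ann, "term_names") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), names(ann))
  ann
}
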