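#' ROC curve and tie-corrected Mann-Whitney AUC
#'
#' AUC is computed as the Mann-Whitney U statistic divided by `n1 * n0`,
#' with ties counted 1/2 (midrank construction); ROC points enumerate every
#' distinct score threshold, grouping tied scores.
#'
#' @param scores numeric risk scores (higher = more event-like).
#' @param outcome binary outcome (0/1, logical, or `"event"`/`"non_event"`).
#' @return list with `roc` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
#' @export
rocAuc <- function(scores, outcome) {
  y <- as_binary_outcome(outcome)
  if (length(scores) != length(y))
    stop("scores and outcome differ in length", call. = FALSE)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes must be present", call. = FALSE)

  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp_end <- c(which(diff(s) != 0), length(s))  # collapse tied thresholds
  tp <- cumsum(yy)[grp_end]
  fp <- cumsum(1 - yy)[grp_end]
  roc <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1),
                    threshold = c(Inf, s[grp_end]))
  list(roc = roc, auc = auc)
}

as_binary_outcome <- function(outcome) {
  if (is.factor(outcome) || is.character(outcome)) {
    y <- as.integer(as.character(outcome) == "event")
  } else {
    y <- as.integer(outcome)
    if (!all(y %in% c(0L, 1L), na.rm = TRUE))
      stop("outcome must be binary", call. = FALSE)
  }
  y
}

# DeLong structural components: V10[i] = mean_j psi(X_i, Y_j) over
# negatives, V01[j] likewise over positives, psi scoring 1 / 0.5 / 0.
delong_components <- function(scores, y) {
  x <- scores[y == 1L]; yneg <- scores[y == 0L]
  m <- length(x); n <- length(yneg)
  # midrank identity: V10_i = (rank of x_i among all - rank among positives
  # alone) / n, the O((m+n) log(m+n)) form of the pairwise mean
  r_all <- rank(c(x, yneg), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(yneg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong z-test between two correlated ROC curves
#'
#' Nonparametric comparison of the AUCs of two risk scores computed on the
#' same subjects, using the DeLong structural-components estimate of
#' `var(auc_a - auc_b)` (which accounts for the correlation induced by the
#' shared subjects) and a two-sided normal z-test.
#'
#' @param scoresA,scoresB paired numeric score vectors on identical
#'   subjects, e.g. baseline and biomarker-augmented risk scores.
#' @param outcome binary outcome shared by both scores.
#' @return list with `z`, `p`, `aucA`, `aucB`, `varA`, `varB`, `varDiff`.
#' @examples
#' set.seed(1)
#' y <- rep(0:1, each = 50)
#' a <- rnorm(100) + y; b <- rnorm(100) + 0.5 * y
#' delongTest(a, b, y)
#' @export
delongTest <- function(scoresA, scoresB, outcome) {
  if (length(scoresA) != length(scoresB))
    stop("unpaired inputs: score vectors differ in length", call. = FALSE)
  y <- as_binary_outcome(outcome)
  if (length(y) != length(scoresA))
    stop("outcome length does not match the scores", call. = FALSE)
  m <- sum(y == 1L); n <- sum(y == 0L)
  if (m == 0L || n == 0L)
    stop("both outcome classes must be present", call. = FALSE)

  ca <- delong_components(scoresA, y)
  cb <- delong_components(scoresB, y)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_a <- s10[1, 1] / m + s01[1, 1] / n
  var_b <- s10[2, 2] / m + s01[2, 2] / n
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- ca$auc - cb$auc
  if (var_diff <= 0) {
    z <- if (abs(diff) < .Machine$double.eps^0.5) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       aucA = ca$auc, aucB = cb$auc,
       varA = var_a, varB = var_b, varDiff = var_diff)
}
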