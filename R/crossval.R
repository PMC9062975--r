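# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so class proportions are as even as integer counts
# allow and every training partition keeps both classes whenever each class
# has at least 2 members.
stratified_folds <- function(labels, folds, seed) {
  n <- length(labels)
  if (n < folds) stop("fewer samples than folds", call. = FALSE)
  fold_id <- integer(n)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  for (f in seq_len(folds)) {
    train_lab <- labels[fold_id != f]
    if (length(unique(train_lab)) < 2L)
      stop("stratification error: a class is absent from a training fold",
           call. = FALSE)
  }
  fold_id
}

# Resolve (AbundanceExperiment | matrix, labels) into the samples x features
# log2 matrix used by the classifiers, plus the label factor with levels
# (non_event, event).
resolve_features <- function(x, labels, featureIds) {
  if (is(x, "AbundanceExperiment")) {
    if (is.null(labels)) labels <- as.character(sampleGroups(x))
    miss <- setdiff(featureIds, rownames(x))
    if (length(miss))
      stop("unknown feature id(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    feat <- t(log2(abundance(x)[featureIds, , drop = FALSE]))
  } else {
    feat <- as.matrix(x)
    if (!is.null(featureIds)) feat <- feat[, featureIds, drop = FALSE]
  }
  if (is.null(labels)) stop("labels required for a plain matrix input",
                            call. = FALSE)
  y <- factor(as.character(labels), levels = c("non_event", "event"))
  if (anyNA(y)) stop("labels must be 'event' / 'non_event'", call. = FALSE)
  list(features = feat, labels = y)
}

# Shared CV engine: returns held-out soft-vote probabilities in original
# sample order (each sample held out exactly once).
cv_probs <- function(x, labels, featureIds, spec, folds) {
  rf <- resolve_features(x, labels, featureIds)
  feat <- rf$features; y <- rf$labels
  fold_id <- stratified_folds(y, folds, seed = derive_seed(spec$seed, 0L))
  probs <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (!any(test)) next  # more folds than samples per class leaves gaps
    model <- fit_voting(feat[!test, , drop = FALSE], y[!test], spec,
                        fit_seed = derive_seed(spec$seed, f))
    probs[test] <- predict_voting(model, feat[test, , drop = FALSE])
  }
  list(probs = probs, labels = y, fold_id = fold_id)
}

#' Cross-validated Matthews coefficient of the voting classifier
#'
#' Runs stratified k-fold cross-validation of the soft-voting ensemble on
#' the given feature subset, pools the held-out event probabilities across
#' folds, thresholds them at 0.5 into a single confusion table, and returns
#' its Matthews coefficient. Pooling (rather than averaging per-fold MCCs)
#' keeps the counts non-degenerate at small cohort sizes.
#'
#' @param x an [AbundanceExperiment-class] (features are log2 abundances)
#'   or a samples x features numeric matrix.
#' @param labels sample group labels (`"event"` / `"non_event"`); taken
#'   from `x` when it is an AbundanceExperiment.
#' @param featureIds feature (protein) ids to use.
#' @param spec a [classifierSpec()].
#' @param folds number of CV folds, default 10.
#' @return MCC of the pooled held-out confusion counts, with the counts and
#'   pooled probabilities attached as attributes `counts` and `probs`.
#' @seealso [ifsSelect()], [cvRoc()]
#' @export
cvMcc <- function(x, labels = NULL, featureIds, spec = classifierSpec(),
                  folds = 10) {
  cv <- cv_probs(x, labels, featureIds, spec, folds)
  counts <- confusion_counts(cv$probs, cv$labels)
  out <- matthewsCoefficient(counts)
  attr(out, "counts") <- counts
  attr(out, "probs") <- cv$probs
  out
}

#' Cross-validated ROC of the voting classifier
#'
#' As [cvMcc()], but scores the pooled held-out probabilities as a ROC
#' curve with tie-corrected Mann-Whitney AUC.
#'
#' @inheritParams cvMcc
#' @return list with `roc` (data.frame `fpr`, `tpr`, `threshold`), `auc`,
#'   `counts` (pooled confusion at threshold 0.5), `probs`, `labels`.
#' @export
cvRoc <- function(x, labels = NULL, featureIds, spec = classifierSpec(),
                  folds = 10) {
  cv <- cv_probs(x, labels, featureIds, spec, folds)
  r <- rocAuc(cv$probs, as.integer(cv$labels == "event"))
  list(roc = r$roc, auc = r$auc,
       counts = confusion_counts(cv$probs, cv$labels),
       probs = cv$probs, labels = cv$labels)
}
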