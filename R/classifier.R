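#' Soft-voting classifier specification
#'
#' Configures the ensemble used throughout feature selection: logistic
#' regression, a radial-kernel support vector machine with Platt-calibrated
#' probabilities, and a random forest, combined by equal-weight averaging of
#' the predicted event probabilities. Per-feature median imputation and
#' standardization are fit on training folds only, so no information leaks
#' from held-out samples.
#'
#' @param seed integer seed governing fold assignment and the stochastic
#'   learners. The default is fixed so repeated runs agree; change it to
#'   probe seed sensitivity.
#' @param ntree random-forest trees.
#' @param svmCost SVM soft-margin cost.
#' @return an object of class `votingClassifierSpec`.
#' @examples
#' spec <- classifierSpec(seed = 7)
#' @export
classifierSpec <- function(seed = 20150419, ntree = 500, svmCost = 1) {
  assert_positive_int(ntree, "ntree")
  if (svmCost <= 0) stop("'svmCost' must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), ntree = as.integer(ntree),
                 svmCost = svmCost),
            class = "votingClassifierSpec")
}

# Fit fold-local preprocessing: median imputation then center/scale.
# Constant features get scale 1 so they pass through as zeros.
fit_preprocess <- function(x_train) {
  med <- apply(x_train, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  imputed <- x_train
  for (j in seq_len(ncol(imputed))) {
    nas <- is.na(imputed[, j])
    if (any(nas)) imputed[nas, j] <- med[j]
  }
  ctr <- colMeans(imputed)
  scl <- apply(imputed, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(median = med, center = ctr, scale = scl)
}

apply_preprocess <- function(pp, x) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- pp$median[j]
  }
  scale(x, center = pp$center, scale = pp$scale)
}

# glmnet needs at least two columns; a constant zero column takes a zero
# ridge coefficient and leaves the fit unchanged.
pad_matrix <- function(x) {
  if (ncol(x) >= 2L) x else cbind(x, .pad = 0)
}

# Fit the three base learners on a preprocessed training matrix.
# y: factor with levels c("non_event", "event"); "event" is the positive
# class. The linear learner is ridge-penalized logistic regression
# (lambda = 1/n): at tens of features against tens of samples an
# unpenalized fit separates perfectly and its probabilities degenerate.
# Seeded because the SVM probability calibration and the forest are
# stochastic.
fit_voting <- function(x_train, y_train, spec, fit_seed) {
  pp <- fit_preprocess(x_train)
  xs <- apply_preprocess(pp, x_train)
  with_seed(fit_seed, {
    lambda <- 1 / nrow(xs)
    lr <- suppressWarnings(  # small-class warnings are expected at n ~ 20
      glmnet::glmnet(pad_matrix(xs), y_train, family = "binomial",
                     alpha = 0, lambda = lambda, standardize = FALSE))
    sv <- e1071::svm(xs, y_train, kernel = "radial", cost = spec$svmCost,
                     probability = TRUE)
    rf <- randomForest::randomForest(xs, y_train, ntree = spec$ntree)
    list(pp = pp, lr = lr, lambda = lambda, sv = sv, rf = rf,
         features = colnames(x_train))
  })
}

# Equal-weight soft vote: mean of the three P(event) estimates.
predict_voting <- function(model, x_new) {
  xs <- apply_preprocess(model$pp, x_new)
  p_lr <- stats::predict(model$lr, newx = pad_matrix(xs), s = model$lambda,
                         type = "response")[, 1]
  sv_pred <- stats::predict(model$sv, xs, probability = TRUE)
  p_sv <- attr(sv_pred, "probabilities")[, "event"]
  p_rf <- stats::predict(model$rf, xs, type = "prob")[, "event"]
  probs <- (as.numeric(p_lr) + as.numeric(p_sv) + as.numeric(p_rf)) / 3
  names(probs) <- rownames(x_new)
  probs
}

#' Matthews correlation coefficient from confusion counts
#'
#' \deqn{\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP+FP)(TP+FN)(TN+FN)(TN+FP)}}}
#' Returns 0 when any factor of the denominator is 0 (the standard
#' continuity convention for the otherwise-undefined ratio).
#'
#' @param tp,tn,fp,fn non-negative counts; `tp` may also be a named vector
#'   or list with elements `tp`, `tn`, `fp`, `fn`.
#' @return MCC in `[-1, 1]`.
#' @examples
#' matthewsCoefficient(8, 7, 3, 2)  # 50 / sqrt(9900)
#' @export
matthewsCoefficient <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && (is.list(tp) || length(tp) == 4L)) {
    cc <- as.list(tp)
    tn <- cc$tn; fp <- cc$fp; fn <- cc$fn; tp <- cc$tp
  }
  counts <- c(tp, tn, fp, fn)
  if (length(counts) != 4L || any(is.na(counts)) || any(counts < 0))
    stop("need four non-negative counts tp, tn, fp, fn", call. = FALSE)
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fn) * (tn + fp)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

# Pool predicted probabilities into confusion counts at a threshold.
confusion_counts <- function(probs, labels, threshold = 0.5) {
  pred_event <- probs >= threshold
  is_event <- labels == "event"
  list(tp = sum(pred_event & is_event),
       tn = sum(!pred_event & !is_event),
       fp = sum(pred_event & !is_event),
       fn = sum(!pred_event & is_event))
}
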