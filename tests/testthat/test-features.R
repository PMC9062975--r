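test_that("Matthews coefficient matches direct arithmetic", {
  expect_equal(matthewsCoefficient(5, 5, 0, 0), 1)
  expect_equal(matthewsCoefficient(3, 2, 2, 3), 0)
  expect_equal(matthewsCoefficient(8, 7, 3, 2), 50 / sqrt(9900),
               tolerance = 1e-15)
  expect_equal(matthewsCoefficient(0, 0, 5, 5), -1)
  # zero denominator factor: continuity convention
  expect_equal(matthewsCoefficient(0, 10, 0, 3), 0)
  expect_equal(matthewsCoefficient(list(tp = 8, tn = 7, fp = 3, fn = 2)),
               50 / sqrt(9900))
  expect_error(matthewsCoefficient(-1, 1, 1, 1), "non-negative")
})

test_that("MCC symmetry and label-inversion properties hold by enumeration", {
  for (total in c(6L, 11L)) {
    parts <- expand.grid(tp = 0:total, tn = 0:total, fp = 0:total)
    parts$fn <- total - parts$tp - parts$tn - parts$fp
    parts <- parts[parts$fn >= 0, ]
    for (i in seq_len(nrow(parts))) {
      cc <- parts[i, ]
      m <- matthewsCoefficient(cc$tp, cc$tn, cc$fp, cc$fn)
      # swapping the meaning of the classes (TP<->TN, FP<->FN) preserves MCC
      expect_equal(matthewsCoefficient(cc$tn, cc$tp, cc$fn, cc$fp), m)
      # inverting every predicted label (TP<->FP, TN<->FN) negates MCC
      expect_equal(matthewsCoefficient(cc$fp, cc$fn, cc$tp, cc$tn), -m)
    }
  }
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  ae <- make_discovery(nPerGroup = 12, nProteins = 20, nDep = 2, seed = 6)
  rk <- rankFeatures(ae)
  grp <- sampleGroups(ae)
  vals <- log2(abundance(ae))
  set.seed(2)
  for (id in sample(rk$protein_id, 5)) {
    a <- vals[id, grp == "event"]
    b <- vals[id, grp == "non_event"]
    tt <- t.test(a[!is.na(a)], b[!is.na(b)], var.equal = TRUE)
    row <- rk[rk$protein_id == id, ]
    expect_equal(row$f_score, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("feature ranking is total, deterministic, and power-ordered", {
  ae <- make_discovery(nPerGroup = 19, nProteins = 60, nDep = 5,
                       log2Effect = 1.0, seed = 12)
  rk <- rankFeatures(ae)
  expect_identical(rk$rank, seq_len(nrow(rk)))
  expect_true(!is.unsorted(rk$p_value))
  expect_identical(rankFeatures(ae)$protein_id, rk$protein_id)
  # planted features occupy the top ranks
  expect_true(all(plantedTruth(ae) %in% rk$protein_id[1:10]))

  # a feature with identical groups ranks last
  m <- 2^matrix(rnorm(5 * 10, 20), 5, 10,
                dimnames = list(paste0("F", 1:5), paste0("S", 1:10)))
  m[5, ] <- rep(2^20, 10)  # no separation, zero variance
  m[1, 1:5] <- m[1, 1:5] * 8
  ae2 <- AbundanceExperiment(m, rep(c("event", "non_event"), each = 5))
  rk2 <- rankFeatures(ae2)
  expect_equal(rk2$protein_id[1], "F1")
  expect_equal(rk2$f_score[rk2$protein_id == "F5"], 0)
  expect_equal(rk2$protein_id[nrow(rk2)], "F5")
})

test_that("untestable candidates are excluded with a warning", {
  m <- 2^matrix(rnorm(3 * 8, 20), 3, 8,
                dimnames = list(paste0("F", 1:3), paste0("S", 1:8)))
  m[2, 1:4] <- NA
  ae <- AbundanceExperiment(m, rep(c("event", "non_event"), each = 4))
  expect_warning(rk <- rankFeatures(ae), "untestable")
  expect_false("F2" %in% rk$protein_id)
  expect_error(rankFeatures(ae, "nope"), "unknown candidate")
})

test_that("a perfectly separating feature yields CV-MCC and CV-AUC of 1", {
  set.seed(3)
  x <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(paste0("S", 1:20), paste0("F", 1:3)))
  labels <- rep(c("event", "non_event"), each = 10)
  x[, 1] <- ifelse(labels == "event", 10, -10) + rnorm(20, sd = 0.1)
  m <- cvMcc(x, labels, featureIds = colnames(x),
             spec = classifierSpec(seed = 4), folds = 10)
  expect_equal(as.numeric(m), 1)
  roc <- cvRoc(x, labels, featureIds = colnames(x),
               spec = classifierSpec(seed = 4), folds = 10)
  expect_equal(roc$auc, 1)
  counts <- attr(m, "counts")
  expect_equal(counts$tp + counts$tn + counts$fp + counts$fn, 20)
})

test_that("every sample is held out exactly once and folds are stratified", {
  labels <- factor(rep(c("non_event", "event"), times = c(19, 19)))
  fid <- ProteoMACE:::stratified_folds(labels, folds = 10, seed = 1)
  expect_length(fid, 38L)
  expect_setequal(unique(fid), 1:10)
  # 19 per class over 10 folds: fold sizes 2-4, per-class counts 1-2, and
  # both classes remain in every training set
  expect_true(all(table(fid) %in% 2:4))
  expect_true(all(table(fid, labels) %in% 1:2))
  for (f in 1:10) {
    expect_equal(nlevels(droplevels(labels[fid != f])), 2L)
  }
  # a class with a single member cannot be stratified into training folds
  bad <- factor(c("event", rep("non_event", 11)),
                levels = c("non_event", "event"))
  expect_error(ProteoMACE:::stratified_folds(bad, folds = 4, seed = 1),
               "stratification error")
})

test_that("informative features beat no-signal features under the same seed", {
  ae <- make_discovery(nPerGroup = 19, nProteins = 40, nDep = 3,
                       log2Effect = 1.5, seed = 21)
  rk <- rankFeatures(ae)
  spec <- classifierSpec(seed = 9)
  m_signal <- as.numeric(cvMcc(ae, featureIds = plantedTruth(ae), spec = spec))
  null_ids <- setdiff(rownames(ae), plantedTruth(ae))[1:3]
  m_null <- as.numeric(cvMcc(ae, featureIds = null_ids, spec = spec))
  expect_gt(m_signal, m_null)
})

test_that("the first-maximum rule is enforced on hand-specified curves", {
  mk <- function(mcc, k) new("IFSCurve",
                             points = data.frame(k = seq_along(mcc),
                                                 mcc = mcc),
                             selectedK = k,
                             featureIds = paste0("F", seq_along(mcc)),
                             seed = 1L)
  expect_s4_class(mk(c(0.2, 0.5, 0.5, 0.4), 2L), "IFSCurve")
  expect_error(mk(c(0.2, 0.5, 0.5, 0.4), 3L), "smallest k")
  # monotone-increasing curve selects k_max
  expect_equal(selectedK(mk(c(0.1, 0.2, 0.3), 3L)), 3L)
  expect_equal(selectedFeatures(mk(c(0.7, 0.2), 1L)), "F1")
})

test_that("IFS is deterministic and its curve matches per-k CV-MCC", {
  ae <- make_discovery(nPerGroup = 10, nProteins = 25, nDep = 2,
                       log2Effect = 1.5, missingRate = 0, seed = 31)
  rk <- rankFeatures(ae)
  spec <- classifierSpec(seed = 5)
  c1 <- ifsSelect(ae, rk, kMax = 4, spec = spec)
  c2 <- ifsSelect(ae, rk, kMax = 4, spec = spec)
  expect_identical(ifsPoints(c1), ifsPoints(c2))
  expect_identical(selectedK(c1), selectedK(c2))
  # curve point k reproduces a standalone cvMcc call on the top-k subset
  k <- 3
  expect_equal(ifsPoints(c1)$mcc[k],
               as.numeric(cvMcc(ae, featureIds = rk$protein_id[1:k],
                                spec = spec)))
})
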