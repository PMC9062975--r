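test_that("Welch t matches the closed-form statistic", {
  a <- c(2.1, 2.0, 1.9)
  b <- c(1.0, 1.1, 0.9)
  # closed form: t = (ma - mb) / sqrt(va/na + vb/nb), Welch-Satterthwaite df
  va <- var(a); vb <- var(b)
  se2 <- va / 3 + vb / 3
  t_exp <- (mean(a) - mean(b)) / sqrt(se2)
  df_exp <- se2^2 / ((va / 3)^2 / 2 + (vb / 3)^2 / 2)
  p_exp <- 2 * pt(-abs(t_exp), df_exp)
  res <- welchTTest(a, b)
  expect_equal(res$t, t_exp, tolerance = 1e-12)
  expect_equal(res$df, df_exp, tolerance = 1e-12)
  expect_equal(res$p, p_exp, tolerance = 1e-12)
  # symmetric in (a, b) up to the sign of t
  res2 <- welchTTest(b, a)
  expect_equal(res2$t, -res$t)
  expect_equal(res2$p, res$p)
})

test_that("Welch t handles identical and degenerate groups", {
  res <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # both groups constant: untestable, not an error
  res <- welchTTest(c(5, 5, 5), c(3, 3, 3))
  expect_false(res$testable)
  expect_true(is.na(res$p))
  # fewer than 2 observations after NA removal: untestable
  expect_false(welchTTest(c(1, NA), c(1, 2, 3))$testable)
})

test_that("Welch p is invariant under common positive scaling", {
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    k <- runif(1, 0.1, 50)
    expect_equal(welchTTest(k * a, k * b)$p, welchTTest(a, b)$p,
                 tolerance = 1e-9)
  }
})

test_that("depTable selects planted proteins and flags untestable rows", {
  ae <- simulateDiscovery(nPerGroup = 50, nProteins = 200, nDep = 20,
                          log2Effect = 1.0, missingRate = 0.1, seed = 3)
  dt <- depTable(ae)
  expect_equal(nrow(dt), 200L)
  truth <- plantedTruth(ae)
  hits <- sum(dt$protein_id[dt$selected] %in% truth)
  expect_gte(hits, 16L)
  null_ids <- setdiff(dt$protein_id, truth)
  false_rate <- mean(dt$selected[dt$protein_id %in% null_ids])
  expect_lte(false_rate, 0.10)
  # selection flag honours the joint criterion exactly
  sel_expected <- with(as.data.frame(dt),
    testable & (fold_change > 1.2 | fold_change < 0.8) & p_value < 0.05)
  expect_identical(dt$selected, unname(sel_expected))
})

test_that("a protein missing in one whole group is untestable", {
  m <- matrix(2^rnorm(40, 20), 4, 10,
              dimnames = list(paste0("P", 1:4), paste0("S", 1:10)))
  m[2, 1:5] <- NA
  ae <- AbundanceExperiment(m, rep(c("event", "non_event"), each = 5))
  dt <- depTable(ae)
  expect_false(dt$testable[2])
  expect_false(dt$selected[2])
  expect_equal(S4Vectors::metadata(dt)$n_untestable, 1L)
})

test_that("DEP selection is invariant to row and column permutations", {
  ae <- simulateDiscovery(nPerGroup = 8, nProteins = 40, nDep = 5,
                          log2Effect = 1.2, missingRate = 0.05, seed = 9)
  dt <- depTable(ae)
  set.seed(1)
  ae_perm <- AbundanceExperiment(
    abundance(ae)[sample(nrow(ae)), sample(ncol(ae))],
    sampleGroups(ae))  # named vector realigns to the permuted columns
  dt_perm <- depTable(ae_perm)
  ord <- match(dt$protein_id, dt_perm$protein_id)
  expect_equal(dt$selected, dt_perm$selected[ord])
  expect_equal(dt$p_value, dt_perm$p_value[ord], tolerance = 1e-12)
  expect_equal(dt$fold_change, dt_perm$fold_change[ord], tolerance = 1e-12)
})

test_that("depTable validates thresholds", {
  ae <- simulateDiscovery(nPerGroup = 3, nProteins = 5, nDep = 0, seed = 1)
  expect_error(depTable(ae, fcHi = 0.9), "thresholds")
  expect_error(depTable(ae, fcLo = 1.1), "thresholds")
})

test_that("BH adjustment matches the step-up formula", {
  # by hand: sorted p * m / rank, cumulative minimum from the largest
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustPvalues(0.2), 0.2)
  expect_equal(adjustPvalues(rep(1, 5)), rep(1, 5))
  set.seed(7)
  p <- runif(50)
  adj <- adjustPvalues(p)
  expect_true(all(adj >= p & adj <= 1))
  # monotone non-decreasing after sorting by raw p
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(adjustPvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjustPvalues(-0.1), "\\[0, 1\\]")
})
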