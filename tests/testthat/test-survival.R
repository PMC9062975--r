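test_that("Cox fit recovers a known hazard ratio", {
  d <- sim_ph_binary(n = 4000, log_hr = log(2), seed = 17)
  fit <- fitCox(d, "x")
  hr <- coxTable(fit)$hr
  expect_gt(hr, 1.8)
  expect_lt(hr, 2.2)
  expect_true(coxTable(fit)$ci_lower < hr && hr < coxTable(fit)$ci_upper)
  # null covariate: CI straddles 1
  d0 <- sim_ph_binary(n = 4000, log_hr = 0, seed = 18)
  t0 <- coxTable(fitCox(d0, "x"))
  expect_true(t0$ci_lower < 1 && t0$ci_upper > 1)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- sim_ph_binary(n = 200, log_hr = log(2), seed = 2)
  d$x2 <- d$x
  expect_error(fitCox(d, c("x", "x2")), "singular")
  d$const <- 1
  expect_error(fitCox(d, "const"), "constant covariate")
  expect_error(fitCox(d, "nope"), "missing column")
  expect_error(fitCox(d[d$event == 1, ][1, ], "x"), "2 events")
})

test_that("hazard-ratio rescaling follows exp(k * beta) exactly", {
  sc <- simulateValidation(nSubjects = 400, seed = 23)
  fit <- fitCox(sc, c("EPCR", "CETP"))
  t1 <- coxTable(fit)[1, ]
  expect_equal(unname(rescaleHR(fit, "EPCR", 1)),
               unname(c(t1$hr, t1$ci_lower, t1$ci_upper)), tolerance = 1e-12)
  for (k in c(10, 100)) {
    expect_equal(unname(rescaleHR(fit, "EPCR", k)["hr"]), t1$hr^k,
                 tolerance = 1e-12)
  }
  expect_error(rescaleHR(fit, "CPB2", 10), "unknown term")
  expect_error(rescaleHR(fit, "EPCR", -1), "positive")
})

test_that("rescaling reproduces hand arithmetic", {
  # beta = 0.0005, se = 0.0002, k = 100 => hr = e^0.05, CI e^0.0108..e^0.0892
  fit <- new("CoxFit", fit = NULL,
             table = data.frame(term = "b", beta = 5e-4, se = 2e-4,
                                hr = exp(5e-4), ci_lower = 1, ci_upper = 1,
                                p = 1),
             logrankP = 1, n = 10L, nEvents = 5L)
  r <- rescaleHR(fit, "b", 100)
  expect_equal(unname(r["hr"]), exp(0.05), tolerance = 1e-12)
  expect_equal(unname(r["ci_lower"]), exp(100 * (5e-4 - 1.959963984540054 * 2e-4)),
               tolerance = 1e-12)
  expect_equal(unname(r["ci_upper"]), exp(100 * (5e-4 + 1.959963984540054 * 2e-4)),
               tolerance = 1e-12)
  expect_equal(unname(rescaleHR(fit, "b", 1)["hr"]), exp(5e-4))
})

test_that("log-rank test behaves at the null and under separation", {
  # two groups with identical (time, event) multisets
  d <- data.frame(time_months = rep(c(5, 10, 20, 40), 2),
                  event = rep(c(1, 0, 1, 0), 2),
                  grp = rep(c("a", "b"), each = 4))
  lr <- logrankTest(d, "grp")
  expect_lt(lr$chi2, 1e-10)
  expect_gt(lr$p, 0.999)
  expect_error(logrankTest(d[d$grp == "a", ], "grp"), "2 groups")

  # strongly separated hazards reject decisively
  for (s in 1:5) {
    ds <- sim_ph_binary(n = 1000, log_hr = log(3), seed = 100 + s)
    expect_lt(logrankTest(ds, "x")$p, 1e-3)
  }
})

test_that("log-rank equals the Cox score test for one binary covariate", {
  for (s in 1:10) {
    d <- sim_ph_binary(n = 300, log_hr = 0.5, seed = 200 + s)
    lr <- logrankTest(d, "x")
    fit <- fitCox(d, "x")
    expect_equal(round(lr$p, 3), round(fit@logrankP, 3))
  }
})

test_that("risk-score ordering is invariant to affine covariate rescaling", {
  sc <- simulateValidation(nSubjects = 300, seed = 29)
  base <- buildRiskScore(sc, framinghamCovariates())
  d <- cohortData(sc)
  d$age <- d$age / 10 + 3
  resc <- buildRiskScore(d, framinghamCovariates())
  expect_equal(order(base), order(resc))
  expect_equal(rocAuc(base, cohortData(sc)$event)$auc,
               rocAuc(resc, d$event)$auc, tolerance = 1e-12)
})

test_that("biomarker signal lifts the combined model above the baseline", {
  sc <- simulateValidation(nSubjects = 2000,
                           logHrPerSd = c(EPCR = 0.6, CETP = 0.5),
                           covariateEffects = c(age = 0),  # only biomarkers
                           seed = 37)
  d <- cohortData(sc)
  base <- buildRiskScore(sc, framinghamCovariates())
  comb <- buildRiskScore(sc, c(framinghamCovariates(), "EPCR", "CETP"))
  expect_gt(rocAuc(comb, d$event)$auc, rocAuc(base, d$event)$auc)
  dl <- delongTest(comb, base, d$event)
  expect_lt(dl$p, 0.01)
})

test_that("with all effects zero both risk scores are uninformative", {
  sc <- simulateValidation(nSubjects = 5000,
                           logHrPerSd = c(EPCR = 0, CETP = 0),
                           covariateEffects = c(age = 0), seed = 41)
  d <- cohortData(sc)
  for (terms in list(framinghamCovariates(),
                     c(framinghamCovariates(), "EPCR", "CETP"))) {
    auc <- rocAuc(buildRiskScore(sc, terms), d$event)$auc
    expect_gt(auc, 0.45)
    expect_lt(auc, 0.55)
  }
})

test_that("adding a pure-noise biomarker barely moves the combined AUC", {
  sc <- simulateValidation(nSubjects = 5000,
                           logHrPerSd = c(EPCR = 0.4, CETP = 0.3,
                                          NOISE = 0),
                           seed = 43)
  d <- cohortData(sc)
  with_marker <- rocAuc(buildRiskScore(
    sc, c(framinghamCovariates(), "EPCR", "CETP", "NOISE")), d$event)$auc
  without <- rocAuc(buildRiskScore(
    sc, c(framinghamCovariates(), "EPCR", "CETP")), d$event)$auc
  expect_lt(abs(with_marker - without), 0.03)
})
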