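# Independent oracles used across the suite. Each recomputes a quantity by
# a different route than the implementation under test.

# MCC as the Pearson correlation of the expanded actual/predicted 0-1
# vectors (phi coefficient); zero-variance margins map to 0.
mcc_cor_oracle <- function(tp, tn, fp, fn) {
  actual <- c(rep(1, tp), rep(1, fn), rep(0, fp), rep(0, tn))
  pred <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
  if (length(actual) == 0) return(0)
  r <- suppressWarnings(stats::cor(actual, pred))
  if (is.na(r)) 0 else r
}

# AUC by direct pairwise counting: ties count one half.
auc_pairwise_oracle <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Two-tailed Fisher p by brute-force table enumeration with point
# probabilities from log-binomial coefficients (lchoose), summing all
# tables no more likely than the observed (a hair of relative tolerance
# absorbs float ties, as in standard exact-test implementations).
fisher_enum_oracle <- function(k_hit, n_dep, K_term, N_bg) {
  support <- max(0, n_dep + K_term - N_bg):min(n_dep, K_term)
  logp <- lchoose(K_term, support) + lchoose(N_bg - K_term, n_dep - support) -
    lchoose(N_bg, n_dep)
  probs <- exp(logp)
  p_obs <- probs[support == k_hit]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-07)]))
}

# Exponential proportional-hazards fixture with one binary covariate and
# administrative censoring, for Cox recovery tests.
sim_ph_binary <- function(n, log_hr, baseline_rate = 0.015, censor_time = 48,
                          seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = baseline_rate * exp(log_hr * x))
  data.frame(time_months = pmin(t_event, censor_time),
             event = as.integer(t_event <= censor_time),
             x = x)
}

# Small discovery fixture reused by classifier tests.
make_discovery <- function(nPerGroup = 19, nProteins = 50, nDep = 3,
                           log2Effect = 1, missingRate = 0.1, seed = 1) {
  simulateDiscovery(nPerGroup = nPerGroup, nProteins = nProteins,
                    nDep = nDep, log2Effect = log2Effect,
                    missingRate = missingRate, seed = seed)
}
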