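# Shared fixtures, built once per test run. Kept deliberately small; heavier
# simulations are constructed inside the tests that need them.

fix_lex_native <- build_lexicon(20, "native_like", seed = 2)
fix_lex_foreign <- build_lexicon(50, "foreign_like", seed = 1)
fix_lex_random <- build_lexicon(100, "random", seed = 4)

fix_forward <- make_forward_model(30, seed = 1)

# sequences drawn once for corpus statistics
fix_seqs_native <- lapply(1:20, function(i) generate_sequence(fix_lex_native, 19, seed = 500 + i))
fix_seqs_random <- lapply(1:60, function(i) generate_sequence(fix_lex_random, 19, seed = 700 + i))

# a small simulated dataset shared by spectral/beamformer tests:
# 2 Hz effect in frontal_left, 4 Hz in both auditory ROIs
fix_cfg <- sim_config(
  fs_hz = 200, snr = 2,
  effect_2hz = list(native_like = c(frontal_left = 1)),
  effect_4hz = 1, seed = 7)
fix_trials <- simulate_trials(fix_forward, fix_cfg, fix_seqs_native[1:12])

# brute-force transitional-probability oracle: exhaustive bigram counting
oracle_tp <- function(e1_all, e2_all, e1, e2) {
  sum(e1_all == e1 & e2_all == e2) / sum(e1_all == e1)
}

# exhaustive Mann-Whitney null: exact two-sided p for small samples
oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  u_obs <- sum(rank(pooled)[seq_len(n)]) # rank-sum statistic for x
  u_all <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
  mu <- mean(u_all)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
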