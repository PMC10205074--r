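test_that("CSD matrices are Hermitian with the expected structure", {
  # single sinusoid in one sensor -> rank-1 CSD
  fs <- 100; n <- 1000
  time <- (seq_len(n) - 1) / fs
  data <- array(0, c(3, 4, n))
  for (tr in 1:3) data[tr, 2, ] <- sin(2 * pi * 3 * time)
  tr <- structure(list(data = data, envelope = matrix(0, 3, n), fs_hz = fs,
                       time = time, condition = rep("a", 3), block = rep(1L, 3),
                       is_target = rep(FALSE, 3), correct = rep(TRUE, 3),
                       ground_truth = NULL), class = "ft_trials")
  C <- csd_matrix(tr, band_hz = c(2.8, 3.2), window = c(0.5, 9.5))
  expect_lt(max(Mod(C$matrix - Conj(t(C$matrix)))), 1e-10)
  expect_true(all(Re(diag(C$matrix)) >= 0))
  ev <- eigen(C$matrix, only.values = TRUE)$values
  expect_gt(Re(ev[1]) / (sum(Re(ev)) + 1e-30), 0.99)
  # two perfectly correlated sensors -> coherence 1 from the CSD
  data2 <- data
  data2[, 3, ] <- data2[, 2, ]
  tr2 <- tr; tr2$data <- data2
  C2 <- csd_matrix(tr2, band_hz = c(2.8, 3.2))$matrix
  coh <- Mod(C2[2, 3])^2 / (Re(C2[2, 2]) * Re(C2[3, 3]))
  expect_equal(coh, 1, tolerance = 1e-9)
})

test_that("independent white noise gives vanishing off-diagonal CSD", {
  set.seed(12)
  fs <- 100; n <- 1000
  nt <- 40
  data <- array(rnorm(nt * 4 * n), c(nt, 4, n))
  tr <- structure(list(data = data, envelope = matrix(0, nt, n), fs_hz = fs,
                       time = (seq_len(n) - 1) / fs, condition = rep("a", nt),
                       block = rep(1L, nt), is_target = rep(FALSE, nt),
                       correct = rep(TRUE, nt), ground_truth = NULL),
                  class = "ft_trials")
  C <- csd_matrix(tr, band_hz = c(1, 7))$matrix
  off <- Mod(C[upper.tri(C)])
  diag_mean <- mean(Re(diag(C)))
  # off-diagonals average down with the number of trial-bin samples
  expect_lt(max(off) / diag_mean, 3 / sqrt(40 * 55) * 5)
})

test_that("beamformer filters satisfy the unit-gain constraint", {
  f <- dics_filter(fix_forward, csd_matrix(fix_trials))
  for (s in c(1, 10, nrow(f$weights))) {
    l <- freqtag:::.ft_source_leadfield(fix_forward, s) %*% f$orientation[s, ]
    expect_equal(Mod(sum(f$weights[s, ] * l)), 1, tolerance = 1e-6)
  }
  lf <- lcmv_filter(fix_forward, band_covariance(fix_trials))
  for (s in c(1, 10)) {
    l <- freqtag:::.ft_source_leadfield(fix_forward, s) %*% lf$orientation[s, ]
    expect_equal(abs(sum(lf$weights[s, ] * l)), 1, tolerance = 1e-6)
  }
})

test_that("in the large-lambda limit the filter becomes a matched filter", {
  C <- csd_matrix(fix_trials)
  f <- dics_filter(fix_forward, C, lambda_frac = 1e8)
  s <- 5
  l <- freqtag:::.ft_source_leadfield(fix_forward, s) %*% f$orientation[s, ]
  w <- Re(f$weights[s, ])
  cs <- abs(sum(w * l)) / sqrt(sum(w^2) * sum(l^2))
  expect_equal(cs, 1, tolerance = 1e-4)
})

test_that("DICS power is invariant to a consistent sensor permutation", {
  set.seed(13)
  perm <- sample(nrow(fix_forward$sensor_positions))
  fwd_p <- fix_forward
  fwd_p$sensor_positions <- fwd_p$sensor_positions[perm, ]
  fwd_p$sensor_normals <- fwd_p$sensor_normals[perm, ]
  fwd_p$leadfield <- fwd_p$leadfield[perm, ]
  tr_p <- fix_trials
  tr_p$data <- fix_trials$data[, perm, , drop = FALSE]
  p0 <- source_power_contrast(dics_filter(fix_forward, csd_matrix(fix_trials)),
                              fix_trials, 2)$contrast
  p1 <- source_power_contrast(dics_filter(fwd_p, csd_matrix(tr_p)),
                              tr_p, 2)$contrast
  expect_equal(p0, p1, tolerance = 1e-8)
})

test_that("a single planted source is localized by the DICS contrast", {
  lex <- fix_lex_native
  fwd <- fix_forward
  truth <- fwd$rois$frontal_left[1]
  fwd$rois$probe <- truth
  cfg <- sim_config(fs_hz = 200, snr = 10,
                    effect_2hz = list(native_like = c(probe = 1)),
                    effect_4hz = 0, seed = 21)
  sqs <- lapply(1:10, function(i) generate_sequence(lex, 19, seed = 60 + i))
  tr <- simulate_trials(fwd, cfg, sqs)
  sc <- source_power_contrast(dics_filter(fwd, csd_matrix(tr)), tr, 2)$contrast
  est <- which.max(sc)
  d <- sqrt(sum((fwd$source_positions[est, ] - fwd$source_positions[truth, ])^2))
  expect_lte(d, fwd$grid_spacing_cm + 1e-9)
})

test_that("LCMV projection reconstructs a planted source time course", {
  fwd <- fix_forward
  truth <- fwd$rois$frontal_right[1]
  fwd$rois$probe <- truth
  cfg <- sim_config(fs_hz = 200, snr = 10,
                    effect_2hz = list(native_like = c(probe = 1)),
                    effect_4hz = 0, seed = 22)
  sqs <- lapply(1:8, function(i) generate_sequence(fix_lex_native, 19, seed = 80 + i))
  tr <- simulate_trials(fwd, cfg, sqs)
  st <- project_trials(lcmv_filter(fwd, band_covariance(tr)), tr)
  win <- st$time >= 0.5 & st$time < 9.5
  truth_wave <- cos(2 * pi * 2 * st$time +
                      tr$ground_truth$phase_2hz[truth])[win]
  cors <- vapply(seq_len(dim(st$data)[1]), function(i)
    abs(stats::cor(st$data[i, truth, win], truth_wave)), numeric(1))
  expect_gt(mean(cors), 0.9)
  # noise-only data show no spurious 2 Hz structure in the virtual channel
  cfg0 <- sim_config(fs_hz = 200, snr = 0, seed = 23)
  tr0 <- simulate_trials(fwd, cfg0, sqs[1:4])
  st0 <- project_trials(lcmv_filter(fwd, band_covariance(tr0)), tr0)
  cors0 <- vapply(1:4, function(i)
    abs(stats::cor(st0$data[i, truth, win], truth_wave)), numeric(1))
  expect_lt(mean(cors0), 0.3)
})

test_that("ROI averaging is the arithmetic mean over member sources", {
  v <- c(a = 1, b = 3, c = 5, d = 7)
  rois <- list(one = 2L, pair = c(2L, 4L), all = 1:4)
  out <- roi_average(as.numeric(v), rois)
  expect_equal(unname(out), c(3, 5, 4))
  m <- matrix(1:8, 4, 2)
  expect_equal(roi_average(m, rois)["pair", ], colMeans(m[c(2, 4), ]))
  sp <- spectrum_map(matrix(2, 4, 3), c(1, 2, 3))
  expect_true(all(roi_average(sp, rois)$values == 2))
})
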