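sin_trials <- function(freq, n_trials = 4, phase = function(tr) 0, fs = 100,
                       amp = 1) {
  n <- round(10 * fs)
  time <- (seq_len(n) - 1) / fs
  data <- array(0, c(n_trials, 2, n))
  for (tr in seq_len(n_trials)) for (s in 1:2) {
    data[tr, s, ] <- amp * sin(2 * pi * freq * time + phase(tr))
  }
  structure(list(data = data, envelope = matrix(0, n_trials, n), fs_hz = fs,
                 time = time, condition = rep("a", n_trials),
                 block = rep(1:2, length.out = n_trials),
                 is_target = rep(FALSE, n_trials),
                 correct = rep(TRUE, n_trials), ground_truth = NULL),
            class = "ft_trials")
}

test_that("evoked spectra concentrate phase-locked power at the stimulus bin", {
  tr <- sin_trials(4)
  sp <- evoked_spectrum(tr)
  expect_equal(diff(sp$freqs_hz)[1], 1 / 9, tolerance = 1e-12)
  expect_true(all(sp$freqs_hz >= 1 - 1e-9 & sp$freqs_hz <= 7 + 1e-9))
  i4 <- which.min(abs(sp$freqs_hz - 4))
  expect_equal(sp$values[1, i4], 1, tolerance = 0.01)  # unit amplitude -> power 1
  leak_free <- setdiff(seq_along(sp$freqs_hz), i4 + (-1:1))
  expect_gt(sp$values[1, i4] / max(sp$values[1, leak_free]), 100)
  # zero data -> zero spectrum
  tr0 <- sin_trials(4, amp = 0)
  expect_true(all(evoked_spectrum(tr0)$values == 0))
})

test_that("random-phase activity cancels in the evoked average", {
  set.seed(8)
  tr_locked <- sin_trials(4, n_trials = 40)
  tr_rand <- sin_trials(4, n_trials = 40, phase = function(tr) runif(1, 0, 2 * pi))
  i4 <- which.min(abs(evoked_spectrum(tr_locked)$freqs_hz - 4))
  p_locked <- evoked_spectrum(tr_locked)$values[1, i4]
  p_rand <- evoked_spectrum(tr_rand)$values[1, i4]
  # expectation of the random-phase evoked power is 1/n_trials of locked
  expect_lt(p_rand / p_locked, 5 / 40)
})

test_that("spectrum power satisfies the Parseval relation under the taper", {
  set.seed(9)
  fs <- 100
  n <- 900
  x <- rnorm(n)
  tr <- sin_trials(4, n_trials = 1, fs = fs)
  tr$data[1, 1, ] <- c(x, numeric(round(10 * fs) - n))
  sp <- evoked_spectrum(tr, window = c(0, 9), taper = "rect", fmin = 0, fmax = Inf)
  # one-sided Parseval identity for the rect taper:
  # sum_k (2|X_k|/N)^2 over 0..N/2 = 2 mean(x^2) + 2 mean(x)^2 + 2|X_Nyq|^2/N^2
  total <- sum(sp$values[1, ])
  X <- stats::fft(x)
  expected <- 2 * mean(x^2) + 2 * mean(x)^2 + 2 * Mod(X[n / 2 + 1])^2 / n^2
  expect_equal(total, expected, tolerance = 1e-6)
})

test_that("neighbour-bin contrast follows its arithmetic definition", {
  freqs <- seq(1, 7, by = 1 / 9)
  flat <- spectrum_map(matrix(2, 3, length(freqs)), freqs)
  expect_equal(neighbor_bin_contrast(flat, 4), rep(0, 3))
  # delta of height h over a flat floor: contrast = h
  vals <- matrix(1, 1, length(freqs))
  i4 <- which.min(abs(freqs - 4))
  vals[1, i4] <- 1 + 7
  sp <- spectrum_map(vals, freqs)
  expect_equal(neighbor_bin_contrast(sp, 4), 7)
  # linearity in the spectrum
  sp2 <- spectrum_map(3 * vals, freqs)
  expect_equal(neighbor_bin_contrast(sp2, 4), 3 * neighbor_bin_contrast(sp, 4))
  expect_error(neighbor_bin_contrast(sp, 4.05), "grid")
  expect_error(neighbor_bin_contrast(sp, 2, offsets = c(-300, 300)), "outside")
})

test_that("jackknife values collapse to the full-set value for identical trials", {
  tr <- sin_trials(4, n_trials = 6)
  jk <- jackknife_trial_power(tr, 4)
  expect_equal(nrow(jk), 6)
  expect_lt(diff(range(jk$jk_power)), 1e-10)
  full <- mean(neighbor_bin_contrast(evoked_spectrum(tr), 4))
  expect_equal(jk$jk_power[1], full, tolerance = 1e-8)
})

test_that("with two trials each jackknife value is the other trial's spectrum", {
  tr <- sin_trials(4, n_trials = 2)
  tr$data[2, , ] <- 2 * tr$data[2, , ]
  jk <- jackknife_trial_power(tr, 4)
  s1 <- mean(neighbor_bin_contrast(evoked_spectrum(subset_trials(tr, 1)), 4))
  s2 <- mean(neighbor_bin_contrast(evoked_spectrum(subset_trials(tr, 2)), 4))
  expect_equal(jk$jk_power[1], s2, tolerance = 1e-8)
  expect_equal(jk$jk_power[2], s1, tolerance = 1e-8)
})

test_that("the jackknife mean approaches the full-sample contrast", {
  set.seed(10)
  tr <- sin_trials(4, n_trials = 50)
  tr$data <- tr$data + array(rnorm(length(tr$data), sd = 0.5), dim(tr$data))
  jk <- jackknife_trial_power(tr, 4)
  full <- mean(neighbor_bin_contrast(evoked_spectrum(tr), 4))
  expect_equal(mean(jk$jk_power), full, tolerance = 0.02 * abs(full))
})

test_that("block trends recover planted polynomial structure with min-BIC order", {
  # exact quadratic, no noise: order-2 fit is exact
  block <- rep(1:10, each = 4)
  y <- 2 + 0.5 * block - 0.3 * block^2
  trend <- block_trend(y, block)
  expect_equal(trend$best_order, 2)
  fit <- trend$fits[[2]]
  expect_lt(max(abs(stats::residuals(fit))), 1e-9)
  # flat noisy data prefer the simpler model
  set.seed(11)
  y_flat <- rnorm(40)
  t_flat <- block_trend(y_flat, block)
  expect_lt(t_flat$bic[1], t_flat$bic[2])
  expect_true(all(abs(dplyr::filter(t_flat$table, .data$order == 1,
                                    .data$term != "(Intercept)")$estimate) < 2))
  # inverted-U (learning then fatigue) -> negative quadratic coefficient
  y_u <- -(block - 5.5)^2 + rnorm(40, sd = 0.5)
  t_u <- block_trend(y_u, block)
  q <- dplyr::filter(t_u$table, .data$order == 2, grepl("2$", .data$term))
  expect_lt(q$estimate, 0)
  expect_lt(q$p, 0.001)
  expect_error(block_trend(y[block <= 2], block[block <= 2], max_order = 2),
               "blocks")
  # tidy/glance accessors
  expect_s3_class(tidy(t_u), "tbl_df")
  expect_equal(nrow(glance(t_u)), 2)
})
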