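fs_hi <- 1200

make_trials <- function(data_fun, n_trials = 3, n_sensors = 4, fs = fs_hi,
                        t0 = -0.5, dur = 4) {
  n <- round(dur * fs)
  time <- t0 + (seq_len(n) - 1) / fs
  data <- array(0, c(n_trials, n_sensors, n))
  for (tr in seq_len(n_trials)) for (s in seq_len(n_sensors)) {
    data[tr, s, ] <- data_fun(time, tr, s)
  }
  structure(list(data = data, envelope = matrix(0, n_trials, n), fs_hz = fs,
                 time = time, condition = rep("a", n_trials),
                 block = rep(1L, n_trials), is_target = rep(FALSE, n_trials),
                 correct = rep(TRUE, n_trials), ground_truth = NULL),
            class = "ft_trials")
}

amp_at <- function(x, keep = seq(round(length(x) * 0.3), round(length(x) * 0.7))) {
  max(abs(x[keep]))
}

test_that("band-pass 1-160 Hz attenuates drift and preserves in-band signals", {
  t <- (0:(20 * fs_hi - 1)) / fs_hi
  slow <- sin(2 * pi * 0.1 * t)
  out <- filter_bandpass(slow, 1, 160, fs_hz = fs_hi)
  expect_lt(amp_at(out), 0.1)                       # > 20 dB down
  mid <- sin(2 * pi * 10 * t)
  expect_equal(amp_at(filter_bandpass(mid, 1, 160, fs_hz = fs_hi)), 1,
               tolerance = 0.01)
  expect_true(all(filter_bandpass(numeric(1000) , 1, 160, fs_hz = fs_hi) == 0))
  expect_error(filter_bandpass(mid, 1, 700, fs_hz = fs_hi), "invalid")
})

test_that("line-noise band-stops notch 50 Hz and spare 45 Hz", {
  t <- (0:(8 * fs_hi - 1)) / fs_hi
  line <- sin(2 * pi * 50 * t)
  expect_lt(amp_at(filter_bandstop_line(line, fs_hz = fs_hi)), 0.1)
  near <- sin(2 * pi * 45 * t)
  expect_equal(amp_at(filter_bandstop_line(near, fs_hz = fs_hi)), 1,
               tolerance = 0.05)
  expect_true(all(filter_bandstop_line(numeric(1000), fs_hz = fs_hi) == 0))
})

test_that("zero-phase filtering has no lag for an in-band sinusoid", {
  t <- (0:(4 * fs_hi - 1)) / fs_hi
  x <- sin(2 * pi * 8 * t)
  y <- filter_bandpass(x, 1, 160, fs_hz = fs_hi)
  mid <- 1000:3800
  cc <- stats::ccf(x[mid], y[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("muscular and jump artifacts are detected at the conventional z thresholds", {
  set.seed(5)
  tr <- make_trials(function(time, tr, s) rnorm(length(time)), n_trials = 20)
  # a 50x burst at 120 Hz in trial 2 only
  burst <- function(time) 50 * sin(2 * pi * 120 * time) * (time > 1 & time < 1.3)
  tr$data[2, , ] <- tr$data[2, , ] + matrix(burst(tr$time), 4, length(tr$time),
                                            byrow = TRUE)
  rep_m <- detect_artifacts(tr, "muscular")
  expect_identical(which(rep_m$rejected), 2L)
  # a step discontinuity in trial 3
  tr2 <- make_trials(function(time, tr, s) rnorm(length(time)), n_trials = 20)
  tr2$data[3, , ] <- tr2$data[3, , ] + matrix(80 * (tr2$time > 2), 4,
                                              length(tr2$time), byrow = TRUE)
  rep_j <- detect_artifacts(tr2, "jump")
  expect_identical(which(rep_j$rejected), 3L)
  expect_identical(attr(rep_m, "threshold"), 15)
  expect_identical(attr(rep_j, "threshold"), 30)
})

test_that("clean Gaussian data produce no rejections and rejection is idempotent", {
  set.seed(6)
  tr <- make_trials(function(time, tr, s) rnorm(length(time)), n_trials = 20)
  rep_m <- detect_artifacts(tr, "muscular")
  rep_j <- detect_artifacts(tr, "jump")
  expect_equal(sum(rep_m$rejected), 0)
  expect_equal(sum(rep_j$rejected), 0)
  # idempotence on a set that had one artifact removed
  tr$data[4, , ] <- tr$data[4, , ] + matrix(50 * sin(2 * pi * 120 * tr$time) *
    (tr$time > 0), 4, length(tr$time), byrow = TRUE)
  r1 <- detect_artifacts(tr, "muscular")
  clean <- subset_trials(tr, !r1$rejected)
  r2 <- detect_artifacts(clean, "muscular")
  expect_equal(sum(r2$rejected), 0)
})

test_that("range rejection uses the min-max threshold per channel", {
  tr <- make_trials(function(time, tr, s) rep(1e-6, length(time)))
  expect_equal(sum(reject_range(tr)$rejected), 0)            # constant channels
  tr$data[2, 1, ] <- seq(0, 1e-5, length.out = length(tr$time))
  expect_identical(which(reject_range(tr)$rejected), 2L)     # 1e-5 drift
  expect_equal(sum(reject_range(tr, threshold = Inf)$rejected), 0)
})

test_that("epoching and downsampling: 11.7 s at 1200 Hz becomes 5850 samples at 500 Hz", {
  cfg <- sim_config(fs_hz = 1200, snr = 0, seed = 1)
  sqs <- fix_seqs_native[1]
  tr <- simulate_trials(fix_forward, cfg, sqs)
  expect_equal(dim(tr$data)[3], round(11.7 * 1200))
  out <- epoch_downsample(tr, window = c(-2.1, 9.6), fs_out = 500)
  expect_equal(dim(out$data)[3], 5850)
  expect_equal(out$fs_hz, 500)
  expect_equal(ncol(out$envelope), 5850)
  expect_error(epoch_downsample(tr, window = c(-5, 9.6)), "outside")
})

test_that("downsampling preserves a 4 Hz component within 1%", {
  tr <- make_trials(function(time, tr, s) sin(2 * pi * 4 * time), n_trials = 1,
                    n_sensors = 1, t0 = 0, dur = 5)
  out <- epoch_downsample(tr, window = c(0, 5), fs_out = 500)
  expect_equal(amp_at(out$data[1, 1, ]), 1, tolerance = 0.01)
  # spectrum at 4 Hz matches the original rate within 1%
  sp_hi <- evoked_spectrum(tr, window = c(0.5, 4.5), fmin = 1, fmax = 7)
  sp_lo <- evoked_spectrum(out, window = c(0.5, 4.5), fmin = 1, fmax = 7)
  i <- which.min(abs(sp_hi$freqs_hz - 4))
  expect_equal(sp_lo$values[1, i] / sp_hi$values[1, i], 1, tolerance = 0.01)
})

test_that("trial-count matching equalizes correct trials across conditions", {
  set.seed(7)
  tr <- make_trials(function(time, tr, s) rnorm(length(time)), n_trials = 12)
  tr$condition <- rep(c("a", "b"), each = 6)
  tr$correct <- rep(TRUE, 12)
  tr$correct[1] <- FALSE                       # a: 5 correct, b: 6
  out <- match_trial_counts(tr, seed = 1)
  expect_equal(as.integer(table(out$condition)), c(5L, 5L))
  expect_true(all(out$correct))
  out2 <- match_trial_counts(tr, seed = 1)
  expect_identical(out$data, out2$data)        # seeded selection
})

test_that("M100 sensor selection finds the top-gain sensors of a dipolar pattern", {
  src <- fix_forward$rois$auditory_left[1]
  l <- freqtag:::.ft_source_leadfield(fix_forward, src) %*% c(1, 0, 0)
  fs <- 600
  t <- (0:(0.3 * fs - 1)) / fs
  m100 <- exp(-((t - 0.1) / 0.02)^2)           # evoked peak near 100 ms
  evoked <- as.numeric(l) %o% m100
  sel <- select_m100_sensors(evoked, fs, k = 5)
  expect_setequal(sel, order(-abs(l))[1:5])
  expect_length(select_m100_sensors(evoked, fs, k = nrow(evoked)), nrow(evoked))
  # flat evoked: deterministic tie-break by sensor index
  flat <- matrix(1, 8, length(t))
  expect_identical(select_m100_sensors(flat, fs, k = 3), 1:3)
  expect_error(select_m100_sensors(evoked, fs, k = 999), "exceeds")
})
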