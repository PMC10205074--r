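# Preprocessing chain for ft_trials: zero-phase Butterworth filtering, line
# noise removal, z-score and range artifact rejection, epoching with
# anti-aliased downsampling, trial-count matching, and auditory (M100)
# sensor selection.

.ft_map_trials <- function(trials, f) {
  # apply f to each trial's sensors x samples matrix (transposed to
  # samples x sensors for column-wise filtering)
  for (tr in seq_len(dim(trials$data)[1])) {
    m <- trial_matrix(trials$data, tr)
    trials$data[tr, , ] <- t(f(m))
  }
  trials
}

#' Zero-phase band-pass filter
#'
#' Forward-reverse (zero-phase) Butterworth band-pass, applied per trial and
#' sensor. DC is removed by the high-pass edge; output length is preserved.
#'
#' @param trials An `ft_trials` (or numeric samples x channels matrix with
#'   `fs_hz` supplied).
#' @param low_hz,high_hz Band edges in Hz (default 1-160).
#' @param order Filter order (default 4).
#' @param fs_hz Sample rate, required for matrix input.
#' @return The filtered object of the same type.
#' @export
filter_bandpass <- function(trials, low_hz = 1, high_hz = 160, order = 4,
                            fs_hz = NULL) {
  if (inherits(trials, "ft_trials")) {
    .ft_map_trials(trials, function(m)
      butter_filtfilt(m, low_hz, high_hz, trials$fs_hz, order))
  } else {
    stopifnot(!is.null(fs_hz))
    butter_filtfilt(trials, low_hz, high_hz, fs_hz, order)
  }
}

#' Zero-phase band-stop filters for line noise
#'
#' Applies one zero-phase Butterworth band-stop per line-frequency harmonic
#' (default 49.5-50.5, 99.5-100.5, 149.5-150.5 Hz).
#'
#' @inheritParams filter_bandpass
#' @param centers_hz Center frequencies (default `c(50, 100, 150)`); centers
#'   at or above Nyquist are skipped.
#' @param half_width_hz Half width of each stop band (default 0.5).
#' @return The filtered object of the same type.
#' @export
filter_bandstop_line <- function(trials, centers_hz = c(50, 100, 150),
                                 half_width_hz = 0.5, order = 4, fs_hz = NULL) {
  fs <- if (inherits(trials, "ft_trials")) trials$fs_hz else fs_hz
  stopifnot(!is.null(fs))
  centers_hz <- centers_hz[centers_hz + half_width_hz < fs / 2]
  f <- function(m) {
    for (c0 in centers_hz) {
      m <- butter_filtfilt(m, c0 - half_width_hz, c0 + half_width_hz, fs,
                           order, type = "stop")
    }
    m
  }
  if (inherits(trials, "ft_trials")) .ft_map_trials(trials, f) else f(trials)
}

#' Detect muscular or jump artifacts by sensor-averaged z scores
#'
#' For `kind = "muscular"` each trial is band-passed 110-140 Hz; for
#' `kind = "jump"` a running median (window 9 samples) smooths the signal
#' while preserving edges, and the absolute first difference then turns any
#' step discontinuity into a spike. The result is z-normalized per sensor (mean/SD pooled over all trials'
#' samples, so an artifact confined to one trial stands out against the
#' whole session), z scores are averaged over sensors, and a trial is
#' rejected when its maximum averaged z exceeds the threshold (default 15
#' muscular, 30 jump). Zero-variance sensors are excluded from the average
#' with a warning.
#'
#' @param trials An `ft_trials`.
#' @param kind `"muscular"` or `"jump"`.
#' @param z_threshold Rejection threshold; defaults to 15 (muscular) or
#'   30 (jump).
#' @param scope `"pooled"` (default) normalizes with statistics pooled
#'   across trials; `"per_trial"` uses each trial's own mean/SD.
#' @return An `ft_artifacts` tibble: `trial`, `max_z`, `rejected`, with
#'   attributes `kind`, `threshold` and `scope`.
#' @export
detect_artifacts <- function(trials, kind = c("muscular", "jump"),
                             z_threshold = NULL,
                             scope = c("pooled", "per_trial")) {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  stopifnot(inherits(trials, "ft_trials"))
  if (is.null(z_threshold)) z_threshold <- if (kind == "muscular") 15 else 30
  if (kind == "muscular" && trials$fs_hz / 2 <= 140) {
    abort("sample rate too low for the 110-140 Hz muscular band")
  }
  nt <- dim(trials$data)[1]
  filtered <- vector("list", nt)
  for (tr in seq_len(nt)) {
    m <- trial_matrix(trials$data, tr)         # samples x sensors
    filtered[[tr]] <- if (kind == "muscular") {
      butter_filtfilt(m, 110, 140, trials$fs_hz, order = 4)
    } else {
      apply_cols(m, function(v) c(0, abs(diff(stats::runmed(v, 9)))))
    }
  }
  if (scope == "pooled") {
    all_m <- do.call(rbind, filtered)
    mu <- colMeans(all_m)
    sds <- apply(all_m, 2, stats::sd)
  }
  warned <- FALSE
  max_z <- numeric(nt)
  for (tr in seq_len(nt)) {
    m <- filtered[[tr]]
    if (scope == "per_trial") {
      mu <- colMeans(m)
      sds <- apply(m, 2, stats::sd)
    }
    ok <- sds > 0
    if (!all(ok) && !warned) {
      warn(sprintf("%d zero-variance sensor(s) excluded from artifact z averaging",
                   sum(!ok)))
      warned <- TRUE
    }
    z <- sweep(sweep(m[, ok, drop = FALSE], 2, mu[ok]), 2, sds[ok], "/")
    max_z[tr] <- max(abs(rowMeans(z)))
  }
  structure(
    tibble(trial = seq_len(nt), max_z = max_z, rejected = max_z > z_threshold),
    kind = kind, threshold = z_threshold, scope = scope,
    class = c("ft_artifacts", class(tibble())))
}

#' Reject trials by per-channel range
#'
#' A trial is rejected when the min-max difference of any channel exceeds
#' the threshold (default 0.75e-5, in the data's units).
#'
#' @param trials An `ft_trials`.
#' @param threshold Range threshold (default `0.75e-5`).
#' @return An `ft_artifacts` tibble: `trial`, `max_range`, `rejected`.
#' @export
reject_range <- function(trials, threshold = 0.75e-5) {
  stopifnot(inherits(trials, "ft_trials"))
  nt <- dim(trials$data)[1]
  max_range <- vapply(seq_len(nt), function(tr) {
    m <- t(trial_matrix(trials$data, tr))      # sensors x samples
    max(apply(m, 1, function(v) diff(range(v))))
  }, numeric(1))
  structure(
    tibble(trial = seq_len(nt), max_range = max_range,
           rejected = max_range > threshold),
    kind = "range", threshold = threshold,
    class = c("ft_artifacts", class(tibble())))
}

#' Crop to an epoch window and downsample
#'
#' Crops each trial to `window` (seconds relative to stimulus onset) and
#' resamples data and acoustic envelope to `fs_out` with the polyphase FIR
#' anti-aliasing resampler. The output has `round(diff(window) * fs_out)`
#' samples.
#'
#' @param trials An `ft_trials`.
#' @param window Epoch limits, must lie within the trials' time axis
#'   (default `c(-2.1, 9.6)`).
#' @param fs_out Output sample rate (default 500).
#' @return The cropped, resampled `ft_trials`.
#' @export
epoch_downsample <- function(trials, window = c(-2.1, 9.6), fs_out = 500) {
  stopifnot(inherits(trials, "ft_trials"), length(window) == 2)
  tol <- 0.5 / trials$fs_hz
  if (window[1] < min(trials$time) - tol || window[2] > max(trials$time) + 1 / trials$fs_hz + tol) {
    abort("window outside the data's time axis")
  }
  keep <- trials$time >= window[1] - tol & trials$time < window[2] - tol
  n_out <- round(diff(window) * fs_out)
  nt <- dim(trials$data)[1]
  n_sensors <- dim(trials$data)[2]
  out <- trials
  out$data <- array(0, c(nt, n_sensors, n_out))
  out$envelope <- matrix(0, nt, n_out)
  for (tr in seq_len(nt)) {
    m <- trial_matrix(trials$data, tr, keep)
    r <- resample_to(m, trials$fs_hz, fs_out)
    out$data[tr, , ] <- t(r[seq_len(n_out), , drop = FALSE])
    e <- resample_to(trials$envelope[tr, keep], trials$fs_hz, fs_out)
    out$envelope[tr, ] <- e[seq_len(n_out)]
  }
  out$fs_hz <- fs_out
  out$time <- window[1] + (seq_len(n_out) - 1) / fs_out
  out
}

#' Match trial counts across conditions
#'
#' Keeps correct-response trials only and randomly subsamples every
#' condition down to the smallest per-condition count, with a seeded
#' selection.
#'
#' @param trials An `ft_trials`.
#' @param seed Integer seed.
#' @return The matched `ft_trials`.
#' @export
match_trial_counts <- function(trials, seed = 1) {
  stopifnot(inherits(trials, "ft_trials"))
  set.seed(seed)
  ok <- which(trials$correct)
  counts <- table(trials$condition[ok])
  n_min <- min(counts)
  keep <- sort(unlist(lapply(names(counts), function(cc) {
    idx <- ok[trials$condition[ok] == cc]
    if (length(idx) > n_min) sample(idx, n_min) else idx
  })))
  subset_trials(trials, keep)
}

#' Select auditory (M100) sensors from a localizer evoked response
#'
#' Returns the `k` sensors with the largest RMS evoked amplitude within the
#' latency window after tone onset. Ties are broken by ascending sensor
#' index.
#'
#' @param evoked Sensors x samples matrix of the evoked response.
#' @param fs_hz Sample rate of `evoked`.
#' @param k Number of sensors to select.
#' @param latency_window Window in seconds after onset (default
#'   `c(0.08, 0.12)`); onset is sample 1 unless `onset_s` shifts it.
#' @param onset_s Time of sample 1 relative to tone onset (default 0).
#' @return Integer vector of `k` sensor indices, sorted by decreasing RMS.
#' @export
select_m100_sensors <- function(evoked, fs_hz, k,
                                latency_window = c(0.08, 0.12), onset_s = 0) {
  stopifnot(is.matrix(evoked))
  if (k > nrow(evoked)) abort("k exceeds the number of sensors")
  t_axis <- onset_s + (seq_len(ncol(evoked)) - 1) / fs_hz
  win <- t_axis >= latency_window[1] & t_axis <= latency_window[2]
  if (!any(win)) abort("latency window outside the evoked response")
  rms <- sqrt(rowMeans(evoked[, win, drop = FALSE]^2))
  order(-rms, seq_along(rms))[seq_len(k)]
}
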