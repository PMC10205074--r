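# Trial simulator: projects ground-truth source activity through the toy
# leadfield and adds spatially correlated 1/f noise. Effects mirror the
# tagging design: envelope-driven 4 Hz responses in auditory sources,
# condition-dependent 2 Hz responses, and an optional dependence of the 2 Hz
# amplitude on the 4 Hz envelope (cross-frequency coupling).

#' Simulation configuration
#'
#' @param fs_hz Sample rate in Hz (default 1200, the acquisition rate of a
#'   typical MEG system; analyses downstream downsample).
#' @param epoch_window_s Epoch limits in seconds relative to stimulus onset
#'   (default `c(-2.1, 9.6)`; the stimulus occupies 0 to `n_syllables * ioi`).
#' @param syllable_rate_hz,unit_rate_hz Tagging rates; the unit rate must be
#'   half the syllable rate (defaults 4 and 2).
#' @param snr Source-to-noise amplitude ratio: a unit-amplitude source
#'   yields per-sensor signal RMS equal to `snr` times the per-sensor noise
#'   RMS. `snr = 0` yields noise-only data.
#' @param effect_2hz Named list mapping each condition label to a named
#'   numeric vector of ROI -> 2 Hz source amplitude.
#' @param effect_4hz Envelope-driven 4 Hz amplitude: a scalar applied to
#'   both auditory ROIs, or a named vector of ROI -> amplitude.
#' @param cfc_strength Coefficient in `[0, 1]` coupling the standardized
#'   4 Hz envelope to the 2 Hz source amplitude (0 = none).
#' @param noise_exponent Spectral slope of the 1/f^exponent background
#'   noise (default 1).
#' @param sensor_noise Independent white sensor-noise amplitude relative to
#'   the projected brain noise (default 0.1).
#' @param response_jitter Amplitude of slow multiplicative gain
#'   fluctuations, independent per active source and trial (default 0,
#'   i.e. fully reliable responses; positive values emulate sources whose
#'   responses are not perfectly coherent across trials or hemispheres).
#' @param token_jitter_sd Per-token log-amplitude jitter of the acoustic
#'   envelope (default 0.15, mimicking natural intensity variation; it is
#'   independent of syllable position so it adds no unit-rate cue).
#' @param n_noise Number of source locations carrying independent 1/f
#'   noise generators (default `Inf`, i.e. every grid source; the noise is
#'   projected through the leadfield, so every beamformed virtual channel
#'   sees a local noise floor).
#' @param response_accuracy Probability of a correct behavioral response per
#'   trial: scalar or named per-condition vector (default 1).
#' @param orientation `"random"` (default) draws an isotropic random fixed
#'   orientation per source; `"dominant"` uses each source leadfield's
#'   dominant direction instead.
#' @param seed Integer seed; the simulated dataset is bit-identical for
#'   identical seed and configuration.
#' @return A validated list of class `ft_sim_config`.
#' @export
sim_config <- function(fs_hz = 1200, epoch_window_s = c(-2.1, 9.6),
                       syllable_rate_hz = 4, unit_rate_hz = 2,
                       snr = 1, effect_2hz = list(), effect_4hz = 1,
                       cfc_strength = 0, noise_exponent = 1,
                       sensor_noise = 0.1, token_jitter_sd = 0.15,
                       response_jitter = 0, n_noise = Inf,
                       response_accuracy = 1,
                       orientation = c("random", "dominant"), seed = 1) {
  if (snr < 0) abort("snr must be >= 0")
  if (cfc_strength < 0 || cfc_strength > 1) abort("cfc_strength must be in [0, 1]")
  if (abs(unit_rate_hz - syllable_rate_hz / 2) > 1e-9) {
    abort("unit_rate_hz must equal syllable_rate_hz / 2")
  }
  orientation <- match.arg(orientation)
  stopifnot(length(epoch_window_s) == 2, diff(epoch_window_s) > 0, fs_hz > 0)
  structure(
    list(fs_hz = fs_hz, epoch_window_s = epoch_window_s,
         syllable_rate_hz = syllable_rate_hz, unit_rate_hz = unit_rate_hz,
         snr = snr, effect_2hz = effect_2hz, effect_4hz = effect_4hz,
         cfc_strength = cfc_strength, noise_exponent = noise_exponent,
         sensor_noise = sensor_noise, token_jitter_sd = token_jitter_sd,
         response_jitter = response_jitter, n_noise = n_noise,
         response_accuracy = response_accuracy, orientation = orientation,
         seed = seed),
    class = "ft_sim_config")
}

#' Simulate multichannel trials from a forward model and stimulus sequences
#'
#' For each trial the sensor data are the leadfield projection of (a)
#' envelope-driven, phase-locked 4 Hz responses in the auditory ROI sources,
#' (b) 2 Hz responses in the sources named by `effect_2hz` for the trial's
#' condition, whose instantaneous amplitude is
#' `base * (1 + cfc_strength * standardized 4 Hz envelope)`, and (c)
#' spatially correlated 1/f noise. Each active source has a fixed random
#' orientation; effective leadfield columns are unit-normalized so that
#' `snr` is interpretable as a per-sensor amplitude ratio.
#'
#' @param forward An [make_forward_model()] model.
#' @param config An [sim_config()].
#' @param trials Tibble from [generate_experiment()] (columns `condition`,
#'   `sequence`, optionally `block`, `is_target`), or a list of
#'   `ft_sequence` objects (condition taken from each sequence).
#' @return An `ft_trials` object: list with `data` (trials x sensors x
#'   samples), `envelope` (trials x samples), `fs_hz`, `time`, `condition`,
#'   `block`, `is_target`, `correct`, and `ground_truth`.
#' @export
simulate_trials <- function(forward, config, trials) {
  stopifnot(inherits(forward, "ft_forward"), inherits(config, "ft_sim_config"))
  if (!is.data.frame(trials)) {
    trials <- tibble(
      condition = vapply(trials, function(s) s$condition, character(1)),
      sequence = trials, block = 1L, is_target = FALSE)
  }
  stopifnot(all(c("condition", "sequence") %in% names(trials)))
  if (is.null(trials$block)) trials$block <- 1L
  if (is.null(trials$is_target)) trials$is_target <- FALSE

  conds <- unique(trials$condition)
  if (length(config$effect_2hz) > 0) {
    missing <- setdiff(conds, names(config$effect_2hz))
    if (length(missing) > 0) {
      abort(paste0("condition(s) missing from effect_2hz: ",
                   paste(missing, collapse = ", ")))
    }
  }

  set.seed(config$seed)
  fs <- config$fs_hz
  win <- config$epoch_window_s
  n <- round(diff(win) * fs)
  time <- win[1] + (seq_len(n) - 1) / fs
  n_trials <- nrow(trials)
  n_sensors <- nrow(forward$sensor_positions)
  n_sources <- nrow(forward$source_positions)

  # fixed random orientation and 2 Hz carrier phase per source, shared
  # across trials (random relative phases between regions, as in real
  # evoked responses; they keep sources mutually decorrelated without
  # affecting power envelopes)
  orient <- matrix(stats::rnorm(3 * n_sources), ncol = 3)
  orient <- orient / sqrt(rowSums(orient^2))
  if (identical(config$orientation, "dominant")) {
    orient <- t(vapply(seq_len(n_sources), function(s)
      svd(.ft_source_leadfield(forward, s))$v[, 1], numeric(3)))
  }
  phase2 <- stats::runif(n_sources, 0, 2 * pi)
  l_eff <- vapply(seq_len(n_sources), function(s) {
    l <- .ft_source_leadfield(forward, s) %*% orient[s, ]
    as.numeric(l / sqrt(sum(l^2)))
  }, numeric(n_sensors))                       # n_sensors x n_sources

  e4 <- config$effect_4hz
  if (is.null(names(e4))) {
    e4 <- stats::setNames(rep(e4[1], 2), c("auditory_left", "auditory_right"))
  }
  src4 <- unlist(lapply(names(e4), function(r) {
    stats::setNames(rep(e4[[r]], length(forward$rois[[r]])), forward$rois[[r]])
  }))
  active2 <- lapply(config$effect_2hz, function(m) {
    unlist(lapply(names(m), function(r) {
      stats::setNames(rep(m[[r]], length(forward$rois[[r]])), forward$rois[[r]])
    }))
  })

  stim <- time >= 0
  acc <- config$response_accuracy
  data <- array(0, dim = c(n_trials, n_sensors, n))
  envelope <- matrix(0, n_trials, n)
  correct <- logical(n_trials)

  for (tr in seq_len(n_trials)) {
    sq <- trials$sequence[[tr]]
    env <- sequence_envelope(sq, time, token_jitter_sd = config$token_jitter_sd)
    envelope[tr, ] <- env

    drive4 <- butter_filtfilt(env - mean(env[stim]), 3, 5, fs, order = 2)
    drive4 <- drive4 / stats::sd(drive4[stim])
    env4 <- hilbert_envelope(drive4)
    std4 <- (env4 - mean(env4[stim])) / stats::sd(env4[stim])

    amp2 <- pmax(0, 1 + config$cfc_strength * std4)

    amps <- numeric(n_sources)
    waves <- matrix(0, 0, n)
    cols <- integer(0)
    if (any(src4 != 0)) {
      for (s in names(src4)) {
        waves <- rbind(waves, src4[[s]] * .ft_gain(n, config$response_jitter) *
                         drive4 * stim)
        cols <- c(cols, as.integer(s))
      }
    }
    a2 <- active2[[trials$condition[tr]]]
    if (!is.null(a2) && any(a2 != 0)) {
      for (s in names(a2)) {
        si <- as.integer(s)
        carrier2 <- cos(2 * pi * config$unit_rate_hz * time + phase2[si]) * stim
        carrier2 <- carrier2 / stats::sd(carrier2[stim])
        waves <- rbind(waves, a2[[s]] * .ft_gain(n, config$response_jitter) *
                         amp2 * carrier2)
        cols <- c(cols, si)
      }
    }
    signal <- if (length(cols) > 0) l_eff[, cols, drop = FALSE] %*% waves
              else matrix(0, n_sensors, n)

    noise <- .ft_brain_noise(l_eff, n, config$n_noise, config$noise_exponent,
                             config$sensor_noise)
    data[tr, , ] <- config$snr * sqrt(n_sensors) * signal + noise

    p <- if (length(acc) > 1) acc[[trials$condition[tr]]] else acc
    correct[tr] <- stats::runif(1) < p
  }

  structure(
    list(data = data, envelope = envelope, fs_hz = fs, time = time,
         condition = trials$condition, block = trials$block,
         is_target = trials$is_target, correct = correct,
         ground_truth = list(orientations = orient, phase_2hz = phase2,
                             sources_4hz = src4,
                             sources_2hz = active2,
                             cfc_strength = config$cfc_strength,
                             effective_leadfield = l_eff)),
    class = "ft_trials")
}

# slow (1/f^2-shaped) multiplicative gain fluctuation around 1
.ft_gain <- function(n, jitter) {
  if (jitter <= 0) return(rep(1, n))
  pmax(1 + jitter * one_over_f_noise(n, 2), 0)
}

# spatially correlated "brain noise": independent 1/f generators at sources
# drawn at random, projected through the effective leadfield, plus a small
# independent sensor-noise floor; normalized to unit per-sensor RMS
.ft_brain_noise <- function(l_eff, n, k, alpha, sensor_noise) {
  n_sensors <- nrow(l_eff)
  n_sources <- ncol(l_eff)
  src <- if (k >= n_sources) seq_len(n_sources) else sample(n_sources, k)
  gen <- vapply(src, function(i) one_over_f_noise(n, alpha), numeric(n))
  out <- l_eff[, src, drop = FALSE] %*% t(gen) / sqrt(length(src))
  out <- out / sqrt(mean(out^2))
  out <- out + sensor_noise * matrix(stats::rnorm(n_sensors * n), n_sensors, n)
  out / sqrt(mean(out^2))
}

#' @export
print.ft_trials <- function(x, ...) {
  cat(sprintf("<ft_trials> %d trials x %d sensors x %d samples @ %g Hz, conditions: %s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs_hz,
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Subset trials
#'
#' @param trials An `ft_trials`.
#' @param idx Integer or logical trial index.
#' @return An `ft_trials` with the selected trials.
#' @export
subset_trials <- function(trials, idx) {
  stopifnot(inherits(trials, "ft_trials"))
  out <- trials
  out$data <- trials$data[idx, , , drop = FALSE]
  out$envelope <- trials$envelope[idx, , drop = FALSE]
  out$condition <- trials$condition[idx]
  out$block <- trials$block[idx]
  out$is_target <- trials$is_target[idx]
  out$correct <- trials$correct[idx]
  out
}

#' Number of trials
#' @param trials An `ft_trials`.
#' @return Integer trial count.
#' @export
n_trials <- function(trials) dim(trials$data)[1]
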