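# Cochlear-filterbank speech envelope, modulation spectra, and
# cerebro-acoustic coherence in beamformed source space.

#' ERB-rate scale helpers
#'
#' Conversion between frequency in Hz and the ERB-rate (equivalent
#' rectangular bandwidth) scale used to space cochlear filterbank bands.
#'
#' @param f_hz Frequency in Hz.
#' @param erb ERB-rate value.
#' @return The converted value.
#' @export
hz_to_erb <- function(f_hz) 21.4 * log10(1 + 0.00437 * f_hz)

#' @rdname hz_to_erb
#' @export
erb_to_hz <- function(erb) (10^(erb / 21.4) - 1) / 0.00437

#' Cochlear filterbank
#'
#' Splits a waveform into `n_bands` zero-phase Butterworth band-pass
#' channels whose edges are equidistant on an auditory-frequency scale
#' between `range_hz[1]` and `range_hz[2]` (ERB-rate by default, log
#' spacing as an option).
#'
#' @param waveform Numeric waveform.
#' @param fs_hz Sample rate; must exceed twice the upper band edge.
#' @param n_bands Number of bands (default 8).
#' @param range_hz Frequency range (default `c(100, 8000)`).
#' @param order Butterworth order (default 3).
#' @param scale `"erb"` (default) or `"log"`.
#' @return An `ft_bands` list: `bands` (samples x n_bands matrix),
#'   `edges_hz` (length n_bands + 1), `fs_hz`.
#' @export
cochlear_filterbank <- function(waveform, fs_hz, n_bands = 8,
                                range_hz = c(100, 8000), order = 3,
                                scale = c("erb", "log")) {
  scale <- match.arg(scale)
  if (fs_hz <= 2 * range_hz[2]) {
    abort(sprintf("fs_hz = %g too low to cover %g Hz", fs_hz, range_hz[2]))
  }
  edges <- if (scale == "erb") {
    erb_to_hz(seq(hz_to_erb(range_hz[1]), hz_to_erb(range_hz[2]),
                  length.out = n_bands + 1))
  } else {
    exp(seq(log(range_hz[1]), log(range_hz[2]), length.out = n_bands + 1))
  }
  edges[1] <- range_hz[1]; edges[n_bands + 1] <- range_hz[2]
  bands <- vapply(seq_len(n_bands), function(b) {
    butter_filtfilt(waveform, edges[b], edges[b + 1], fs_hz, order)
  }, numeric(length(waveform)))
  structure(list(bands = bands, edges_hz = edges, fs_hz = fs_hz),
            class = "ft_bands")
}

#' Extract the wide-band envelope from filterbank channels
#'
#' Averages the Hilbert magnitudes of the filterbank channels and resamples
#' (anti-aliased) to `fs_out`.
#'
#' @param bands An [cochlear_filterbank()] result (or samples x bands
#'   matrix with `fs_in` given).
#' @param fs_out Output rate (default 500, matching the neural data).
#' @param fs_in Input rate for matrix input.
#' @return An `ft_envelope`: `samples` (non-negative numeric), `fs_hz`.
#' @export
extract_envelope <- function(bands, fs_out = 500, fs_in = NULL) {
  if (inherits(bands, "ft_bands")) {
    fs_in <- bands$fs_hz
    bands <- bands$bands
  }
  stopifnot(is.matrix(bands), !is.null(fs_in))
  env <- rowMeans(apply(bands, 2, hilbert_envelope))
  env <- resample_to(env, fs_in, fs_out)
  structure(list(samples = pmax(env, 0), fs_hz = fs_out), class = "ft_envelope")
}

#' Modulation spectrum of an envelope
#'
#' Power spectrum of the mean-removed envelope at the tagging resolution
#' (default 1/9 Hz from a 9 s analysis window taken from the end of the
#' signal, so a 9.5 s stimulus discards its onset).
#'
#' @param envelope An `ft_envelope` (or numeric vector with `fs_hz` given).
#' @param fs_hz Sample rate for numeric input.
#' @param window_s Analysis window length in seconds (default 9).
#' @param fmax Highest modulation frequency retained (default 20 Hz).
#' @param taper Taper (default `"hann"`).
#' @return An `ft_spectrum` of kind `"power"` with one channel.
#' @export
modulation_spectrum <- function(envelope, fs_hz = NULL, window_s = 9,
                                fmax = 20, taper = "hann") {
  if (inherits(envelope, "ft_envelope")) {
    fs_hz <- envelope$fs_hz
    envelope <- envelope$samples
  }
  stopifnot(is.numeric(envelope), !is.null(fs_hz))
  n <- round(window_s * fs_hz)
  if (length(envelope) < n) abort("envelope shorter than the analysis window")
  x <- envelope[(length(envelope) - n + 1):length(envelope)]
  x <- x - mean(x)
  w <- taper_window(n, taper)
  freqs <- (seq_len(n) - 1) * fs_hz / n
  sel <- which(freqs <= fmax + 1e-9)
  coef <- taper_fft_bins(matrix(x, ncol = 1), w, sel)
  spectrum_map(t((2 * Mod(coef))^2), freqs[sel], kind = "power")
}

#' Peak modulation frequency
#'
#' @param spec An `ft_spectrum` from [modulation_spectrum()].
#' @return Frequency (Hz) of the largest non-DC bin.
#' @export
peak_modulation_hz <- function(spec) {
  stopifnot(inherits(spec, "ft_spectrum"))
  nz <- spec$freqs_hz > 1e-9
  spec$freqs_hz[nz][which.max(spec$values[1, nz])]
}

#' Cerebro-acoustic coherence in source space
#'
#' Computes, per trial, the tapered Fourier coefficient at `target_hz` of
#' every sensor and of the trial's acoustic envelope; forms the sensor-level
#' auto- and cross-spectra summed over trials; projects them through a
#' common DICS filter (applied to both auto- and cross-terms); and returns
#' the Fisher-z transformed coherence magnitude averaged over each ROI's
#' sources:
#' \deqn{coh_v^2 = |w_v S_{xe}|^2 / ((w_v S_{xx} w_v^H) S_{ee}),\quad
#'       z_v = \mathrm{arctanh}(coh_v).}
#'
#' @param trials An `ft_trials` with per-trial envelopes.
#' @param filter A common DICS `ft_filter`.
#' @param rois Named list of source index sets (default: the filter's
#'   forward-model ROIs).
#' @param target_hz Frequency (default 4, the syllable rate).
#' @param window Analysis window (default `c(0.5, 9.5)`).
#' @param taper Taper (default `"hann"`).
#' @param envelopes Optional trials x samples envelope matrix overriding
#'   `trials$envelope`.
#' @return Tibble: `roi`, `hemisphere` (parsed from a trailing `_left` /
#'   `_right` in the ROI name, else `NA`), `n_trials`, `coherence`
#'   (magnitude), `z` (Fisher z). Per-source values are attached as
#'   attribute `source_z`.
#' @export
cerebroacoustic_coherence <- function(trials, filter, rois = NULL,
                                      target_hz = 4, window = c(0.5, 9.5),
                                      taper = "hann", envelopes = NULL) {
  stopifnot(inherits(trials, "ft_trials"), inherits(filter, "ft_filter"))
  if (is.null(rois)) rois <- filter$forward$rois
  env <- envelopes %||% trials$envelope
  nt <- dim(trials$data)[1]
  if (nrow(env) != nt) abort("envelope trial count does not match the data")

  keep <- .ft_crop_idx(trials$time, window, trials$fs_hz)
  n <- length(keep)
  w <- taper_window(n, taper)
  freqs <- (seq_len(n) - 1) * trials$fs_hz / n
  bin <- which.min(abs(freqs - target_hz))
  if (abs(freqs[bin] - target_hz) > 1e-6) abort("target_hz not on the bin grid")

  ns <- dim(trials$data)[2]
  Sxx <- matrix(0i, ns, ns)
  Sxe <- complex(ns)
  See <- 0
  for (tr in seq_len(nt)) {
    x <- trial_matrix(trials$data, tr, keep)
    X <- as.vector(taper_fft_bins(x, w, bin))
    E <- as.complex(taper_fft_bins(matrix(env[tr, keep], ncol = 1), w, bin))
    Sxx <- Sxx + tcrossprod(X, Conj(X))
    Sxe <- Sxe + X * Conj(E)
    See <- See + Mod(E)^2
  }
  W <- filter$weights
  num <- Mod(W %*% Sxe)^2
  den <- Re(rowSums((W %*% Sxx) * Conj(W))) * See
  coh2 <- pmin(pmax(as.numeric(num / den), 0), 1)
  coh <- sqrt(coh2)
  z <- atanh(pmin(coh, 1 - 1e-12))

  out <- tibble(
    roi = names(rois),
    hemisphere = .ft_roi_hemisphere(names(rois)),
    n_trials = nt,
    coherence = unname(vapply(rois, function(i) mean(coh[i]), numeric(1))),
    z = unname(vapply(rois, function(i) mean(z[i]), numeric(1))))
  attr(out, "source_z") <- z
  attr(out, "source_coherence") <- coh
  out
}

.ft_roi_hemisphere <- function(names) {
  ifelse(grepl("_left$", names), "left",
         ifelse(grepl("_right$", names), "right", NA_character_))
}
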