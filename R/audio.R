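# Audio rendering of stimulus sequences. Syllables are band-limited noise
# bursts: only the amplitude-envelope structure matters for the analyses
# downstream (modulation spectrum, cerebro-acoustic coherence), so no
# articulatory synthesis is attempted.

#' Synthesize a stimulus sequence as a waveform
#'
#' Each syllable token is rendered as band-limited noise with a
#' label-specific spectral centroid under a raised-cosine amplitude window
#' covering the token's content duration, peak-normalized per token.
#' Plosive-onset tokens occupy 230 ms preceded by 20 ms of silence (the oral
#' occlusion); all other tokens occupy the full 250 ms inter-onset interval.
#' Because every token shares the same window shape and peak amplitude, the
#' waveform's modulation spectrum peaks at the syllable rate with no
#' systematic energy at the unit rate.
#'
#' The label `"sil"` renders as silence.
#'
#' @param sequence An `ft_sequence`.
#' @param fs_hz Sample rate, >= 8000 (default 22050).
#' @param seed Integer seed; token spectra are deterministic given the seed
#'   and the label, so repeated labels sound identical within a call.
#' @return Numeric waveform of length `n_syllables * ioi * fs_hz` samples,
#'   with attributes `fs_hz` and `sequence`.
#' @export
synthesize_audio <- function(sequence, fs_hz = 22050, seed = 1) {
  stopifnot(inherits(sequence, "ft_sequence"))
  if (fs_hz < 8000) abort("fs_hz must be >= 8000")
  set.seed(seed)
  pool <- attr(sequence, "syllables_table")
  ioi <- sequence$ioi
  n_tok <- round(ioi * fs_hz)
  wave <- numeric(length(sequence$syllables) * n_tok)

  labels <- unique(sequence$syllables)
  centroids <- stats::setNames(
    exp(stats::runif(length(labels), log(300), log(3000))), labels)

  for (i in seq_along(sequence$syllables)) {
    lab <- sequence$syllables[i]
    if (lab == "sil") next
    plos <- .ft_token_is_plosive(lab, pool)
    sil <- if (plos) round(0.020 * fs_hz) else 0L
    n_content <- n_tok - sil
    f0 <- centroids[[lab]]
    tok <- .ft_noise_burst(n_content, fs_hz, f0)
    w <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n_content)))
    tok <- tok * w
    tok <- tok / max(abs(tok))                 # peak-amplitude normalization
    at <- (i - 1) * n_tok + sil
    wave[(at + 1):(at + n_content)] <- tok
  }
  structure(wave, fs_hz = fs_hz, sequence = sequence)
}

# noise burst band-limited around a centroid frequency (one octave wide)
.ft_noise_burst <- function(n, fs, centroid_hz) {
  lo <- max(80, centroid_hz / sqrt(2))
  hi <- min(fs / 2 * 0.95, centroid_hz * sqrt(2))
  butter_filtfilt(stats::rnorm(n), lo, hi, fs, order = 2)
}

#' Write a waveform as 16-bit PCM mono WAV
#'
#' @param wave Numeric waveform in `[-1, 1]` (clipped otherwise), with an
#'   `fs_hz` attribute or `fs_hz` given explicitly.
#' @param path Output file path.
#' @param fs_hz Sample rate; defaults to `attr(wave, "fs_hz")`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, fs_hz = attr(wave, "fs_hz")) {
  stopifnot(is.numeric(wave), !is.null(fs_hz))
  pcm <- as.integer(pmax(-1, pmin(1, wave)) * 32767)
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
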