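# Shared signal-processing helpers. Filtering goes through the 'signal'
# package (Butterworth design + zero-phase filtfilt); the analytic signal is
# built here via the standard FFT construction.

#' Analytic signal via the FFT method
#'
#' Returns the complex analytic signal of a real vector: positive
#' frequencies doubled, negative frequencies zeroed (DC and Nyquist kept).
#' The magnitude of the result is the instantaneous amplitude (Hilbert
#' envelope) of `x`.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x))
  n <- length(x)
  if (n == 0L) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert amplitude envelope
#'
#' @param x Real numeric vector.
#' @return Non-negative numeric vector `Mod(analytic_signal(x))`.
#' @export
hilbert_envelope <- function(x) Mod(analytic_signal(x))

# Zero-phase Butterworth band-pass applied column-wise.
# x: numeric vector or samples x channels matrix.
butter_filtfilt <- function(x, low_hz, high_hz, fs, order = 4,
                            type = c("pass", "stop")) {
  type <- match.arg(type)
  nyq <- fs / 2
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < nyq)) {
    abort(sprintf("band [%g, %g] Hz invalid for fs = %g Hz", low_hz, high_hz, fs))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = type)
  apply_cols(x, function(v) signal::filtfilt(bf, v))
}

apply_cols <- function(x, f) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- f(x[, j])
    out
  } else {
    f(x)
  }
}

# Fourier-domain resampling: truncating (or zero-padding) the spectrum is an
# ideal anti-aliasing low-pass with exact passband amplitude. Output length
# is round(n * fs_out / fs_in). Matrices are resampled per column.
resample_to <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  f <- function(v) {
    n <- length(v)
    n_out <- round(n * fs_out / fs_in)
    X <- stats::fft(v)
    Y <- complex(n_out)
    half <- min(n, n_out) %/% 2
    Y[1:(half + 1)] <- X[1:(half + 1)]
    if (half > 0) Y[(n_out - half + 1):n_out] <- X[(n - half + 1):n]
    if (n_out %% 2 == 0 && n_out < n) Y[half + 1] <- Re(Y[half + 1])
    Re(stats::fft(Y, inverse = TRUE)) * (n_out / n) / n_out
  }
  if (is.matrix(x)) vapply(seq_len(ncol(x)), function(j) f(x[, j]),
                           numeric(round(nrow(x) * fs_out / fs_in))) else f(x)
}

# Fourier coefficients of tapered columns at selected bin indices.
# x: samples x channels; returns length(bins) x channels complex matrix.
# Coefficients are normalized so a unit-amplitude sinusoid at a bin center
# yields |coef| = 0.5 (standard two-sided convention divided by sum(w)).
taper_fft_bins <- function(x, w, bin_idx) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  xw <- x * w
  basis <- exp(-2i * pi * outer(bin_idx - 1, 0:(n - 1)) / n)
  (basis %*% xw) / sum(w)
}

taper_window <- function(n, taper = c("hann", "dpss", "rect")) {
  taper <- match.arg(taper)
  switch(taper,
    hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
    # single Slepian-like taper: use a Kaiser window (signal pkg) as the
    # standard low-leakage approximation for one-taper dpss use
    dpss = as.numeric(signal::kaiser(n, beta = 6)),
    rect = rep(1, n)
  )
}

# 1/f^alpha noise via spectral shaping, unit standard deviation.
one_over_f_noise <- function(n, alpha = 1, fs = 1) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))            # avoid DC blow-up
  f <- pmin(f, n - f + 1)              # mirror for negative freqs
  shaped <- X / (f^(alpha / 2))
  x <- Re(stats::fft(shaped, inverse = TRUE) / n)
  as.numeric(scale(x))
}

# samples x sensors matrix of one trial, robust to single-sensor data
trial_matrix <- function(data, tr, keep = TRUE) {
  m <- data[tr, , keep, drop = FALSE]          # 1 x sensors x samples
  t(array(m, dim = dim(m)[2:3]))
}
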