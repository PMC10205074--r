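# Evoked tagging spectra at the paradigm's frequency resolution and the
# neighbour-bin contrast used throughout, plus the jackknife trial-wise
# power and polynomial block-trend fits for the learning analysis.

#' Spectrum map container
#'
#' @param values Channels-or-voxels x frequency-bins numeric matrix.
#' @param freqs_hz Strictly increasing, uniformly spaced bin centers.
#' @param kind One of `"power"`, `"contrast"`, `"coherence"`, `"mi"`.
#' @param space `"sensor"` or `"source"`.
#' @return An `ft_spectrum` object.
#' @export
spectrum_map <- function(values, freqs_hz,
                         kind = c("power", "contrast", "coherence", "mi"),
                         space = c("sensor", "source")) {
  kind <- match.arg(kind); space <- match.arg(space)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  stopifnot(ncol(values) == length(freqs_hz), !is.unsorted(freqs_hz, strictly = TRUE))
  if (length(freqs_hz) > 2) {
    stopifnot(diff(range(diff(freqs_hz))) < 1e-9 * max(freqs_hz))
  }
  if (kind == "power") stopifnot(all(values >= -1e-12))
  structure(list(values = values, freqs_hz = freqs_hz, kind = kind,
                 space = space), class = "ft_spectrum")
}

#' @export
print.ft_spectrum <- function(x, ...) {
  cat(sprintf("<ft_spectrum> %s (%s space): %d channels x %d bins, %.4f-%.4f Hz (res %.4f)\n",
              x$kind, x$space, nrow(x$values), ncol(x$values),
              min(x$freqs_hz), max(x$freqs_hz),
              if (length(x$freqs_hz) > 1) diff(x$freqs_hz)[1] else NA_real_))
  invisible(x)
}

#' Evoked power spectrum
#'
#' Averages trials in the time domain (phase-locked activity survives, the
#' induced part cancels), crops to the analysis window, applies a single
#' taper and returns per-channel power. With the default 0.5-9.5 s window
#' the bin spacing is 1/9 s = 0.1111 Hz, placing the 2 Hz and 4 Hz tagging
#' rates exactly on bin centers. Power is scaled as squared sinusoid
#' amplitude: a unit-amplitude phase-locked sinusoid at a bin center yields
#' power 1 at that bin.
#'
#' @param trials An `ft_trials`.
#' @param window Analysis window in seconds (default `c(0.5, 9.5)`,
#'   excluding onset-related activity).
#' @param taper `"hann"` (default), `"dpss"` or `"rect"`.
#' @param fmin,fmax Frequency range retained (defaults 1-7 Hz; use
#'   `fmin = 0, fmax = Inf` for the full spectrum).
#' @return An `ft_spectrum` of kind `"power"`.
#' @export
evoked_spectrum <- function(trials, window = c(0.5, 9.5), taper = "hann",
                            fmin = 1, fmax = 7) {
  stopifnot(inherits(trials, "ft_trials"))
  avg <- apply(trials$data, c(2, 3), mean)     # sensors x samples
  .ft_power_spectrum(avg, trials$time, trials$fs_hz, window, taper, fmin, fmax)
}

.ft_crop_idx <- function(time, window, fs) {
  tol <- 0.5 / fs
  if (window[1] < min(time) - tol || window[2] > max(time) + 1 / fs + tol) {
    abort("analysis window not inside the epoch")
  }
  which(time >= window[1] - tol & time < window[2] - tol)
}

.ft_power_spectrum <- function(chan_by_samp, time, fs, window, taper, fmin, fmax,
                               space = "sensor") {
  keep <- .ft_crop_idx(time, window, fs)
  x <- t(chan_by_samp[, keep, drop = FALSE])   # samples x channels
  n <- nrow(x)
  w <- taper_window(n, taper)
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- which(freqs >= fmin - 1e-9 & freqs <= min(fmax, fs / 2) + 1e-9)
  coef <- taper_fft_bins(x, w, sel)
  power <- t((2 * Mod(coef))^2)                # channels x bins
  spectrum_map(power, freqs[sel], kind = "power", space = space)
}

#' Neighbour-bin contrast at a tagged frequency
#'
#' Contrasts the value at the bin nearest `target_hz` with the mean of the
#' bins at the given offsets (default ±2-3 bins, excluding the immediate
#' neighbours to avoid spectral leakage from the target bin).
#'
#' @param spec An `ft_spectrum`.
#' @param target_hz Target frequency; must sit on the bin grid within
#'   1e-6 Hz.
#' @param offsets Integer bin offsets (default `c(-3, -2, 2, 3)`).
#' @param relative Return `(target - neighbours) / neighbours` instead of
#'   the subtraction (default `FALSE`).
#' @return Numeric contrast per channel/voxel.
#' @export
neighbor_bin_contrast <- function(spec, target_hz, offsets = c(-3, -2, 2, 3),
                                  relative = FALSE) {
  stopifnot(inherits(spec, "ft_spectrum"))
  i <- which.min(abs(spec$freqs_hz - target_hz))
  if (abs(spec$freqs_hz[i] - target_hz) > 1e-6) {
    abort(sprintf("target %.4f Hz is not on the frequency grid", target_hz))
  }
  j <- i + offsets
  if (any(j < 1 | j > length(spec$freqs_hz))) {
    abort("offset bins fall outside the spectrum")
  }
  target <- spec$values[, i]
  neigh <- rowMeans(spec$values[, j, drop = FALSE])
  if (relative) (target - neigh) / neigh else target - neigh
}

#' Jackknife (leave-one-out) trial-wise power contrast
#'
#' For each trial i, the evoked spectrum is computed from all trials except
#' i, the neighbour-bin contrast at `target_hz` is taken, and the result is
#' averaged over `sensors`. Implemented via per-trial Fourier coefficients
#' (the leave-one-out average is linear in them), so the cost is one
#' transform per trial.
#'
#' @inheritParams evoked_spectrum
#' @param target_hz Tagged frequency of interest.
#' @param sensors Integer sensor subset to average (default all).
#' @param offsets Neighbour-bin offsets (default `c(-3, -2, 2, 3)`).
#' @return Tibble with columns `trial`, `block`, `condition`, `jk_power`.
#' @export
jackknife_trial_power <- function(trials, target_hz, sensors = NULL,
                                  window = c(0.5, 9.5), taper = "hann",
                                  offsets = c(-3, -2, 2, 3)) {
  stopifnot(inherits(trials, "ft_trials"))
  nt <- dim(trials$data)[1]
  if (nt < 2) abort("jackknife needs at least 2 trials")
  if (is.null(sensors)) sensors <- seq_len(dim(trials$data)[2])
  keep <- .ft_crop_idx(trials$time, window, trials$fs_hz)
  n <- length(keep)
  w <- taper_window(n, taper)
  freqs <- (seq_len(n) - 1) * trials$fs_hz / n
  ti <- which.min(abs(freqs - target_hz))
  if (abs(freqs[ti] - target_hz) > 1e-6) abort("target_hz not on the bin grid")
  bins <- ti + c(0, offsets)
  stopifnot(all(bins >= 1 & bins <= n))

  coefs <- array(0i, c(nt, length(bins), length(sensors)))
  for (tr in seq_len(nt)) {
    x <- trial_matrix(trials$data[, sensors, , drop = FALSE], tr, keep)
    coefs[tr, , ] <- taper_fft_bins(x, w, bins)
  }
  total <- apply(coefs, c(2, 3), sum)
  jk <- vapply(seq_len(nt), function(tr) {
    loo <- (total - coefs[tr, , ]) / (nt - 1)
    p <- (2 * Mod(loo))^2                      # bins x sensors
    mean(p[1, ] - colMeans(p[-1, , drop = FALSE]))
  }, numeric(1))
  tibble(trial = seq_len(nt), block = trials$block,
         condition = trials$condition, jk_power = jk)
}

#' Polynomial block-order trend with BIC model comparison
#'
#' Fits orthogonal-polynomial least-squares trends of the jackknife power
#' against block order, at orders 1 and 2 (or up to `max_order`), and
#' selects the minimum-BIC model. A positive linear trend indicates
#' statistical learning across blocks; a negative quadratic term indicates a
#' late decrease (e.g. fatigue).
#'
#' @param jk Tibble from [jackknife_trial_power()] (columns `jk_power`,
#'   `block`), or a numeric vector with `block` given.
#' @param block Block index per value (taken from `jk` if absent).
#' @param max_order Highest polynomial order fitted (1 or 2; default 2).
#' @return An `ft_trend` list: `fits` (per-order `lm` objects), `table`
#'   (tibble of order, term, estimate, se, t, p), `bic` (named numeric),
#'   `best_order`.
#' @export
block_trend <- function(jk, block = NULL, max_order = 2) {
  if (is.data.frame(jk)) {
    block <- jk$block
    y <- jk$jk_power
  } else {
    y <- as.numeric(jk)
  }
  stopifnot(length(y) == length(block), max_order %in% 1:2)
  if (length(unique(block)) < max_order + 1) {
    abort("fewer distinct blocks than poly_order + 1")
  }
  fits <- lapply(seq_len(max_order), function(k) {
    stats::lm(y ~ poly(block, k), data = tibble(y = y, block = block))
  })
  bic <- vapply(fits, stats::BIC, numeric(1))
  names(bic) <- paste0("order", seq_len(max_order))
  tab <- dplyr::bind_rows(lapply(seq_len(max_order), function(k) {
    sm <- suppressWarnings(summary(fits[[k]]))$coefficients
    tibble(order = k, term = rownames(sm), estimate = sm[, 1],
           se = sm[, 2], t = sm[, 3], p = sm[, 4])
  }))
  structure(list(fits = fits, table = tab, bic = bic,
                 best_order = unname(which.min(bic))),
            class = "ft_trend")
}

#' @export
print.ft_trend <- function(x, ...) {
  cat(sprintf("<ft_trend> best order %d (BIC: %s)\n", x$best_order,
              paste(sprintf("%s=%.1f", names(x$bic), x$bic), collapse = ", ")))
  invisible(x)
}
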