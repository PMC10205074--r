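# DICS and LCMV beamforming on the toy grid. Filters are "common" filters:
# estimated once from data pooled across conditions and applied identically
# to each condition, so filter estimation cannot bias condition contrasts.

#' Cross-spectral density matrix
#'
#' Averages, over trials and the frequency bins inside `band_hz`, the outer
#' product of tapered sensor Fourier coefficients. Hermitian by
#' construction.
#'
#' @param trials An `ft_trials`.
#' @param band_hz Frequency band (default `c(1.333, 4.666)`, the common
#'   DICS filter band spanning both tagging frequencies).
#' @param window Analysis window in seconds (default `c(0.5, 9.5)`).
#' @param taper Taper name (default `"hann"`).
#' @return An `ft_csd`: `matrix` (sensors x sensors complex Hermitian),
#'   `freq_band_hz`, `freqs_hz` (bins used), `n_trials`.
#' @export
csd_matrix <- function(trials, band_hz = c(1.333, 4.666),
                       window = c(0.5, 9.5), taper = "hann") {
  stopifnot(inherits(trials, "ft_trials"))
  keep <- .ft_crop_idx(trials$time, window, trials$fs_hz)
  n <- length(keep)
  w <- taper_window(n, taper)
  freqs <- (seq_len(n) - 1) * trials$fs_hz / n
  bins <- which(freqs >= band_hz[1] - 1e-9 & freqs <= band_hz[2] + 1e-9)
  if (length(bins) == 0) abort("no frequency bins inside band_hz")
  nt <- dim(trials$data)[1]
  ns <- dim(trials$data)[2]
  C <- matrix(0i, ns, ns)
  for (tr in seq_len(nt)) {
    x <- trial_matrix(trials$data, tr, keep)
    X <- taper_fft_bins(x, w, bins)            # bins x sensors
    for (b in seq_len(nrow(X))) {
      C <- C + tcrossprod(X[b, ], Conj(X[b, ]))
    }
  }
  C <- C / (nt * length(bins))
  C <- (C + Conj(t(C))) / 2                    # enforce exact Hermitian
  structure(list(matrix = C, freq_band_hz = band_hz, freqs_hz = freqs[bins],
                 n_trials = nt), class = "ft_csd")
}

#' Band-limited sensor covariance
#'
#' Real time-domain covariance of band-passed data, averaged over trials;
#' the LCMV analogue of [csd_matrix()].
#'
#' @inheritParams csd_matrix
#' @param band_hz Band (default `c(1.5, 4.5)`, the common LCMV filter band).
#' @param order Butterworth order (default 4).
#' @return An `ft_csd` with a real `matrix`.
#' @export
band_covariance <- function(trials, band_hz = c(1.5, 4.5),
                            window = c(0.5, 9.5), order = 4) {
  stopifnot(inherits(trials, "ft_trials"))
  keep <- .ft_crop_idx(trials$time, window, trials$fs_hz)
  nt <- dim(trials$data)[1]
  ns <- dim(trials$data)[2]
  C <- matrix(0, ns, ns)
  for (tr in seq_len(nt)) {
    x <- trial_matrix(trials$data, tr)
    xf <- butter_filtfilt(x, band_hz[1], band_hz[2], trials$fs_hz, order)[keep, , drop = FALSE]
    xf <- sweep(xf, 2, colMeans(xf))
    C <- C + crossprod(xf) / (nrow(xf) - 1)
  }
  structure(list(matrix = C / nt, freq_band_hz = band_hz, freqs_hz = NULL,
                 n_trials = nt), class = "ft_csd")
}

.ft_beamformer_weights <- function(forward, C, lambda_frac, complex_ok) {
  ns <- nrow(C)
  reg <- lambda_frac * mean(Re(diag(C)))
  Creg <- C + diag(reg, ns)
  sv <- svd(Creg, nu = 0, nv = 0)$d
  kappa <- max(sv) / max(min(sv), .Machine$double.xmin)
  Cinv <- tryCatch(solve(Creg), error = function(e) {
    abort(sprintf("regularized matrix is singular (condition number %.3g)", kappa))
  })
  n_src <- nrow(forward$source_positions)
  W <- matrix(if (complex_ok) 0i else 0, n_src, ns)
  ori <- matrix(0, n_src, 3)
  for (s in seq_len(n_src)) {
    L3 <- .ft_source_leadfield(forward, s)
    # dominant (maximum-power) orientation: leading eigenvector of
    # (L' C^-1 L)^-1, i.e. the direction the beamformer passes most power
    A <- Re(crossprod(Conj(L3), Cinv %*% L3))
    eg <- eigen(A, symmetric = TRUE)
    keep <- eg$values > max(eg$values) * 1e-10  # rank-deficient orientations
    u <- eg$vectors[, max(which(keep))]
    l <- L3 %*% u
    num <- crossprod(Conj(l), Cinv)            # l^H C^-1  (1 x ns)
    denom <- as.complex(num %*% l)
    W[s, ] <- as.vector(num) / denom
    ori[s, ] <- u
  }
  list(W = W, ori = ori, kappa = kappa)
}

#' DICS spatial filter
#'
#' Frequency-domain beamformer: for each source, the leadfield is reduced
#' to its dominant orientation (largest singular value) and the filter is
#' `w = (l' C^-1 l)^-1 l' C^-1` with `C` the cross-spectral density
#' regularized by `lambda_frac` times the mean of its real diagonal. The
#' filter satisfies the unit-gain constraint `w l = 1`.
#'
#' @param forward An `ft_forward`.
#' @param csd An [csd_matrix()] result.
#' @param lambda_frac Regularization fraction (default 0.10, i.e. "lambda =
#'   10%").
#' @return An `ft_filter`: `weights` (sources x sensors, complex),
#'   `orientation` (sources x 3), `lambda`, `kind = "dics"`.
#' @export
dics_filter <- function(forward, csd, lambda_frac = 0.10) {
  stopifnot(inherits(forward, "ft_forward"), inherits(csd, "ft_csd"))
  bw <- .ft_beamformer_weights(forward, csd$matrix, lambda_frac, complex_ok = TRUE)
  structure(list(weights = bw$W, orientation = bw$ori, lambda = lambda_frac,
                 kind = "dics", forward = forward),
            class = "ft_filter")
}

#' LCMV spatial filter
#'
#' Time-domain analogue of [dics_filter()] built from a band-limited real
#' covariance; yields real weights usable for virtual-channel projection.
#'
#' @inheritParams dics_filter
#' @param covariance An [band_covariance()] result.
#' @return An `ft_filter` with `kind = "lcmv"` and real weights.
#' @export
lcmv_filter <- function(forward, covariance, lambda_frac = 0.10) {
  stopifnot(inherits(forward, "ft_forward"), inherits(covariance, "ft_csd"))
  bw <- .ft_beamformer_weights(forward, covariance$matrix, lambda_frac,
                               complex_ok = FALSE)
  structure(list(weights = Re(bw$W), orientation = bw$ori, lambda = lambda_frac,
                 kind = "lcmv", forward = forward),
            class = "ft_filter")
}

#' @export
print.ft_filter <- function(x, ...) {
  cat(sprintf("<ft_filter> %s, %d sources x %d sensors, lambda %.0f%%\n",
              toupper(x$kind), nrow(x$weights), ncol(x$weights), 100 * x$lambda))
  invisible(x)
}

#' Project trials to source space (virtual channels)
#'
#' Applies an LCMV filter to every trial, producing one time series per
#' source.
#'
#' @param filter An `ft_filter` of kind `"lcmv"`.
#' @param trials An `ft_trials`.
#' @return An `ft_trials` whose `data` is trials x sources x samples and
#'   whose `space` field is `"source"`.
#' @export
project_trials <- function(filter, trials) {
  stopifnot(inherits(filter, "ft_filter"), inherits(trials, "ft_trials"))
  if (filter$kind != "lcmv") abort("virtual-channel projection needs an LCMV filter")
  nt <- dim(trials$data)[1]
  n_src <- nrow(filter$weights)
  n_samp <- dim(trials$data)[3]
  out <- trials
  out$data <- array(0, c(nt, n_src, n_samp))
  for (tr in seq_len(nt)) {
    out$data[tr, , ] <- filter$weights %*% t(trial_matrix(trials$data, tr))
  }
  out$space <- "source"
  out
}

#' Source-space power spectrum and neighbour-bin contrast
#'
#' Computes per-source power `Re(w S(f) w^H)` at each frequency bin from
#' per-bin cross-spectral densities through a common DICS filter, and the
#' neighbour-bin contrast at `target_hz`.
#'
#' @param filter An `ft_filter` (DICS).
#' @param trials An `ft_trials` (sensor space).
#' @param target_hz Tagged frequency.
#' @param offsets Neighbour-bin offsets (default `c(-3, -2, 2, 3)`).
#' @param window Analysis window (default `c(0.5, 9.5)`).
#' @param taper Taper (default `"hann"`).
#' @param fmin,fmax Bin range computed (default 1-7 Hz).
#' @return List: `spectrum` (`ft_spectrum`, source space), `contrast`
#'   (numeric per source).
#' @export
source_power_contrast <- function(filter, trials, target_hz,
                                  offsets = c(-3, -2, 2, 3),
                                  window = c(0.5, 9.5), taper = "hann",
                                  fmin = 1, fmax = 7) {
  stopifnot(inherits(filter, "ft_filter"), inherits(trials, "ft_trials"))
  keep <- .ft_crop_idx(trials$time, window, trials$fs_hz)
  n <- length(keep)
  w <- taper_window(n, taper)
  freqs <- (seq_len(n) - 1) * trials$fs_hz / n
  bins <- which(freqs >= fmin - 1e-9 & freqs <= fmax + 1e-9)
  nt <- dim(trials$data)[1]
  W <- filter$weights
  power <- matrix(0, nrow(W), length(bins))
  for (tr in seq_len(nt)) {
    x <- trial_matrix(trials$data, tr, keep)
    X <- taper_fft_bins(x, w, bins)            # bins x sensors
    P <- Mod(X %*% t(Conj(W)))^2               # bins x sources: |w^H X|^2
    power <- power + t(P)
  }
  spec <- spectrum_map((2^2) * power / nt, freqs[bins], kind = "power",
                       space = "source")
  list(spectrum = spec,
       contrast = neighbor_bin_contrast(spec, target_hz, offsets))
}

#' Average a map or source trials over ROI source sets
#'
#' @param x Numeric vector (per-source values), matrix (sources x anything),
#'   `ft_spectrum` in source space, or source-space `ft_trials`.
#' @param rois Named list of source index vectors.
#' @return Named vector, matrix with one row per ROI, `ft_spectrum` with one
#'   row per ROI, or array trials x ROIs x samples, matching the input.
#' @export
roi_average <- function(x, rois) {
  stopifnot(is.list(rois), !is.null(names(rois)))
  if (inherits(x, "ft_spectrum")) {
    vals <- t(vapply(rois, function(i) colMeans(x$values[i, , drop = FALSE]),
                     numeric(ncol(x$values))))
    out <- x
    out$values <- vals
    rownames(out$values) <- names(rois)
    return(out)
  }
  if (inherits(x, "ft_trials")) {
    nt <- dim(x$data)[1]
    out <- x
    out$data <- array(0, c(nt, length(rois), dim(x$data)[3]))
    for (tr in seq_len(nt)) {
      m <- t(trial_matrix(x$data, tr))         # sources x samples
      out$data[tr, , ] <- t(vapply(rois, function(i)
        colMeans(m[i, , drop = FALSE]), numeric(ncol(m))))
    }
    return(out)
  }
  if (is.matrix(x)) {
    out <- t(vapply(rois, function(i) colMeans(x[i, , drop = FALSE]),
                    numeric(ncol(x))))
    rownames(out) <- names(rois)
    return(out)
  }
  vapply(rois, function(i) mean(x[i]), numeric(1))
}
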