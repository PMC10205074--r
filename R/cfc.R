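# Cross-frequency coupling as Gaussian-copula mutual information between
# the 4 Hz power envelope of a seed ROI and 2 Hz power envelopes across all
# sources.

#' Band-limited power envelopes of source trials
#'
#' Per trial and source: downsample to `fs_out`, zero-phase Butterworth
#' band-pass, Hilbert magnitude; trials are then concatenated per source in
#' trial order.
#'
#' @param source_trials A source-space `ft_trials` (see [project_trials()]);
#'   sensor-space input works identically per channel.
#' @param band_hz Band, e.g. `c(1.5, 2.5)` or `c(3.5, 4.5)`.
#' @param fs_out Downsampled rate (default 100).
#' @param order Butterworth order (default 4).
#' @param window Portion of the epoch used, in seconds (default
#'   `c(0.5, 9.5)`; applied after downsampling).
#' @return An `ft_band_env`: `values` (channels x concatenated samples),
#'   `band_hz`, `fs_hz`, `n_trials`, `samples_per_trial`.
#' @export
band_envelope <- function(source_trials, band_hz, fs_out = 100, order = 4,
                          window = c(0.5, 9.5)) {
  stopifnot(inherits(source_trials, "ft_trials"))
  if (band_hz[2] >= fs_out / 2) abort("band above the Nyquist of fs_out")
  nt <- dim(source_trials$data)[1]
  nc <- dim(source_trials$data)[2]
  fs <- source_trials$fs_hz
  per_trial <- vector("list", nt)
  for (tr in seq_len(nt)) {
    m <- trial_matrix(source_trials$data, tr)
    md <- resample_to(m, fs, fs_out)
    t_ds <- source_trials$time[1] + (seq_len(nrow(md)) - 1) / fs_out
    keep <- t_ds >= window[1] & t_ds < window[2]
    mf <- butter_filtfilt(md, band_hz[1], band_hz[2], fs_out, order)
    per_trial[[tr]] <- apply(mf[keep, , drop = FALSE], 2, hilbert_envelope)
  }
  values <- t(do.call(rbind, per_trial))       # channels x concatenated
  structure(list(values = values, band_hz = band_hz, fs_hz = fs_out,
                 n_trials = nt, samples_per_trial = nrow(per_trial[[1]])),
            class = "ft_band_env")
}

#' Copula normalization
#'
#' Maps each sample to its rank quantile `r / (n + 1)` (average ranks for
#' ties) and through the inverse standard normal CDF, enforcing a Gaussian
#' marginal while preserving rank order.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Numeric vector of normal scores.
#' @export
copula_normalize <- function(x) {
  stopifnot(is.numeric(x))
  if (length(unique(x)) < 2) abort("copula normalization undefined for constant input")
  stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

#' Gaussian-copula mutual information (bits)
#'
#' Copula-normalizes both inputs (rank -> normal scores) and applies the
#' parametric Gaussian MI `-0.5 log2(1 - r^2)`, with the analytic
#' psi-function bias correction for Gaussian entropy estimates subtracted by
#' default. By construction the estimate is invariant to strictly monotone
#' transformations of either input; small negative values can occur after
#' bias correction under independence.
#'
#' @param x,y Numeric vectors of equal length `n >= 10`.
#' @param bias_correct Subtract the analytic small-sample bias (default
#'   `TRUE`).
#' @param normalize Copula-normalize the inputs first (default `TRUE`; set
#'   to `FALSE` if they already are).
#' @return MI in bits. Perfectly dependent inputs (|r| -> 1) are capped at
#'   the value for `r^2 = 1 - 1e-12` with a warning.
#' @export
gcmi <- function(x, y, bias_correct = TRUE, normalize = TRUE) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 10) abort("gcmi needs n >= 10")
  if (normalize) {
    x <- copula_normalize(x)
    y <- copula_normalize(y)
  }
  r <- stats::cor(x, y)
  r2 <- r^2
  if (r2 >= 1 - 1e-12) {
    warn("near-perfectly dependent inputs; MI capped")
    r2 <- 1 - 1e-12
  }
  mi <- -0.5 * log2(1 - r2)
  if (bias_correct) {
    # analytic psi-function bias of Gaussian entropy estimates:
    # MI bias (nats) = psi((n-1)/2)/2 - psi((n-2)/2)/2
    bias_nats <- digamma((n - 1) / 2) / 2 - digamma((n - 2) / 2) / 2
    mi <- mi - bias_nats / log(2)
  }
  mi
}

#' Seed-ROI to whole-cortex cross-frequency coupling map
#'
#' MI between the 4 Hz power envelope at each voxel of the seed ROI and the
#' 2 Hz power envelope at every source, averaged over seed voxels (MI
#' computed per seed-voxel/target pair, then ROI-averaged). Envelopes are
#' computed on concatenated trials per condition.
#'
#' @param source_trials Source-space `ft_trials`.
#' @param seed_roi Name of the seed ROI in `rois`.
#' @param rois Named list of source index sets.
#' @param band_low,band_high 2 Hz and 4 Hz band definitions (defaults
#'   `c(1.5, 2.5)` and `c(3.5, 4.5)`).
#' @param fs_out Envelope sample rate (default 100).
#' @param condition Optional condition label to subset trials first.
#' @param roi_mean_seed Average the seed envelope before MI instead of
#'   averaging MI over seed voxels (default `FALSE`).
#' @return An `ft_mimap` tibble: `source`, `mi_bits`, with attributes
#'   `seed_roi` and `condition`.
#' @export
cfc_map <- function(source_trials, seed_roi, rois,
                    band_low = c(1.5, 2.5), band_high = c(3.5, 4.5),
                    fs_out = 100, condition = NULL, roi_mean_seed = FALSE) {
  stopifnot(inherits(source_trials, "ft_trials"), seed_roi %in% names(rois))
  if (!is.null(condition)) {
    source_trials <- subset_trials(source_trials,
                                   source_trials$condition == condition)
  }
  env4 <- band_envelope(source_trials, band_high, fs_out)
  env2 <- band_envelope(source_trials, band_low, fs_out)
  seed_idx <- rois[[seed_roi]]

  seed_env <- env4$values[seed_idx, , drop = FALSE]
  if (roi_mean_seed) seed_env <- matrix(colMeans(seed_env), nrow = 1)
  seed_norm <- t(apply(seed_env, 1, copula_normalize))
  targ_norm <- t(apply(env2$values, 1, copula_normalize))

  mi <- vapply(seq_len(nrow(targ_norm)), function(s) {
    mean(vapply(seq_len(nrow(seed_norm)), function(k) {
      gcmi(seed_norm[k, ], targ_norm[s, ], normalize = FALSE)
    }, numeric(1)))
  }, numeric(1))

  structure(tibble(source = seq_along(mi), mi_bits = mi),
            seed_roi = seed_roi, condition = condition,
            class = c("ft_mimap", class(tibble())))
}

#' Surrogate null band for a CFC map
#'
#' Recomputes the maximum MI over sources after randomly permuting trial
#' blocks of the seed envelope relative to the target envelopes, giving a
#' null distribution for "any source coupled".
#'
#' @inheritParams cfc_map
#' @param n_surrogates Number of surrogates (default 100).
#' @param seed RNG seed.
#' @return Numeric vector of surrogate maximum MI values.
#' @export
cfc_surrogate_max <- function(source_trials, seed_roi, rois,
                              band_low = c(1.5, 2.5), band_high = c(3.5, 4.5),
                              fs_out = 100, n_surrogates = 100, seed = 1,
                              condition = NULL) {
  stopifnot(inherits(source_trials, "ft_trials"))
  if (!is.null(condition)) {
    source_trials <- subset_trials(source_trials,
                                   source_trials$condition == condition)
  }
  env4 <- band_envelope(source_trials, band_high, fs_out)
  env2 <- band_envelope(source_trials, band_low, fs_out)
  seed_idx <- rois[[seed_roi]]
  spt <- env4$samples_per_trial
  nt <- env4$n_trials
  seed_norm <- t(apply(env4$values[seed_idx, , drop = FALSE], 1, copula_normalize))
  targ_norm <- t(apply(env2$values, 1, copula_normalize))

  set.seed(seed)
  vapply(seq_len(n_surrogates), function(b) {
    perm <- sample(nt)
    idx <- as.vector(vapply(perm, function(p) (p - 1) * spt + seq_len(spt),
                            numeric(spt)))
    sp <- seed_norm[, idx, drop = FALSE]
    max(vapply(seq_len(nrow(targ_norm)), function(s) {
      mean(vapply(seq_len(nrow(sp)), function(k) {
        gcmi(sp[k, ], targ_norm[s, ], normalize = FALSE)
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
}
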