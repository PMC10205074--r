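# Stimulus sequences: isochronous syllables at the syllable rate forming
# disyllabic units at half that rate.

#' Generate one stimulus sequence
#'
#' Concatenates randomly selected disyllabic units (sampled with probability
#' proportional to wordform frequency) into an isochronous syllable sequence.
#' No unit is immediately repeated (unless the lexicon has a single word).
#' When `target` is set, one unit is replaced by a repetition of the same
#' syllable, the target listeners must detect.
#'
#' @param lexicon An [build_lexicon()] lexicon.
#' @param n_units Number of disyllabic units (default 19, i.e. 38 syllables).
#' @param target Insert a same-syllable repetition target unit?
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param ioi Syllable inter-onset interval in seconds (default 0.250, i.e.
#'   4 syllables/s and 2 units/s).
#' @return An `ft_sequence`: list with `syllables` (labels), `onsets_s`,
#'   `unit_boundaries` (indices of unit-initial syllables), `target_index`
#'   (unit index or `NA`), `condition`, `ioi`.
#' @export
generate_sequence <- function(lexicon, n_units = 19, target = FALSE,
                              seed = NULL, ioi = 0.25) {
  stopifnot(inherits(lexicon, "ft_lexicon"), nrow(lexicon) >= 1, n_units >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (identical(attr(lexicon, "profile"), "random")) {
    # no word-grouping cues: each unit is a fresh quasi-random pairing with
    # an equal probability of each syllable at first and second position
    pool <- unique(c(lexicon$syllable1, lexicon$syllable2))
    s1 <- sample(pool, n_units, replace = TRUE)
    s2 <- sample(pool, n_units, replace = TRUE)
    syl <- as.vector(rbind(s1, s2))
  } else {
    idx <- integer(n_units)
    prob <- lexicon$frequency / sum(lexicon$frequency)
    for (u in seq_len(n_units)) {
      repeat {
        idx[u] <- sample.int(nrow(lexicon), 1, prob = prob)
        if (u == 1 || nrow(lexicon) == 1 || idx[u] != idx[u - 1]) break
      }
    }
    syl <- as.vector(rbind(lexicon$syllable1[idx], lexicon$syllable2[idx]))
  }
  target_index <- NA_integer_
  if (isTRUE(target)) {
    target_index <- sample.int(n_units, 1)
    rep_syl <- sample(attr(lexicon, "syllables")$label, 1)
    syl[2 * target_index - 1] <- rep_syl
    syl[2 * target_index] <- rep_syl
  }
  structure(
    list(
      syllables = syl,
      onsets_s = ioi * (seq_along(syl) - 1),
      unit_boundaries = seq(1, 2 * n_units, by = 2),
      target_index = target_index,
      condition = attr(lexicon, "profile"),
      ioi = ioi
    ),
    class = "ft_sequence", syllables_table = attr(lexicon, "syllables")
  )
}

#' @export
print.ft_sequence <- function(x, ...) {
  cat(sprintf("<ft_sequence> %d syllables / %d units, ioi %.3f s%s\n",
              length(x$syllables), length(x$unit_boundaries), x$ioi,
              if (!is.na(x$target_index)) sprintf(", target at unit %d", x$target_index) else ""))
  invisible(x)
}

#' Generate a full experiment's worth of stimulus sequences
#'
#' Builds the trial list of a frequency-tagging session: `n_trials` trials
#' split equally across the conditions named in `lexicon_by_condition`,
#' grouped into `n_blocks` blocks in presentation order, with exactly
#' `round(target_fraction * n_trials)` target trials allocated as evenly as
#' possible across conditions (remainder assigned in condition-name order).
#'
#' @param lexicon_by_condition Named list of lexicons, one per condition.
#' @param n_trials Total trial count (divisible by the number of conditions;
#'   default 210).
#' @param target_fraction Fraction of target trials in `[0, 1]` (default 0.29).
#' @param n_blocks Number of blocks (default 15).
#' @param n_units Units per sequence (default 19).
#' @param seed Integer seed.
#' @return Tibble with columns `trial`, `block`, `condition`, `is_target`,
#'   `sequence` (list column of `ft_sequence`).
#' @export
generate_experiment <- function(lexicon_by_condition, n_trials = 210,
                                target_fraction = 0.29, n_blocks = 15,
                                n_units = 19, seed = 1) {
  stopifnot(is.list(lexicon_by_condition), length(names(lexicon_by_condition)) > 0)
  conds <- names(lexicon_by_condition)
  n_cond <- length(conds)
  if (n_trials %% n_cond != 0) abort("n_trials must be divisible by the number of conditions")
  if (target_fraction < 0 || target_fraction > 1) abort("target_fraction must be in [0, 1]")
  set.seed(seed)

  per_cond <- n_trials / n_cond
  n_targets <- round(target_fraction * n_trials)
  base <- n_targets %/% n_cond
  extra <- n_targets %% n_cond
  targets_per_cond <- stats::setNames(base + (seq_len(n_cond) <= extra), conds)

  # presentation order: blocks of balanced, shuffled condition labels
  per_block <- n_trials / n_blocks
  cond_seq <- unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(conds, length.out = per_block))
  }))
  trials <- tibble(
    trial = seq_len(n_trials),
    block = rep(seq_len(n_blocks), each = per_block),
    condition = cond_seq,
    is_target = FALSE
  )
  for (cc in conds) {
    rows <- which(trials$condition == cc)
    trials$is_target[sample(rows, targets_per_cond[[cc]])] <- TRUE
  }
  trials$sequence <- purrr::map2(trials$condition, trials$is_target, function(cc, tg) {
    generate_sequence(lexicon_by_condition[[cc]], n_units = n_units, target = tg)
  })
  trials
}

#' Idealized acoustic envelope of a sequence
#'
#' Renders the amplitude envelope implied by a sequence: one smooth
#' raised-cosine bump per syllable token (230 ms content preceded by 20 ms
#' silence for plosive-onset tokens, 250 ms otherwise), sampled on an
#' arbitrary time axis. Token peak amplitudes are 1 up to an optional
#' multiplicative jitter that drifts slowly across tokens (AR(1) in token
#' order, emulating natural loudness drift) and is independent of syllable
#' position, so the envelope has no systematic energy at the unit rate.
#'
#' @param sequence An `ft_sequence`.
#' @param time Numeric vector of sample times in seconds (0 = first onset).
#' @param token_jitter_sd Standard deviation of per-token log-amplitude
#'   jitter (default 0, i.e. identical peaks).
#' @param token_jitter_rho AR(1) coefficient of the jitter across tokens
#'   (default 0.9; 0 gives independent tokens).
#' @return Non-negative numeric envelope, same length as `time`.
#' @export
sequence_envelope <- function(sequence, time, token_jitter_sd = 0,
                              token_jitter_rho = 0.9) {
  stopifnot(inherits(sequence, "ft_sequence"))
  pool <- attr(sequence, "syllables_table")
  n_tok <- length(sequence$syllables)
  amps <- rep(1, n_tok)
  if (token_jitter_sd > 0) {
    a <- numeric(n_tok)
    a[1] <- stats::rnorm(1)
    for (i in seq_len(n_tok - 1)) {
      a[i + 1] <- token_jitter_rho * a[i] +
        sqrt(1 - token_jitter_rho^2) * stats::rnorm(1)
    }
    amps <- exp(token_jitter_sd * a)
  }
  env <- numeric(length(time))
  for (i in seq_len(n_tok)) {
    lab <- sequence$syllables[i]
    if (lab == "sil") next
    plos <- .ft_token_is_plosive(lab, pool)
    t0 <- sequence$onsets_s[i] + if (plos) 0.020 else 0
    dur <- if (plos) sequence$ioi - 0.020 else sequence$ioi
    rel <- (time - t0) / dur
    inside <- rel >= 0 & rel < 1
    env[inside] <- env[inside] + amps[i] * 0.5 * (1 - cos(2 * pi * rel[inside]))
  }
  env
}

.ft_token_is_plosive <- function(label, pool) {
  if (is.null(pool)) return(FALSE)
  i <- match(label, pool$label)
  !is.na(i) && identical(pool$manner[i], "plosive")
}
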