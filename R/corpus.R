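# Syllable-to-syllable transitional probability analysis.
#
# A transition is the pair of consecutive syllables (i, i+1); transitions
# starting at a unit-initial syllable are "within word", those crossing a
# unit boundary are "between word". Each syllable is projected onto one of
# six phonological measurements before counting; transitional probabilities
# follow the classical conditional-probability definition
# TP(e2 | e1) = freq(pair e1-e2) / freq(e1).

.ft_measurements <- c("identity", "cv_pattern", "onset", "manner", "rime",
                      "cross_boundary_phoneme")

#' Bigram frequency table
#'
#' Counts first-element and pair frequencies from paired element vectors.
#'
#' @param e1,e2 Character vectors of equal length: the first and second
#'   element of each observed transition.
#' @param measurement Label recording which projection produced the elements.
#' @return An `ft_bigram` list: `unit_freq` (named counts of first
#'   elements), `pair_freq` (named counts with keys `"e1 e2"`), `vocab2`
#'   (observed continuation vocabulary), `alpha` (smoothing pseudo-count,
#'   0 = unsmoothed), `measurement`.
#' @export
bigram_table <- function(e1, e2, measurement = "identity") {
  stopifnot(length(e1) == length(e2), length(e1) > 0)
  key <- paste(e1, e2)
  structure(
    list(unit_freq = c(table(e1)), pair_freq = c(table(key)),
         vocab2 = sort(unique(e2)), alpha = 0, measurement = measurement),
    class = "ft_bigram")
}

#' Laplace-smooth a bigram table
#'
#' Adds the pseudo-count `alpha` to every (observed first element, observed
#' continuation) pair and adds `alpha * |continuation vocabulary|` to each
#' first-element frequency, so that smoothed transitional probabilities
#' remain in `[0, 1]` and sum to 1 over the continuation vocabulary.
#'
#' @param table An `ft_bigram`.
#' @param alpha Pseudo-count > 0 (default 1).
#' @return The smoothed `ft_bigram`.
#' @export
laplace_smooth <- function(table, alpha = 1) {
  stopifnot(inherits(table, "ft_bigram"), alpha > 0)
  table$alpha <- table$alpha + alpha
  table$unit_freq <- table$unit_freq + alpha * length(table$vocab2)
  table
}

#' Transitional probability of e2 given e1
#'
#' @param table An `ft_bigram`.
#' @param e1,e2 Elements.
#' @return `freq(pair) / freq(e1)` including any smoothing pseudo-counts;
#'   in `[0, 1]`.
#' @export
transitional_probability <- function(table, e1, e2) {
  stopifnot(inherits(table, "ft_bigram"))
  denom <- table$unit_freq[e1]
  if (is.na(denom) || denom <= 0) {
    abort(paste0("element '", e1, "' has zero (smoothed) frequency"))
  }
  pair <- table$pair_freq[paste(e1, e2)]
  if (is.na(pair)) pair <- 0
  extra <- if (table$alpha > 0 && e2 %in% table$vocab2) table$alpha else 0
  unname((pair + extra) / denom)
}

# measurement projections; for cross_boundary_phoneme the first element of a
# transition is the final phoneme of the leading syllable and the second is
# the initial phoneme of the trailing syllable
.ft_project <- function(labels, pool, measurement, side = c("first", "second")) {
  side <- match.arg(side)
  i <- match(labels, pool$label)
  if (anyNA(i)) {
    abort(paste0("syllable without phoneme annotation: ",
                 paste(unique(labels[is.na(i)]), collapse = ", ")))
  }
  switch(measurement,
    identity = labels,
    cv_pattern = pool$cv_pattern[i],
    onset = pool$onset[i],
    manner = pool$manner[i],
    rime = paste0(pool$nucleus[i], pool$coda[i]),
    cross_boundary_phoneme =
      if (side == "first") {
        ifelse(pool$coda[i] != "", pool$coda[i], pool$nucleus[i])
      } else {
        pool$onset[i]
      },
    abort(paste0("unknown measurement: ", measurement))
  )
}

.ft_sequence_transitions <- function(sequences, measurement) {
  rows <- lapply(sequences, function(sq) {
    stopifnot(inherits(sq, "ft_sequence"))
    pool <- attr(sq, "syllables_table")
    syl <- sq$syllables
    k <- length(syl) - 1
    e1 <- .ft_project(syl[seq_len(k)], pool, measurement, "first")
    e2 <- .ft_project(syl[seq_len(k) + 1], pool, measurement, "second")
    within <- seq_len(k) %in% sq$unit_boundaries
    tibble(e1 = e1, e2 = e2, within = within)
  })
  dplyr::bind_rows(rows)
}

#' Within- vs between-word transitional probability contrast
#'
#' Projects every syllable of the sequences onto `measurement`, pools all
#' transitions into one bigram table, evaluates the transitional probability
#' of each transition, and contrasts within-word against between-word
#' transitions with a two-sided Mann-Whitney-Wilcoxon test (exact for small
#' tie-free samples, normal approximation with tie correction otherwise).
#'
#' @param sequences List of `ft_sequence` objects sharing one condition.
#' @param measurement One of `"identity"`, `"cv_pattern"`, `"onset"`,
#'   `"manner"`, `"rime"`, `"cross_boundary_phoneme"`.
#' @param alpha Laplace pseudo-count applied to the pooled table (default 0,
#'   i.e. unsmoothed; transitions observed in the sequences always have
#'   positive counts).
#' @param n_family Bonferroni family size used to correct the p value
#'   (default 1; [tp_analysis()] sets it to the full measurement x condition
#'   family).
#' @param drop_outliers Remove transition probabilities further than 2.5 SD
#'   from their group mean before testing (default `FALSE`).
#' @return An `ft_tp_contrast` list: `within`, `between` (TP vectors),
#'   `diff` (mean within - mean between), `p_value`, `p_corrected`,
#'   `measurement`, `condition`.
#' @export
within_between_contrast <- function(sequences, measurement = "identity",
                                    alpha = 0, n_family = 1,
                                    drop_outliers = FALSE) {
  measurement <- match.arg(measurement, .ft_measurements)
  trans <- .ft_sequence_transitions(sequences, measurement)
  tab <- bigram_table(trans$e1, trans$e2, measurement)
  if (alpha > 0) tab <- laplace_smooth(tab, alpha)
  tp <- vapply(seq_len(nrow(trans)),
               function(i) transitional_probability(tab, trans$e1[i], trans$e2[i]),
               numeric(1))
  within <- tp[trans$within]
  between <- tp[!trans$within]
  if (drop_outliers) {
    within <- .ft_drop_outliers(within)
    between <- .ft_drop_outliers(between)
  }
  p <- suppressWarnings(
    stats::wilcox.test(within, between, alternative = "two.sided")$p.value)
  structure(
    list(within = within, between = between,
         diff = mean(within) - mean(between),
         p_value = p, p_corrected = min(1, p * n_family),
         measurement = measurement,
         condition = sequences[[1]]$condition),
    class = "ft_tp_contrast")
}

.ft_drop_outliers <- function(x, k = 2.5) x[abs(x - mean(x)) <= k * stats::sd(x)]

#' @export
print.ft_tp_contrast <- function(x, ...) {
  cat(sprintf("<ft_tp_contrast> %s (%s): within %.3f, between %.3f, diff %.3f, p_corr %.3g\n",
              x$measurement, x$condition, mean(x$within), mean(x$between),
              x$diff, x$p_corrected))
  invisible(x)
}

#' Full transition-probability table across measurements and conditions
#'
#' Runs [within_between_contrast()] for every measurement and every
#' condition group, Bonferroni-correcting over the whole family of tests.
#'
#' @param sequences_by_condition Named list: condition -> list of
#'   `ft_sequence`.
#' @param measurements Measurements to analyse (default all six).
#' @param ... Passed to [within_between_contrast()].
#' @return Tibble with columns `condition`, `measurement`, `within`,
#'   `between`, `diff`, `p_value`, `p_corrected`.
#' @export
tp_analysis <- function(sequences_by_condition,
                        measurements = .ft_measurements, ...) {
  stopifnot(is.list(sequences_by_condition), !is.null(names(sequences_by_condition)))
  n_family <- length(sequences_by_condition) * length(measurements)
  rows <- list()
  for (cond in names(sequences_by_condition)) {
    for (m in measurements) {
      ct <- within_between_contrast(sequences_by_condition[[cond]], m,
                                    n_family = n_family, ...)
      rows[[length(rows) + 1]] <- tibble(
        condition = cond, measurement = m,
        within = mean(ct$within), between = mean(ct$between),
        diff = ct$diff, p_value = ct$p_value, p_corrected = ct$p_corrected)
    }
  }
  dplyr::bind_rows(rows)
}
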