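# Synthetic disyllabic lexicons with explicit phoneme annotation.
#
# Words are pairs of CV(C) syllables. Every syllable carries an (onset,
# nucleus, coda) annotation from which the six phonological projections used
# in the transition-probability analysis are derived: syllable identity, CV
# pattern, onset phoneme, onset manner class, rime (nucleus + coda), and the
# phoneme pair across the syllable boundary.

.ft_onsets <- list(
  plosive   = c("p", "t", "k", "b", "d", "g"),
  fricative = c("f", "v", "s", "z", "x", "h", "sh", "ch"),
  nasal     = c("m", "n"),
  liquid    = c("l", "r")
)
.ft_first_nuclei  <- c("a", "i", "u")
.ft_second_nuclei <- c("e", "o", "y")

# cyclic shift within each manner class; manner is preserved so that the
# distribution of onset manners (and hence of plosive silences in the audio)
# is identical at first and second syllable positions
.ft_map_onset <- function(onset) {
  for (cls in .ft_onsets) {
    i <- match(onset, cls)
    if (!is.na(i)) return(cls[(i %% length(cls)) + 1])
  }
  abort(paste0("unknown onset phoneme: ", onset))
}

.ft_map_nucleus <- function(nucleus) {
  i <- match(nucleus, .ft_first_nuclei)
  if (is.na(i)) abort(paste0("unknown first-syllable nucleus: ", nucleus))
  .ft_second_nuclei[i]
}

# coda is a deterministic function of the onset's manner class, which makes
# the phoneme pair across the within-word syllable boundary predictive
.ft_coda_for_manner <- c(plosive = "", fricative = "n", nasal = "s", liquid = "l")

.ft_manner_of <- function(onset) {
  for (m in names(.ft_onsets)) if (onset %in% .ft_onsets[[m]]) return(m)
  abort(paste0("unknown onset phoneme: ", onset))
}

.ft_make_syllable <- function(onset, nucleus) {
  coda <- unname(.ft_coda_for_manner[.ft_manner_of(onset)])
  tibble(
    label = paste0(onset, nucleus, coda),
    onset = onset, nucleus = nucleus, coda = coda,
    cv_pattern = if (coda == "") "CV" else "CVC",
    manner = .ft_manner_of(onset)
  )
}

.ft_syllable_pool <- function(nuclei) {
  onsets <- unlist(.ft_onsets, use.names = FALSE)
  dplyr::bind_rows(lapply(nuclei, function(v) {
    dplyr::bind_rows(lapply(onsets, .ft_make_syllable, nucleus = v))
  }))
}

#' Build a synthetic disyllabic lexicon
#'
#' Generates a lexicon of disyllabic words whose syllable-to-syllable
#' transition statistics emulate one of three stimulus conditions:
#'
#' * `"native_like"` — strongly structured: each first syllable has a
#'   dominant second syllable (via manner-preserving phoneme mappings), so
#'   within-word transitional probability greatly exceeds the between-word
#'   probability on every phonological measurement.
#' * `"foreign_like"` — the same structure with a fraction of irregular
#'   words, giving a positive but smaller within-vs-between margin.
#' * `"random"` — pseudo-words formed by quasi-random pairing with an equal
#'   probability of each syllable appearing at first or second position;
#'   within- and between-word statistics are then indistinguishable.
#'
#' @param n_words Number of words (>= 4).
#' @param profile One of `"native_like"`, `"foreign_like"`, `"random"`.
#' @param seed Integer seed; the lexicon is deterministic given the seed.
#' @param irregular_fraction For `"foreign_like"`, fraction of words whose
#'   second syllable breaks the phoneme mapping (default 0.3).
#' @param margin Required minimum within-minus-between identity-TP margin for
#'   structured profiles (default 0.6 native, 0.3 foreign). Construction
#'   fails if `n_words` cannot satisfy it.
#' @return A tibble of class `ft_lexicon` with columns `word`, `syllable1`,
#'   `syllable2`, `frequency`, and attributes `syllables` (annotation table)
#'   and `profile`.
#' @export
build_lexicon <- function(n_words, profile = c("native_like", "foreign_like", "random"),
                          seed = 1, irregular_fraction = 0.3, margin = NULL) {
  profile <- match.arg(profile)
  if (n_words < 4) abort("n_words must be >= 4")
  set.seed(seed)

  if (profile == "random") {
    pool <- .ft_syllable_pool(c(.ft_first_nuclei, .ft_second_nuclei))
    s1 <- sample(pool$label, n_words, replace = n_words > nrow(pool))
    s2 <- sample(pool$label, n_words, replace = n_words > nrow(pool))
    lex <- tibble(word = seq_len(n_words), syllable1 = s1, syllable2 = s2,
                  frequency = rep(100L, n_words))
    return(.ft_new_lexicon(lex, pool, profile))
  }

  if (is.null(margin)) margin <- if (profile == "native_like") 0.6 else 0.3
  first_pool <- .ft_syllable_pool(.ft_first_nuclei)
  second_pool <- .ft_syllable_pool(.ft_second_nuclei)
  if (n_words > nrow(first_pool)) {
    abort(sprintf("n_words = %d exceeds the %d distinct first syllables available",
                  n_words, nrow(first_pool)))
  }
  s1 <- sample(first_pool$label, n_words)
  ann1 <- first_pool[match(s1, first_pool$label), ]
  s2 <- vapply(seq_len(n_words), function(i) {
    .ft_make_syllable(.ft_map_onset(ann1$onset[i]),
                      .ft_map_nucleus(ann1$nucleus[i]))$label
  }, character(1))
  if (profile == "foreign_like") {
    n_irr <- floor(irregular_fraction * n_words)
    if (n_irr > 0) {
      idx <- sample(n_words, n_irr)
      s2[idx] <- sample(second_pool$label, n_irr, replace = TRUE)
    }
  }
  freq <- pmax(10L, as.integer(round(stats::rlnorm(n_words, log(60), 0.5))))
  lex <- tibble(word = seq_len(n_words), syllable1 = s1, syllable2 = s2,
                frequency = freq)
  pool <- dplyr::bind_rows(first_pool, second_pool)
  out <- .ft_new_lexicon(lex, pool, profile)

  got <- .ft_identity_margin(out)
  if (got < margin) {
    abort(sprintf(
      "n_words = %d cannot satisfy the %s within-vs-between margin %.2f (achieved %.3f)",
      n_words, profile, margin, got))
  }
  out
}

.ft_new_lexicon <- function(lex, pool, profile) {
  pool <- dplyr::distinct(pool)
  stopifnot(all(lex$syllable1 %in% pool$label), all(lex$syllable2 %in% pool$label),
            all(lex$frequency >= 0))
  structure(lex, class = c("ft_lexicon", class(lex)),
            syllables = pool, profile = profile)
}

#' @export
print.ft_lexicon <- function(x, ...) {
  cat(sprintf("<ft_lexicon> %d words, profile '%s', %d syllables in inventory\n",
              nrow(x), attr(x, "profile"), nrow(attr(x, "syllables"))))
  NextMethod()
}

# expected within-vs-between identity-TP margin implied by the lexicon
# frequencies: within = freq-weighted mean of freq(pair)/freq(first syllable
# word-initially); between = collision probability of word-initial syllables
.ft_identity_margin <- function(lexicon) {
  f1 <- tapply(lexicon$frequency, lexicon$syllable1, sum)
  within <- sum(lexicon$frequency / f1[lexicon$syllable1] * lexicon$frequency) /
    sum(lexicon$frequency)
  p_start <- f1 / sum(f1)
  between <- sum(p_start^2)
  within - between
}

#' Syllable annotation table of a lexicon
#'
#' @param lexicon An `ft_lexicon`.
#' @return Tibble with columns `label`, `onset`, `nucleus`, `coda`,
#'   `cv_pattern`, `manner`.
#' @export
syllable_inventory <- function(lexicon) {
  stopifnot(inherits(lexicon, "ft_lexicon"))
  attr(lexicon, "syllables")
}

#' Filter a lexicon by wordform frequency and syllable transition probability
#'
#' The syllable transition probability (STP) of a word is its wordform
#' frequency divided by the summed frequency of all wordforms sharing its
#' first syllable. Words are retained when `frequency >= min_frequency` and
#' `STP >= min_stp`.
#'
#' @param lexicon An `ft_lexicon`.
#' @param min_frequency Minimum wordform frequency (default 10).
#' @param min_stp Minimum STP (default 0.003, i.e. 0.3%).
#' @return The filtered `ft_lexicon` with an `stp` column added.
#' @export
select_words <- function(lexicon, min_frequency = 10, min_stp = 0.003) {
  stopifnot(inherits(lexicon, "ft_lexicon"))
  f1 <- tapply(lexicon$frequency, lexicon$syllable1, sum)
  stp <- lexicon$frequency / as.numeric(f1[lexicon$syllable1])
  keep <- lexicon$frequency >= min_frequency & stp >= min_stp
  out <- lexicon[keep, , drop = FALSE]
  out$stp <- stp[keep]
  .ft_new_lexicon(out, attr(lexicon, "syllables"), attr(lexicon, "profile"))
}

#' Read / write a lexicon as TSV
#'
#' The TSV has the word table columns (`syllable1`, `syllable2`,
#' `frequency`) followed by the syllable annotation columns (`label`,
#' `onset`, `nucleus`, `coda`, `cv_pattern`, `manner`) in a second block
#' written to a companion file `<path>.syllables.tsv`.
#'
#' @param lexicon An `ft_lexicon`.
#' @param path Path of the word-table TSV.
#' @return `write_lexicon_tsv()` returns `path` invisibly;
#'   `read_lexicon_tsv()` returns an `ft_lexicon`.
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "ft_lexicon"))
  utils::write.table(as.data.frame(lexicon[, c("syllable1", "syllable2", "frequency")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(as.data.frame(attr(lexicon, "syllables")),
                     paste0(path, ".syllables.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lexicon_tsv
#' @param profile Profile label recorded on the lexicon read back in.
#' @export
read_lexicon_tsv <- function(path, profile = "native_like") {
  lex <- as_tibble(utils::read.delim(path, fileEncoding = "UTF-8",
                                     colClasses = c("character", "character", "integer")))
  stopifnot(all(c("syllable1", "syllable2", "frequency") %in% names(lex)))
  pool <- as_tibble(utils::read.delim(paste0(path, ".syllables.tsv"),
                                      fileEncoding = "UTF-8",
                                      colClasses = "character"))
  lex$word <- seq_len(nrow(lex))
  .ft_new_lexicon(lex[, c("word", "syllable1", "syllable2", "frequency")],
                  pool, profile)
}
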