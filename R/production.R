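# The learner's quasi-random syllabic babble, biased towards perceived
# frequencies, with lexicon words as additional top-level candidates.
#
# Draw order within one babble step (documented for bit-reproducibility):
# first the candidate draw (uniform over the four syllable types plus the
# lexicon words), then - if a type was drawn - the syllable draw
# (frequency-proportional, or uniform random legal syllable when the type's
# table is empty).  All randomness comes from R's global RNG; seed it once
# per session.

#' Draw a production candidate
#'
#' A uniform draw over `4 + |lexicon|` items: the four syllable types plus
#' every word in the lexicon.  With an empty lexicon each type has
#' probability 1/4; with two words in the lexicon there are six candidate
#' items at 1/6 each.  Drawing a lexicon word emits that word directly,
#' which is how reinforced forms gain a higher production probability.
#'
#' @param lexicon A [lexicon()].
#' @return A list with `kind` (`"type"` or `"word"`) and `value` (the type
#'   tag or the lexicon word's phoneme string).
#' @export
choose_candidate <- function(lexicon) {
  items <- c(SYLLABLE_TYPES, lexicon_words(lexicon))
  i <- sample.int(length(items), 1L)
  if (i <= 4L) list(kind = "type", value = items[i])
  else list(kind = "word", value = items[i])
}

#' Production probabilities for one syllable type
#'
#' The exact categorical distribution the biased babble samples from:
#' perceived counts normalised by their sum.  If syllables of the chosen
#' type were perceived 1, 3 and 6 times, their production probabilities are
#' 1/10, 3/10 and 6/10.
#'
#' @param table A [syllable_table()].
#' @param stype Syllable type.
#' @return Named numeric vector of probabilities (empty if no syllables of
#'   that type have been perceived).
#' @export
production_probs <- function(table, stype) {
  r <- rank_syllables(table, stype)
  if (!nrow(r)) return(stats::setNames(numeric(), character()))
  stats::setNames(r$count / sum(r$count), r$syllable)
}

#' Sample one syllable of a given type
#'
#' Frequency-proportional draw from the type's perception table; if the
#' table is empty for that type (the initial random-babble state), a uniform
#' random legal syllable of that type is generated instead.
#'
#' @param table A [syllable_table()].
#' @param stype Syllable type.
#' @param inventory,clusters Phonology configuration (used for the
#'   random-babble fallback).
#' @return A syllable as a space-collapsed phoneme string.
#' @export
sample_syllable <- function(table, stype, inventory = cmu_phonemes(),
                            clusters = english_clusters()) {
  p <- production_probs(table, stype)
  if (!length(p))
    return(random_syllable(stype, inventory, clusters))
  names(p)[sample.int(length(p), 1L, prob = p)]
}

#' Generate a uniform random legal syllable
#'
#' Uniform over (onset choice) x (vowel) x (coda choice): for types with an
#' onset/coda, the cluster is drawn uniformly from the legal single
#' consonants plus the listed multi-consonant clusters (in `"permissive"`
#' mode, a uniform length 1..max then uniform consonants).
#'
#' @param stype Syllable type to generate.
#' @param inventory,clusters Phonology configuration.
#' @return A syllable as a space-collapsed phoneme string.
#' @export
random_syllable <- function(stype, inventory = cmu_phonemes(),
                            clusters = english_clusters()) {
  stype <- match.arg(stype, SYLLABLE_TYPES)
  draw_cluster <- function(edge) {
    pool <- switch(clusters$mode,
                   single = inventory$consonants,
                   list = c(inventory$consonants, clusters[[edge]]),
                   permissive = NULL)
    if (is.null(pool)) {   # permissive: uniform length, uniform consonants
      len <- sample.int(clusters$max_cluster_len, 1L)
      return(paste(sample(inventory$consonants, len, replace = TRUE),
                   collapse = " "))
    }
    pool[sample.int(length(pool), 1L)]
  }
  vowel <- inventory$vowels[sample.int(length(inventory$vowels), 1L)]
  parts <- c(if (grepl("^C", stype)) draw_cluster("onsets"),
             vowel,
             if (grepl("C$", stype)) draw_cluster("codas"))
  paste(parts, collapse = " ")
}

#' Produce one babbled utterance
#'
#' Each of the `n_syllables` positions is filled via [choose_candidate()]
#' followed by [sample_syllable()] (or direct emission of a drawn lexicon
#' word).  Identical RNG state and table/lexicon state give identical
#' utterances.
#'
#' @param table A [syllable_table()].
#' @param lexicon A [lexicon()].
#' @param turn Integer turn index recorded on the utterance.
#' @param n_syllables Syllables per utterance (default 5, the typical count
#'   of one 4-second babble turn).
#' @param inventory,clusters Phonology configuration.
#' @return An `utterance`: list with `syllables` (character vector of
#'   space-collapsed phoneme strings), `stypes`, and `turn`.
#' @export
babble <- function(table, lexicon, turn, n_syllables = 5L,
                   inventory = cmu_phonemes(), clusters = english_clusters()) {
  syllables <- character(n_syllables)
  stypes <- character(n_syllables)
  for (j in seq_len(n_syllables)) {
    cand <- choose_candidate(lexicon)
    if (cand$kind == "word") {
      syllables[j] <- cand$value
      stypes[j] <- "CVC"          # lexicon entries are CVC by construction
    } else {
      syllables[j] <- sample_syllable(table, cand$value, inventory, clusters)
      stypes[j] <- cand$value
    }
  }
  utterance(syllables, stypes, turn)
}

#' Construct a learner utterance
#'
#' @param syllables Character vector of space-collapsed phoneme strings.
#' @param stypes Matching syllable type tags (computed by parsing if
#'   omitted).
#' @param turn Integer turn index.
#' @param inventory,clusters Phonology configuration (only used when
#'   `stypes` must be computed).
#' @return An object of class `utterance`.
#' @export
utterance <- function(syllables, stypes = NULL, turn = NA_integer_,
                      inventory = cmu_phonemes(),
                      clusters = english_clusters()) {
  if (is.null(stypes)) {
    stypes <- vapply(syllables, function(s) {
      form <- parse_syllable(strsplit(s, " +")[[1L]], inventory, clusters)
      if (is.null(form)) stop("not a legal syllable: '", s, "'")
      form$stype
    }, character(1), USE.NAMES = FALSE)
  }
  structure(list(syllables = syllables, stypes = stypes,
                 turn = as.integer(turn)),
            class = "utterance")
}

#' Format an utterance in dialogue notation
#'
#' Multi-phoneme syllables are parenthesised, single phonemes left bare:
#' `(ao k s) (ow d z) ae (r eh d) (ao s)`.
#'
#' @param u An [utterance()].
#' @return A single string.
#' @export
format_utterance <- function(u) {
  paste(ifelse(grepl(" ", u$syllables), paste0("(", u$syllables, ")"),
               u$syllables),
        collapse = " ")
}

#' @export
print.utterance <- function(x, ...) {
  cat(format_utterance(x), "\n")
  invisible(x)
}

#' Parse dialogue notation back into an utterance
#'
#' Inverse of [format_utterance()]: parenthesised groups are syllables, bare
#' tokens are single-phoneme syllables.
#'
#' @param text A string such as `"(ao k s) ae (r eh d)"`.
#' @param turn Integer turn index.
#' @param inventory,clusters Phonology configuration.
#' @return An [utterance()].
#' @export
parse_utterance <- function(text, turn = NA_integer_,
                            inventory = cmu_phonemes(),
                            clusters = english_clusters()) {
  text <- trimws(text)
  m <- gregexpr("\\(([^)]*)\\)|[^()[:space:]]+", text)[[1L]]
  toks <- regmatches(text, list(m))[[1L]]
  syllables <- trimws(gsub("[()]", "", toks))
  syllables <- tolower(gsub("[[:space:]]+", " ", syllables))
  utterance(syllables[nzchar(syllables)], NULL, turn, inventory, clusters)
}
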