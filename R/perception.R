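# Exhaustive overlapping-syllable extraction from unsegmented phoneme
# streams, and the learner's per-type frequency/recency tables.

SYLLABLE_TYPES <- c("V", "CV", "VC", "CVC")

#' Create an empty syllable table
#'
#' The learner's perceptual store: for each syllable type (V, CV, VC, CVC) a
#' hash map from syllable (space-collapsed phoneme sequence) to its
#' occurrence count and the dialogue turn at which it was last heard.
#' `perceive()` updates the table in place (reference semantics, as with
#' environments); it also returns the table so calls can be chained.
#'
#' @return An object of class `syllable_table`.
#' @seealso [perceive()], [rank_syllables()], [syllable_count()]
#' @export
syllable_table <- function() {
  types <- stats::setNames(
    lapply(SYLLABLE_TYPES, function(t) new.env(parent = emptyenv())),
    SYLLABLE_TYPES
  )
  structure(list(types = types), class = "syllable_table")
}

#' @export
print.syllable_table <- function(x, ...) {
  sizes <- vapply(x$types, function(e) length(ls(e)), integer(1))
  cat("<syllable_table> distinct syllables:",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract every possible syllable from an unsegmented phoneme stream
#'
#' With no segmentation knowledge, every contiguous substring of the stream
#' that parses as a legal syllable (exactly one vowel, legal onset/coda
#' clusters of up to 3 consonants) is returned, with multiplicity; extracted
#' syllables therefore overlap.  For the pseudo-phoneme stream
#' `a r e d b o x` (letters as phonemes, single-consonant mode) this is
#' *a, ar, re, red, e, ed, bo, box, o, ox*.
#'
#' @param tokens Character vector: the phoneme stream (one utterance).
#' @param inventory A [phoneme_inventory()].
#' @param clusters A [cluster_inventory()].
#' @return A data frame with one row per occurrence: columns `syllable`
#'   (space-collapsed phonemes) and `stype`.
#' @export
extract_syllables <- function(tokens, inventory = cmu_phonemes(),
                              clusters = english_clusters()) {
  tokens <- .check_tokens(tokens, inventory)
  n <- length(tokens)
  if (n == 0L)
    return(data.frame(syllable = character(), stype = character()))
  is_v <- unname(inventory$category[tokens]) == "vowel"
  maxc <- clusters$max_cluster_len
  syl <- character(0)
  sty <- character(0)
  for (i in which(is_v)) {
    # onset lengths 0..maxc of pure consonants ending at i-1
    for (on in 0:min(maxc, i - 1L)) {
      if (on > 0L) {
        if (is_v[i - on]) break      # vowel entered the onset window
        if (!is_legal_onset(clusters, tokens[(i - on):(i - 1L)])) next
      }
      for (co in 0:min(maxc, n - i)) {
        if (co > 0L) {
          if (is_v[i + co]) break    # vowel entered the coda window
          if (!is_legal_coda(clusters, tokens[(i + 1L):(i + co)])) next
        }
        syl[length(syl) + 1L] <- paste(tokens[(i - on):(i + co)],
                                       collapse = " ")
        sty[length(sty) + 1L] <- paste0(if (on) "C" else "", "V",
                                        if (co) "C" else "")
      }
    }
  }
  data.frame(syllable = syl, stype = sty)
}

#' Perceive an utterance: update the syllable frequency/recency table
#'
#' Every syllable occurrence extracted from the stream increments that
#' syllable's count by 1 and sets its last-heard turn to `turn`.  Streams
#' are perceived per utterance; syllables never span utterance boundaries.
#'
#' @param table A [syllable_table()] (updated in place).
#' @param tokens Phoneme stream of one teacher utterance.
#' @param turn Integer dialogue-turn index at which the stream was heard.
#' @param inventory,clusters Phonology configuration.
#' @return The updated table, invisibly.
#' @export
perceive <- function(table, tokens, turn, inventory = cmu_phonemes(),
                     clusters = english_clusters()) {
  stopifnot(inherits(table, "syllable_table"))
  occ <- extract_syllables(tokens, inventory, clusters)
  if (nrow(occ)) {
    for (k in seq_len(nrow(occ))) {
      env <- table$types[[occ$stype[k]]]
      key <- occ$syllable[k]
      prev <- if (exists(key, envir = env, inherits = FALSE))
        get(key, envir = env, inherits = FALSE) else c(0, NA_real_)
      assign(key, c(prev[1] + 1, as.numeric(turn)), envir = env)
    }
  }
  invisible(table)
}

#' Look up a syllable's perception statistics
#'
#' @param table A [syllable_table()].
#' @param syllable Space-collapsed phoneme sequence, e.g. `"r eh d"`.
#' @param stype Syllable type; if `NULL`, all types are searched.
#' @return `syllable_count()`: the occurrence count (0 if never perceived).
#'   `last_heard()`: the turn of the most recent perception (`NA` if never).
#' @export
syllable_count <- function(table, syllable, stype = NULL) {
  .lookup_stat(table, syllable, stype, 1L, 0)
}

#' @rdname syllable_count
#' @export
last_heard <- function(table, syllable, stype = NULL) {
  .lookup_stat(table, syllable, stype, 2L, NA_real_)
}

.lookup_stat <- function(table, syllable, stype, slot, default) {
  envs <- if (is.null(stype)) table$types else table$types[stype]
  for (env in envs) {
    if (exists(syllable, envir = env, inherits = FALSE))
      return(get(syllable, envir = env, inherits = FALSE)[slot])
  }
  default
}

#' Rank the syllables of one type by perceived frequency
#'
#' Descending by count; ties are broken lexicographically by phoneme
#' sequence, for reproducibility.
#'
#' @param table A [syllable_table()].
#' @param stype One of `"V"`, `"CV"`, `"VC"`, `"CVC"`.
#' @return A data frame with columns `rank`, `syllable`, `count`,
#'   `last_heard` (empty if no syllables of that type have been perceived).
#' @export
rank_syllables <- function(table, stype) {
  stype <- match.arg(stype, SYLLABLE_TYPES)
  env <- table$types[[stype]]
  keys <- sort(ls(env))            # lexicographic tie-break
  if (!length(keys))
    return(data.frame(rank = integer(), syllable = character(),
                      count = numeric(), last_heard = numeric()))
  stats_m <- vapply(keys, function(k) get(k, envir = env, inherits = FALSE),
                    numeric(2))
  ord <- order(-stats_m[1L, ])     # stable sort keeps lexicographic ties
  data.frame(rank = seq_along(keys), syllable = keys[ord],
             count = unname(stats_m[1L, ord]),
             last_heard = unname(stats_m[2L, ord]))
}

#' Convert a syllable table to a data frame
#'
#' @param x A [syllable_table()].
#' @param ... Unused.
#' @return Data frame with columns `stype`, `syllable`, `count`,
#'   `last_heard`, ordered by type then descending count.
#' @export
as.data.frame.syllable_table <- function(x, ...) {
  parts <- lapply(SYLLABLE_TYPES, function(t) {
    r <- rank_syllables(x, t)
    if (nrow(r)) cbind(stype = t, r[c("syllable", "count", "last_heard")])
    else NULL
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(stype = character(), syllable = character(),
                      count = numeric(), last_heard = numeric())
  rownames(out) <- NULL
  out
}

#' Read a phoneme-stream corpus
#'
#' One utterance per line, whitespace-separated phoneme symbols; `#` starts
#' a comment; blank lines are skipped.
#'
#' @param path Path to the corpus file, or a character vector of lines via
#'   `text`.
#' @param text Optional character vector of lines (used instead of `path`).
#' @return A list of token vectors, one per utterance.
#' @export
read_corpus <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(strsplit(lines, "[[:space:]]+"), tolower)
}

#' Write a syllable table as TSV
#'
#' Columns: `stype`, `syllable`, `count`, `last_heard`.
#'
#' @param table A [syllable_table()].
#' @param path Output file path.
#' @export
write_syllable_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank-frequency export for Zipf plots
#'
#' @param table A [syllable_table()].
#' @param stype Syllable type to export.
#' @param path Optional CSV output path (columns `rank`, `syllable`,
#'   `count`).
#' @return The rank-frequency data frame, invisibly if written to file.
#' @export
rank_frequency <- function(table, stype, path = NULL) {
  rf <- rank_syllables(table, stype)[c("rank", "syllable", "count")]
  if (!is.null(path)) {
    utils::write.csv(rf, path, row.names = FALSE, quote = FALSE)
    return(invisible(rf))
  }
  rf
}

#' Log-log rank-frequency (Zipf) plot
#'
#' @param table A [syllable_table()].
#' @param stype Syllable type to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_rank_frequency <- function(table, stype, ...) {
  rf <- rank_frequency(table, stype)
  if (!nrow(rf)) stop("no syllables of type ", stype, " perceived yet")
  graphics::plot(rf$rank, rf$count, log = "xy", xlab = "rank",
                 ylab = "frequency",
                 main = paste0("Rank-frequency of ", stype, " syllables"),
                 ...)
  invisible(rf)
}
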