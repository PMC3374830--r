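# Approval detection and the reinforcement heuristic that moves one CVC
# syllable of the learner's previous utterance into the lexicon.

#' Construct an approval set
#'
#' The approving comments the learner listens for (e.g. "well done", "good",
#' "clever"), each with a canonical phonemic rendering.  Detection is exact
#' contiguous matching of the rendering inside the teacher's perceived
#' phoneme stream; recognizer noise (which can corrupt the rendering and
#' make detection fail) is part of the synthetic teacher, not of detection.
#'
#' @param terms Character vector of orthographic terms.
#' @param phonemes Character vector of space-separated phonemic renderings,
#'   same length as `terms`.
#' @return An object of class `approval_set`.
#' @export
approval_set <- function(terms, phonemes) {
  stopifnot(length(terms) == length(phonemes), length(terms) > 0)
  structure(
    data.frame(term = as.character(terms),
               phonemes = tolower(gsub("[[:space:]]+", " ",
                                       trimws(phonemes)))),
    class = c("approval_set", "data.frame")
  )
}

#' The default approval terms
#'
#' well done, good, clever, yes, very good -- read from the editable file
#' `system.file("extdata", "approval_terms.tsv", package = "babblelex")`.
#'
#' @return An [approval_set()].
#' @export
default_approvals <- function() {
  if (is.null(.babblelex_cache$approvals)) {
    path <- system.file("extdata", "approval_terms.tsv",
                        package = "babblelex", mustWork = TRUE)
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("term", "phonemes"))
    .babblelex_cache$approvals <- approval_set(tab$term, tab$phonemes)
  }
  .babblelex_cache$approvals
}

#' Does a phoneme stream contain an approval term?
#'
#' TRUE iff the phonemic rendering of any approval term occurs as a
#' contiguous subsequence of the stream.
#'
#' @param tokens Phoneme stream (character vector); may be empty.
#' @param approvals An [approval_set()].
#' @return Logical scalar.
#' @export
#' @examples
#' detect_approval(c("w", "eh", "l", "d", "ah", "n"))
detect_approval <- function(tokens, approvals = default_approvals()) {
  if (!length(tokens)) return(FALSE)
  hay <- paste0(" ", paste(tolower(tokens), collapse = " "), " ")
  any(vapply(approvals$phonemes,
             function(p) grepl(paste0(" ", p, " "), hay, fixed = TRUE),
             logical(1)))
}

#' Create an empty lexicon
#'
#' The learner's store of reinforced CVC word forms ("ilex").  Entries are
#' only ever added or re-counted, never removed during a session.  Like
#' [syllable_table()], the lexicon has reference semantics.
#'
#' @return An object of class `lexicon`.
#' @export
lexicon <- function() {
  structure(list(entries = new.env(parent = emptyenv())), class = "lexicon")
}

#' Lexicon contents
#'
#' @param lexicon A [lexicon()].
#' @return `lexicon_words()`: sorted character vector of the stored phoneme
#'   strings.  `lexicon_size()`: the number of entries.
#' @export
lexicon_words <- function(lexicon) sort(ls(lexicon$entries))

#' @rdname lexicon_words
#' @export
lexicon_size <- function(lexicon) length(ls(lexicon$entries))

#' @export
print.lexicon <- function(x, ...) {
  w <- lexicon_words(x)
  cat("<lexicon> ", length(w), " entries",
      if (length(w)) paste0(": ", paste0("(", w, ")", collapse = " ")),
      "\n", sep = "")
  invisible(x)
}

#' Convert a lexicon to a data frame
#'
#' @param x A [lexicon()].
#' @param ... Unused.
#' @return Data frame with columns `form`, `first_learned_turn`,
#'   `reinforcement_count`, in insertion-turn order.
#' @export
as.data.frame.lexicon <- function(x, ...) {
  w <- lexicon_words(x)
  if (!length(w))
    return(data.frame(form = character(), first_learned_turn = integer(),
                      reinforcement_count = integer()))
  m <- vapply(w, function(k) get(k, envir = x$entries, inherits = FALSE),
              numeric(2))
  out <- data.frame(form = w, first_learned_turn = as.integer(m[1L, ]),
                    reinforcement_count = as.integer(m[2L, ]))
  out <- out[order(out$first_learned_turn, out$form), ]
  rownames(out) <- NULL
  out
}

#' Write a lexicon as TSV
#'
#' @param lexicon A [lexicon()].
#' @param path Output file path.
#' @param gloss Optional named character vector mapping phoneme strings to
#'   orthographic glosses.
#' @export
write_lexicon <- function(lexicon, path, gloss = NULL) {
  df <- as.data.frame(lexicon)
  df$gloss <- if (is.null(gloss)) NA_character_ else unname(gloss[df$form])
  utils::write.table(df[c("form", "gloss", "first_learned_turn",
                          "reinforcement_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score a syllable for reinforcement selection
#'
#' The selection heuristic combines the syllable's perceived frequency with
#' the elapsed time since the teacher last uttered it.  Two functional forms
#' are available:
#'
#' * `"count_recency"` (default): `count / (1 + dt)`;
#' * `"exp_decay"`: `count * exp(-lambda * dt)`.
#'
#' `dt` is measured in dialogue turns.  Syllables never heard from the
#' teacher score 0.
#'
#' @param count Perceived occurrence count.
#' @param dt Turns elapsed since last heard (`NA` if never heard).
#' @param method Scoring strategy name.
#' @param lambda Decay rate for `"exp_decay"` (default 0.1 per turn).
#' @return Numeric score (vectorised).
#' @export
syllable_score <- function(count, dt, method = c("count_recency",
                                                 "exp_decay"),
                           lambda = 0.1) {
  method <- match.arg(method)
  s <- switch(method,
              count_recency = count / (1 + dt),
              exp_decay = count * exp(-lambda * dt))
  ifelse(is.na(dt) | count <= 0, 0, s)
}

#' Select the syllable to reinforce from the previous learner utterance
#'
#' Applied when approval is detected: among the CVC syllables of the
#' learner's immediately preceding utterance (only CVC types are candidates
#' for selection), returns the one with the highest [syllable_score()].
#' Ties are broken by smaller elapsed time, then lexicographically.  Returns
#' `NULL` when the utterance contains no CVC syllable with positive score
#' (a heuristic failure at the event level).
#'
#' @param prev The learner [utterance()] immediately preceding the approval.
#' @param table The [syllable_table()] of teacher perceptions.
#' @param now Integer current turn index.
#' @param method,lambda Passed to [syllable_score()].
#' @return A syllable phoneme string, or `NULL`.
#' @details Score ties are broken by smaller elapsed time, then by longer
#'   form (more phonemes), then lexicographically.  Preferring the longer
#'   form matters because a word with a cluster edge co-occurs with an
#'   extraction shadow of itself at identical count and recency (every
#'   `b aa k s` also yields `b aa k`); a tie-break blind to length would
#'   systematically reinforce the fragment instead of the word.
#' @export
heuristic_select <- function(prev, table, now, method = "count_recency",
                             lambda = 0.1) {
  cand <- unique(prev$syllables[prev$stypes == "CVC"])
  if (!length(cand)) return(NULL)
  count <- vapply(cand, function(s) syllable_count(table, s, "CVC"),
                  numeric(1))
  heard <- vapply(cand, function(s) last_heard(table, s, "CVC"), numeric(1))
  dt <- now - heard
  score <- syllable_score(count, dt, method, lambda)
  if (all(score <= 0)) return(NULL)
  n_phon <- lengths(strsplit(cand, " ", fixed = TRUE))
  ord <- order(-score, dt, -n_phon, cand)
  cand[ord][1L]
}

#' Reinforce a CVC syllable into the lexicon
#'
#' Adds a new entry (recording the turn it was first learned) or increments
#' the reinforcement count of an existing one.  Non-CVC input is a contract
#' violation and an error.
#'
#' @param lexicon A [lexicon()] (updated in place).
#' @param syllable Space-collapsed phoneme string of a CVC syllable.
#' @param turn Integer turn index of the reinforcement event.
#' @param inventory,clusters Phonology configuration (for the CVC check).
#' @return The updated lexicon, invisibly.
#' @export
reinforce <- function(lexicon, syllable, turn, inventory = cmu_phonemes(),
                      clusters = english_clusters()) {
  form <- parse_syllable(strsplit(syllable, " +")[[1L]], inventory, clusters)
  if (is.null(form) || form$stype != "CVC")
    stop("only CVC syllables can be reinforced, got '", syllable, "'")
  key <- paste(form$phonemes, collapse = " ")
  env <- lexicon$entries
  if (exists(key, envir = env, inherits = FALSE)) {
    prev <- get(key, envir = env, inherits = FALSE)
    assign(key, c(prev[1L], prev[2L] + 1), envir = env)
  } else {
    assign(key, c(as.numeric(turn), 1), envir = env)
  }
  invisible(lexicon)
}
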