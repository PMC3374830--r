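# Synthetic teacher: child-directed-speech-like utterances with Zipf-like
# word frequencies, near-canonical pronunciation of salient content words vs
# variable pronunciation of function words, phoneme-recognizer noise, and
# imperfect approval behaviour (missed words, over-praise, talk-over).
#
# Draw order within one teacher step (for reproducibility): utterance length,
# word draws, per-word canonical/variant draw, per-phoneme noise draws
# (substitution then deletion), per-word talkover draws.  In respond():
# hearing draw, heard-word draw, overpraise draw, approval-term draw.

#' Read a scenario vocabulary file
#'
#' TSV columns: `orth` (orthographic form), `phonemes` (canonical phonemic
#' rendering), `role` (`salient`, `other_word` or `function`), `weight`
#' (positive base frequency weight), and optional `variants`
#' (pipe-separated alternative renderings).  `#` starts a comment.
#'
#' @param path Path to the vocabulary file.
#' @return A data frame of class `vocabulary`.
#' @export
read_vocabulary <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           fill = TRUE, quote = "",
                           col.names = c("orth", "phonemes", "role",
                                         "weight", "variants"))
  tab$variants[is.na(tab$variants)] <- ""
  vocabulary(tab$orth, tab$phonemes, tab$role, tab$weight, tab$variants)
}

#' Construct a scenario vocabulary
#'
#' @param orth Orthographic word forms.
#' @param phonemes Canonical phonemic renderings (space-separated symbols).
#' @param role One of `salient`, `other_word`, `function` per word.
#' @param weight Positive base frequency weights.
#' @param variants Pipe-separated alternative renderings (may be `""`).
#' @return A data frame of class `vocabulary` with columns as above.
#' @export
vocabulary <- function(orth, phonemes, role, weight, variants = "") {
  role <- match.arg(role, c("salient", "other_word", "function"),
                    several.ok = TRUE)
  stopifnot(all(weight > 0))
  norm <- function(p) tolower(gsub("[[:space:]]+", " ", trimws(p)))
  v <- data.frame(orth = as.character(orth), phonemes = norm(phonemes),
                  role = role, weight = as.numeric(weight),
                  variants = as.character(variants),
                  stringsAsFactors = FALSE)
  v$variants <- vapply(strsplit(v$variants, "|", fixed = TRUE),
                       function(x) paste(norm(x[nzchar(trimws(x))]),
                                         collapse = "|"),
                       character(1))
  class(v) <- c("vocabulary", "data.frame")
  v
}

.variant_pool <- function(entry) {
  v <- strsplit(entry$variants, "|", fixed = TRUE)[[1L]]
  v[nzchar(v)]
}

#' The shipped shapes-and-colours scenario vocabulary
#'
#' Read from `system.file("extdata", "vocabulary_cds.tsv", package =
#' "babblelex")`.
#'
#' @return A `vocabulary` data frame.
#' @export
default_vocabulary <- function() {
  if (is.null(.babblelex_cache$vocab)) {
    path <- system.file("extdata", "vocabulary_cds.tsv",
                        package = "babblelex", mustWork = TRUE)
    .babblelex_cache$vocab <- read_vocabulary(path)
  }
  .babblelex_cache$vocab
}

#' Construct a synthetic-teacher profile
#'
#' Bundles the vocabulary with the behavioural parameters of the simulated
#' teacher/recognizer channel.  All probabilities are in `[0, 1]`.
#'
#' @param vocabulary A [vocabulary()] data frame.
#' @param words_per_utterance Integer vector: the utterance length is drawn
#'   uniformly from it.
#' @param canonical_prob_content Probability a salient content word is
#'   realised canonically.
#' @param canonical_prob_function Probability a function (or other
#'   non-salient) word is realised canonically; must not exceed
#'   `canonical_prob_content` in a CDS profile.
#' @param sub_rate Per-phoneme probability of substitution by a uniformly
#'   chosen phoneme of the same category (recognizer noise).
#' @param del_rate Per-phoneme deletion probability (recognizer noise).
#' @param hearing_prob Probability the teacher notices a salient word in the
#'   learner's babble and approves.
#' @param overpraise_prob Probability of approval regardless of content.
#' @param talkover_drop Fraction of teacher words unperceived because of
#'   talk-over (each word dropped independently).
#' @param topic_share Fraction of each utterance's word slots occupied by
#'   the current topic word (the salient word being taught); child-directed
#'   teaching talk is topic-coherent, naming the object in focus repeatedly.
#' @param topic_dwell Number of consecutive teacher turns spent on one topic
#'   word before a new topic is drawn.  Topic dwell is what makes the
#'   recency term of the reinforcement heuristic informative: the word
#'   currently being taught is the recently heard one.
#' @param approvals An [approval_set()].
#' @return An object of class `teacher_profile`.
#' @export
teacher_profile <- function(vocabulary = default_vocabulary(),
                            words_per_utterance = 4:12,
                            canonical_prob_content = 1,
                            canonical_prob_function = 0.4,
                            sub_rate = 0.08, del_rate = 0.05,
                            hearing_prob = 0.3, overpraise_prob = 0.1,
                            talkover_drop = 0.05,
                            topic_share = 0.5, topic_dwell = 6L,
                            approvals = default_approvals()) {
  probs <- c(canonical_prob_content = canonical_prob_content,
             canonical_prob_function = canonical_prob_function,
             sub_rate = sub_rate, del_rate = del_rate,
             hearing_prob = hearing_prob, overpraise_prob = overpraise_prob,
             talkover_drop = talkover_drop)
  if (any(probs < 0 | probs > 1))
    stop("all profile probabilities must be in [0, 1]")
  if (canonical_prob_content < canonical_prob_function)
    stop("canonical_prob_content must be >= canonical_prob_function")
  # config error: a word that can be realised non-canonically needs variants
  canon_p <- ifelse(vocabulary$role == "salient",
                    canonical_prob_content, canonical_prob_function)
  no_var <- !nzchar(vocabulary$variants)
  if (any(canon_p < 1 & no_var))
    stop("canonical probability < 1 with empty variant pool for: ",
         paste(vocabulary$orth[canon_p < 1 & no_var], collapse = ", "))
  if (topic_share < 0 || topic_share > 1)
    stop("topic_share must be in [0, 1]")
  structure(
    list(vocabulary = vocabulary,
         words_per_utterance = as.integer(words_per_utterance),
         canonical_prob_content = canonical_prob_content,
         canonical_prob_function = canonical_prob_function,
         sub_rate = sub_rate, del_rate = del_rate,
         hearing_prob = hearing_prob, overpraise_prob = overpraise_prob,
         talkover_drop = talkover_drop,
         topic_share = topic_share, topic_dwell = as.integer(topic_dwell),
         approvals = approvals),
    class = "teacher_profile"
  )
}

#' @export
print.teacher_profile <- function(x, ...) {
  cat("<teacher_profile> ", nrow(x$vocabulary), " words (",
      sum(x$vocabulary$role == "salient"), " salient); canonical p ",
      x$canonical_prob_content, "/", x$canonical_prob_function,
      " (content/function); noise sub=", x$sub_rate, " del=", x$del_rate,
      "; hearing=", x$hearing_prob, " overpraise=", x$overpraise_prob,
      " talkover=", x$talkover_drop, "\n", sep = "")
  invisible(x)
}

#' The default child-directed-speech teacher profile
#'
#' The shipped vocabulary with the package's default behavioural parameters
#' (see [teacher_profile()] and the methods vignette for the rationale).
#'
#' @param ... Overrides passed to [teacher_profile()].
#' @return A `teacher_profile`.
#' @export
cds_profile <- function(...) teacher_profile(...)

#' An idealised teacher profile
#'
#' The attentive, focused teacher modelled on the effective participants: a
#' compact set of salient target words taught with canonical pronunciation
#' over a noise-free channel, perfect hearing and no over-praise.  This is
#' the regime in which every salient word the learner utters is approved, so
#' real and simulated reinforcement coincide.  A focused vocabulary is part
#' of the regime: an ideal teacher concentrates the session on a handful of
#' words, which lets each target build up the perceived frequency the
#' selection heuristic relies on (teaching spread thinly across many words
#' leaves low-frequency targets losing the heuristic to dominant forms --
#' see the methods vignette).
#'
#' @param vocabulary Vocabulary to draw the focus words from (default the
#'   shipped vocabulary).
#' @param focus Orthographic forms of the taught words (default the five
#'   dominant CVC colour/shape words of the shipped vocabulary).
#' @param ... Further overrides passed to [teacher_profile()].
#' @return A `teacher_profile`.
#' @export
ideal_profile <- function(vocabulary = default_vocabulary(),
                          focus = c("red", "green", "cross", "heart",
                                    "box"), ...) {
  voc <- vocabulary[vocabulary$role == "salient" &
                      vocabulary$orth %in% focus, ]
  if (!nrow(voc)) stop("no salient vocabulary entries match 'focus'")
  teacher_profile(vocabulary = voc,
                  canonical_prob_content = 1, canonical_prob_function = 1,
                  sub_rate = 0, del_rate = 0, hearing_prob = 1,
                  overpraise_prob = 0, talkover_drop = 0, ...)
}

#' Realise one vocabulary word as phonemes
#'
#' Canonical rendering with the word's role-dependent canonical probability
#' (salient words use `canonical_prob_content`; function and other words use
#' `canonical_prob_function`), otherwise a uniform draw from the variant
#' pool.
#'
#' @param entry One row of a [vocabulary()] data frame.
#' @param profile A [teacher_profile()].
#' @return Character vector of phoneme symbols.
#' @export
pronounce <- function(entry, profile) {
  p <- if (entry$role == "salient") profile$canonical_prob_content
       else profile$canonical_prob_function
  rendering <- entry$phonemes
  if (p < 1 && stats::runif(1) >= p) {
    pool <- .variant_pool(entry)
    if (!length(pool))
      stop("empty variant pool for '", entry$orth,
           "' with canonical probability < 1")
    rendering <- pool[sample.int(length(pool), 1L)]
  }
  strsplit(rendering, " ")[[1L]]
}

#' Apply recognizer noise to a phoneme stream
#'
#' Each phoneme is independently substituted (by a uniformly chosen *other*
#' phoneme of the same category) with probability `sub_rate`, then deleted
#' with probability `del_rate`.
#'
#' @param tokens Phoneme stream.
#' @param profile A [teacher_profile()].
#' @param inventory A [phoneme_inventory()].
#' @return The corrupted stream (possibly shorter).
#' @export
apply_phoneme_noise <- function(tokens, profile,
                                inventory = cmu_phonemes()) {
  n <- length(tokens)
  if (!n || (profile$sub_rate == 0 && profile$del_rate == 0))
    return(tokens)
  sub_hit <- stats::runif(n) < profile$sub_rate
  if (any(sub_hit)) {
    cat <- unname(inventory$category[tokens])
    for (i in which(sub_hit)) {
      pool <- if (cat[i] == "vowel") inventory$vowels
              else inventory$consonants
      pool <- setdiff(pool, tokens[i])
      tokens[i] <- pool[sample.int(length(pool), 1L)]
    }
  }
  keep <- stats::runif(n) >= profile$del_rate
  tokens[keep]
}

#' Generate one teacher utterance
#'
#' Teaching talk is topic-coherent: a salient topic word (the object in
#' focus) is drawn proportionally to vocabulary weight and occupies
#' `topic_share` of the utterance's word slots; the remaining slots are
#' filled with weight-proportional draws from the non-salient vocabulary
#' (function and other words), giving the characteristic child-directed mix
#' of a repeated content word among high-frequency filler.  If the
#' vocabulary has no non-salient entries the utterance is topic-only; if it
#' has no salient entries all slots are weight-proportional draws.  Each
#' word is realised via [pronounce()], passed through the recognizer noise
#' channel, subjected to talk-over word drop, and concatenated into one
#' unsegmented phoneme stream.
#'
#' @param profile A [teacher_profile()].
#' @param inventory A [phoneme_inventory()].
#' @param topic Orthographic form of the current topic word; `NULL` (the
#'   default) draws a fresh topic.  [run_session()] keeps a topic for
#'   `topic_dwell` consecutive teacher turns.
#' @return A list with `words` (orthographic ground truth), `tokens` (the
#'   phoneme stream as perceived by the learner) and `topic`.
#' @export
generate_teacher_utterance <- function(profile, inventory = cmu_phonemes(),
                                       topic = NULL) {
  voc <- profile$vocabulary
  sal_idx <- which(voc$role == "salient")
  oth_idx <- which(voc$role != "salient")
  len_pool <- profile$words_per_utterance
  k <- len_pool[sample.int(length(len_pool), 1L)]
  if (is.null(topic) && length(sal_idx)) {
    w <- voc$weight[sal_idx]
    topic <- voc$orth[sal_idx[sample.int(length(sal_idx), 1L, prob = w)]]
  }
  if (!is.null(topic)) {
    t_i <- match(topic, voc$orth)
    if (is.na(t_i)) stop("topic '", topic, "' is not in the vocabulary")
    n_topic <- if (length(oth_idx)) max(1L, round(profile$topic_share * k))
               else k
    n_topic <- min(n_topic, k)
    filler <- if (k > n_topic)
      oth_idx[sample.int(length(oth_idx), k - n_topic, replace = TRUE,
                         prob = voc$weight[oth_idx])]
    else integer()
    idx <- c(rep(t_i, n_topic), filler)
    idx <- idx[sample.int(length(idx))]           # shuffle slot order
  } else {
    idx <- sample.int(nrow(voc), k, replace = TRUE, prob = voc$weight)
  }
  words <- voc$orth[idx]
  streams <- lapply(idx, function(i)
    apply_phoneme_noise(pronounce(voc[i, ], profile), profile, inventory))
  if (profile$talkover_drop > 0) {
    keep <- stats::runif(k) >= profile$talkover_drop
    streams <- streams[keep]
  }
  list(words = words, tokens = unlist(streams, use.names = FALSE),
       topic = topic)
}

#' Teacher reaction to a learner utterance
#'
#' If the utterance contains the canonical form of a salient word, the
#' teacher notices it with probability `hearing_prob` and approves,
#' recording *which* word was heard (simulator-only ground truth, used by
#' the evaluator).  Independently, approval may be issued with probability
#' `overpraise_prob` regardless of content (no heard word).  The approval is
#' rendered as the phoneme stream of a randomly chosen approval term.
#'
#' @param learner_utterance An [utterance()].
#' @param profile A [teacher_profile()].
#' @return `NULL` (no approval), or a list with `term`, `tokens` (the
#'   canonical rendering of the chosen approval term) and `heard_word`
#'   (orthographic form, or `NA` for content-free over-praise).
#' @export
respond <- function(learner_utterance, profile) {
  voc <- profile$vocabulary
  sal <- voc[voc$role == "salient", ]
  present <- sal$orth[sal$phonemes %in% learner_utterance$syllables]
  heard_word <- NA_character_
  approve <- FALSE
  if (length(present) && stats::runif(1) < profile$hearing_prob) {
    approve <- TRUE
    heard_word <- present[sample.int(length(present), 1L)]
  } else if (profile$overpraise_prob > 0 &&
             stats::runif(1) < profile$overpraise_prob) {
    approve <- TRUE
  }
  if (!approve) return(NULL)
  a <- profile$approvals
  i <- sample.int(nrow(a), 1L)
  list(term = a$term[i], tokens = strsplit(a$phonemes[i], " ")[[1L]],
       heard_word = heard_word)
}
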