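# Lexicon classification, reinforcement tallies, and the four F-measure
# variants that compare real against simulated reinforcement.

#' Equal-weight F-measure
#'
#' `F = 2 tp / (2 tp + fp + fn)`, the harmonic mean of precision and recall
#' with both weighted equally; maximal at 1 when everything is learnt with
#' no false positives or negatives.  The degenerate case `tp = fp = fn = 0`
#' is defined as 0, with a warning.
#'
#' @param tp,fp,fn Non-negative counts of true positives, false positives
#'   and false negatives (vectorised).
#' @return Numeric value(s) in `[0, 1]`.
#' @export
#' @examples
#' f_measure(5, 11, 17)   # 0.263...
f_measure <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  denom <- 2 * tp + fp + fn
  if (any(denom == 0))
    warning("F-measure undefined for tp = fp = fn = 0; reporting 0")
  ifelse(denom == 0, 0, 2 * tp / denom)
}

#' Round half away from zero
#'
#' Plain half-up rounding (0.005 -> 0.01), matching how the published
#' two-decimal tables are formatted, unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify lexicon contents against the scenario dictionaries
#'
#' Each lexicon entry is labelled `salient` (a canonical salient word form:
#' a true positive), `other_word` (the canonical form of a proper but
#' non-salient word, such as "this" or "that"), or `non_word` (anything
#' else: recognizer-error forms and sandhi syllables bridging adjacent
#' words).
#'
#' @param lex A [lexicon()] or a character vector of phoneme strings.
#' @param vocabulary A [vocabulary()] data frame supplying both
#'   dictionaries: its salient rows and its non-salient (function/other)
#'   rows.
#' @return A list with `labels` (data frame: `form`, `label`, `orth`) and
#'   counts `tp`, `fp_other`, `fp_nonwords`.
#' @export
classify_lexicon <- function(lex, vocabulary = default_vocabulary()) {
  forms <- if (inherits(lex, "lexicon")) lexicon_words(lex)
           else as.character(lex)
  sal <- vocabulary[vocabulary$role == "salient", ]
  oth <- vocabulary[vocabulary$role != "salient", ]
  label <- ifelse(forms %in% sal$phonemes, "salient",
                  ifelse(forms %in% oth$phonemes, "other_word", "non_word"))
  orth <- vocabulary$orth[match(forms, vocabulary$phonemes)]
  list(labels = data.frame(form = forms, label = label, orth = orth),
       tp = sum(label == "salient"),
       fp_other = sum(label == "other_word"),
       fp_nonwords = sum(label == "non_word"))
}

#' The four F-measure variants from reinforcement tallies
#'
#' * `F1-1` (real reinforcement): tp = salient words learnt, fp = non-words
#'   learnt, fn = salient words produced but missed;
#' * `F1-2` (simulated reinforcement): tp = salient words produced, same fp,
#'   fn = 0 (by definition no false negatives);
#' * `F2-1`, `F2-2`: as above but false positives also include the "other"
#'   (proper but non-salient) words learnt.
#'
#' @param tp Salient words learnt (real-reinforcement true positives).
#' @param fp_nonwords Non-words learnt.
#' @param fp_other Other (proper, non-salient) words learnt.
#' @param produced Salient words produced by the learner
#'   (simulated-reinforcement true positives).
#' @param missed Salient words produced but not reinforced (includes
#'   heuristic failures); real-reinforcement false negatives.
#' @return Data frame with columns `variant`, `tp`, `fp`, `fn`, `value`
#'   (raw) and `rounded` (2 dp, half-up).
#' @export
f_report <- function(tp, fp_nonwords, fp_other, produced, missed) {
  v <- data.frame(
    variant = c("F1-1", "F1-2", "F2-1", "F2-2"),
    tp = c(tp, produced, tp, produced),
    fp = c(fp_nonwords, fp_nonwords,
           fp_nonwords + fp_other, fp_nonwords + fp_other),
    fn = c(missed, 0, missed, 0)
  )
  v$value <- f_measure(v$tp, v$fp, v$fn)
  v$rounded <- round_half_up(v$value, 2)
  v
}

#' Per-set F-measures from aggregated outcome counts
#'
#' Recomputes the four F-measure variants for each experimental set from a
#' table of aggregated reinforcement outcomes (see
#' [set_outcome_counts()] for the shipped published counts).
#'
#' @param counts Data frame with columns `set`, `produced`, `missed`,
#'   `learnt_salient`, `learnt_nonwords`, `learnt_other`.
#' @return Data frame with one row per set and variant.
#' @export
set_f_measures <- function(counts = set_outcome_counts()) {
  out <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    r <- f_report(tp = counts$learnt_salient[i],
                  fp_nonwords = counts$learnt_nonwords[i],
                  fp_other = counts$learnt_other[i],
                  produced = counts$produced[i],
                  missed = counts$missed[i])
    cbind(set = counts$set[i], r)
  }))
  rownames(out) <- NULL
  out
}

#' Published aggregated outcome counts and speech statistics
#'
#' `set_outcome_counts()` returns the per-set reinforcement tallies of the
#' published experiments (salient words produced/missed/learnt, non-words
#' and other words learnt); `participant_speech_stats()` the
#' per-participant speech and perception statistics.  Both are read from
#' plain-text files under `extdata` and serve as inputs to the evaluation
#' functions.
#'
#' @return A data frame.
#' @export
set_outcome_counts <- function() {
  path <- system.file("extdata", "set_outcome_counts.tsv",
                      package = "babblelex", mustWork = TRUE)
  utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    col.names = c("set", "participants", "produced",
                                  "missed", "heuristic_failed",
                                  "learnt_salient", "learnt_nonwords",
                                  "learnt_other"))
}

#' @rdname set_outcome_counts
#' @export
participant_speech_stats <- function() {
  path <- system.file("extdata", "participant_speech_stats.tsv",
                      package = "babblelex", mustWork = TRUE)
  utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    na.strings = "NA", stringsAsFactors = FALSE,
                    col.names = c("participant", "set", "total_words",
                                  "different_words", "syllables_perceived",
                                  "cvc_perceived", "salient_top10_spoken",
                                  "salient_top10_perceived",
                                  "salient_uttered"))
}

#' Descriptive statistics over per-participant columns
#'
#' Computes min / max / mean / SD per numeric column, skipping missing
#' values.  Columns derived from the robot's perception are conventionally
#' summarised excluding experimental sets whose perception pipeline is not
#' comparable (the filtered set); pass these via `exclude`.  Both the sample
#' (n-1) and population (n) standard deviations are reported, since summary
#' tables in the field rarely state their convention; a single observation
#' yields SD 0 and `sd_flag = TRUE`.
#'
#' @param stats_df Data frame of per-participant values, including a set
#'   column.
#' @param cols Character vector of columns to summarise (default: all
#'   numeric columns except `set`).
#' @param exclude Named list: column name -> vector of sets to exclude for
#'   that column, e.g. `list(cvc_perceived = 2)`.
#' @param set_col Name of the set column (default `"set"`).
#' @return Data frame with one row per column: `column`, `n`, `min`, `max`,
#'   `mean`, `sd_sample`, `sd_pop`, `sd_flag`.
#' @export
summarize_speech <- function(stats_df, cols = NULL, exclude = list(),
                             set_col = "set") {
  if (is.null(cols)) {
    num <- vapply(stats_df, is.numeric, logical(1))
    cols <- setdiff(names(stats_df)[num], set_col)
  }
  rows <- lapply(cols, function(cn) {
    x <- stats_df[[cn]]
    if (cn %in% names(exclude) && set_col %in% names(stats_df))
      x <- x[!(stats_df[[set_col]] %in% exclude[[cn]])]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0)
      return(data.frame(column = cn, n = 0L, min = NA_real_,
                        max = NA_real_, mean = NA_real_,
                        sd_sample = NA_real_, sd_pop = NA_real_,
                        sd_flag = TRUE))
    sd_s <- if (n > 1) stats::sd(x) else 0
    sd_p <- sqrt(sum((x - mean(x))^2) / n)
    data.frame(column = cn, n = n, min = min(x), max = max(x),
               mean = mean(x), sd_sample = sd_s, sd_pop = sd_p,
               sd_flag = n < 2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The conventional set-exclusion list for the shipped speech statistics
#'
#' The four perception-derived columns are excluded for set 2 (whose
#' filtered syllable store is not comparable to the other sets).
#'
#' @return A named list suitable for `summarize_speech(exclude = ...)`.
#' @export
speech_stats_exclusions <- function() {
  list(syllables_perceived = 2, cvc_perceived = 2,
       salient_top10_perceived = 2, salient_uttered = 2)
}

#' Evaluate a completed session
#'
#' Tallies reinforcement outcomes from a session's transcript and final
#' lexicon, and computes all four F-measure variants.  Word counting is by
#' distinct forms: `produced_salient` is the number of distinct canonical
#' salient forms that occurred as syllables of learner utterances (the
#' simulated-reinforcement true positives), `tp` the distinct salient forms
#' in the lexicon, and `fn_missed = produced_salient - tp`.  Heuristic
#' failures (an approval event whose stored syllable differs from the word
#' the teacher reports having heard) are counted from the transcript's
#' heard-word annotations.
#'
#' @param session A `babble_session` from [run_session()] or
#'   [replay_transcript()].
#' @param vocabulary The scenario [vocabulary()] used for classification
#'   (defaults to the session profile's vocabulary).
#' @return A list of class `session_eval` with `counts` (tp, fp_nonwords,
#'   fp_other, fn_missed, produced_salient, heuristic_failures) and `f` (the
#'   [f_report()] data frame).
#' @export
evaluate_session <- function(session, vocabulary = NULL) {
  if (is.null(vocabulary))
    vocabulary <- session$config$profile$vocabulary
  ev <- session$transcript
  sal <- vocabulary[vocabulary$role == "salient", ]
  # only CVC word forms are learnable (CVC-only reinforcement candidacy),
  # so the produced tally counts CVC salient forms: a CV form like
  # "b l uw" can be praised but never stored
  is_cvc <- vapply(sal$phonemes, function(p) {
    f <- parse_syllable(strsplit(p, " ")[[1L]],
                        session$config$inventory, session$config$clusters)
    !is.null(f) && f$stype == "CVC"
  }, logical(1))
  sal <- sal[is_cvc, ]
  learner <- ev[ev$speaker == "learner", ]
  produced_forms <- unique(unlist(
    strsplit(learner$phonemes, " \\| "), use.names = FALSE))
  produced_salient_forms <- intersect(sal$phonemes, produced_forms)
  cls <- classify_lexicon(session$lexicon, vocabulary)
  tp <- cls$tp
  produced <- length(produced_salient_forms)
  reinf <- ev[!is.na(ev$reinforced), ]
  heard <- reinf[!is.na(reinf$heard_word), ]
  heuristic_failures <- 0L
  if (nrow(heard)) {
    target <- sal$phonemes[match(heard$heard_word, sal$orth)]
    heuristic_failures <- sum(!is.na(target) & heard$reinforced != target)
  }
  counts <- list(tp = tp, fp_nonwords = cls$fp_nonwords,
                 fp_other = cls$fp_other,
                 fn_missed = produced - tp,
                 produced_salient = produced,
                 heuristic_failures = heuristic_failures)
  structure(list(counts = counts,
                 f = f_report(tp, cls$fp_nonwords, cls$fp_other,
                              produced, counts$fn_missed),
                 labels = cls$labels),
            class = "session_eval")
}

#' @export
print.session_eval <- function(x, ...) {
  c_ <- x$counts
  cat("<session_eval> tp=", c_$tp, " fp_nonwords=", c_$fp_nonwords,
      " fp_other=", c_$fp_other, " produced=", c_$produced_salient,
      " missed=", c_$fn_missed, " heuristic_failures=",
      c_$heuristic_failures, "\n", sep = "")
  print(x$f[c("variant", "tp", "fp", "fn", "rounded")], row.names = FALSE)
  invisible(x)
}
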