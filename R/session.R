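# Turn-taking dialogue loop between the synthetic teacher (or a scripted
# transcript) and the babbling learner, with logging, seeding and replay.

#' Configure a dialogue session
#'
#' Time is discretised into strictly alternating teacher/learner turns: one
#' teacher turn plus one learner turn per cycle.  A 4-minute block maps to
#' 30 cycles (one 4-second utterance per turn), and a session is two such
#' blocks by default.  With `carry_forward = TRUE` (the default) the
#' perception table and lexicon persist across the blocks of one session;
#' with `FALSE` they are reset at each block boundary.  Learning state is
#' never shared between sessions.
#'
#' @param n_cycles Cycles per block (default 30).
#' @param blocks Number of consecutive blocks (default 2).
#' @param syllables_per_utterance Learner syllables per babble turn
#'   (default 5).
#' @param profile A [teacher_profile()].
#' @param seed Optional integer seed; all randomness in the session flows
#'   from R's global RNG seeded once with this value.
#' @param heuristic Scoring strategy for [heuristic_select()].
#' @param lambda Decay rate if `heuristic = "exp_decay"`.
#' @param carry_forward Keep learning across blocks?
#' @param inventory,clusters Phonology configuration.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_cycles = 30L, blocks = 2L,
                           syllables_per_utterance = 5L,
                           profile = cds_profile(), seed = NULL,
                           heuristic = c("count_recency", "exp_decay"),
                           lambda = 0.1, carry_forward = TRUE,
                           inventory = cmu_phonemes(),
                           clusters = english_clusters()) {
  heuristic <- match.arg(heuristic)
  stopifnot(n_cycles >= 1, blocks >= 1, syllables_per_utterance >= 1,
            inherits(profile, "teacher_profile"))
  structure(
    list(n_cycles = as.integer(n_cycles), blocks = as.integer(blocks),
         syllables_per_utterance = as.integer(syllables_per_utterance),
         profile = profile, seed = seed, heuristic = heuristic,
         lambda = lambda, carry_forward = isTRUE(carry_forward),
         inventory = inventory, clusters = clusters),
    class = "session_config"
  )
}

# one empty transcript row set
.empty_transcript <- function() {
  data.frame(turn = integer(), speaker = character(), kind = character(),
             orthographic = character(), phonemes = character(),
             heard_word = character(), reinforced = character(),
             stringsAsFactors = FALSE)
}

.transcript_row <- function(turn, speaker, kind, orthographic, phonemes,
                            heard_word = NA_character_,
                            reinforced = NA_character_) {
  data.frame(turn = turn, speaker = speaker, kind = kind,
             orthographic = orthographic, phonemes = phonemes,
             heard_word = heard_word, reinforced = reinforced,
             stringsAsFactors = FALSE)
}

# Process one teacher turn: perceive the stream, detect approval, apply the
# heuristic to the learner's previous utterance, reinforce.  Returns the
# transcript row.
.teacher_step <- function(state, tokens, orthographic, heard_word, turn,
                          config) {
  perceive(state$table, tokens, turn, config$inventory, config$clusters)
  reinforced <- NA_character_
  kind <- "speech"
  if (!is.null(state$prev_learner) &&
      detect_approval(tokens, config$profile$approvals)) {
    kind <- "approval"
    sel <- heuristic_select(state$prev_learner, state$table, now = turn,
                            method = config$heuristic,
                            lambda = config$lambda)
    if (!is.null(sel)) {
      reinforce(state$lexicon, sel, turn, config$inventory, config$clusters)
      reinforced <- sel
    }
  }
  .transcript_row(turn, "teacher", kind, orthographic,
                  paste(tokens, collapse = " "), heard_word, reinforced)
}

#' Run a simulated teaching session
#'
#' Executes the dialogue loop: each cycle the teacher speaks (an approval of
#' the learner's previous utterance, or a fresh child-directed utterance),
#' the learner perceives the stream and - when an approval term is detected -
#' reinforces one CVC syllable of its previous utterance into the lexicon;
#' then the learner babbles.  The teacher's approval stream passes through
#' the same noisy channel as its speech, so an issued approval is not always
#' detected; approval utterances are themselves perceived into the frequency
#' tables.
#'
#' @param config A [session_config()].
#' @return An object of class `babble_session`: list with `transcript` (the
#'   event data frame; learner rows carry their syllables joined by
#'   `" | "`), `lexicon`, `table`, `config` and `eval` (the
#'   [evaluate_session()] result).
#' @export
run_session <- function(config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  profile <- config$profile
  state <- new.env(parent = emptyenv())
  state$table <- syllable_table()
  state$lexicon <- lexicon()
  state$prev_learner <- NULL
  state$topic <- NULL
  state$dwell_left <- 0L
  rows <- vector("list", 2L * config$n_cycles * config$blocks)
  turn <- 0L
  k <- 0L
  for (b in seq_len(config$blocks)) {
    if (b > 1L && !config$carry_forward) {
      state$table <- syllable_table()
      state$lexicon <- lexicon()
      state$prev_learner <- NULL
    }
    for (cycle in seq_len(config$n_cycles)) {
      turn <- turn + 1L
      approval <- if (!is.null(state$prev_learner))
        respond(state$prev_learner, profile) else NULL
      # A teacher turn always carries content speech; an approving turn
      # prepends the approval term to it ("very good and ...", as teachers
      # do), so praise never displaces the repetition of salient words.
      if (state$dwell_left <= 0L) {
        state$topic <- NULL          # fresh topic drawn by the generator
        state$dwell_left <- profile$topic_dwell
      }
      tu <- generate_teacher_utterance(profile, config$inventory,
                                       topic = state$topic)
      state$topic <- tu$topic
      state$dwell_left <- state$dwell_left - 1L
      if (!is.null(approval)) {
        tokens <- c(apply_phoneme_noise(approval$tokens, profile,
                                        config$inventory),
                    tu$tokens)
        row <- .teacher_step(state, tokens,
                             paste(c(approval$term, tu$words),
                                   collapse = " "),
                             approval$heard_word, turn, config)
      } else {
        row <- .teacher_step(state, tu$tokens,
                             paste(tu$words, collapse = " "),
                             NA_character_, turn, config)
      }
      k <- k + 1L
      rows[[k]] <- row
      turn <- turn + 1L
      u <- babble(state$table, state$lexicon, turn,
                  config$syllables_per_utterance,
                  config$inventory, config$clusters)
      state$prev_learner <- u
      k <- k + 1L
      rows[[k]] <- .transcript_row(turn, "learner", "speech",
                                   NA_character_,
                                   paste(u$syllables, collapse = " | "))
    }
  }
  out <- structure(
    list(transcript = do.call(rbind, rows[seq_len(k)]),
         lexicon = state$lexicon, table = state$table, config = config),
    class = "babble_session"
  )
  out$eval <- evaluate_session(out)
  out
}

#' @export
print.babble_session <- function(x, ...) {
  cat("<babble_session> ", nrow(x$transcript), " turns; lexicon: ",
      lexicon_size(x$lexicon), " entries\n", sep = "")
  print(x$lexicon)
  invisible(x)
}

#' Replay a scripted dialogue transcript
#'
#' Runs the identical learning loop with both sides read from a transcript
#' instead of sampled: lines starting `T:` are teacher phoneme streams
#' (optionally annotated with the word the teacher reports having heard, as
#' `T[word]:`), lines starting `D:` are learner utterances in dialogue
#' notation (see [parse_utterance()]).  Lines must strictly alternate
#' starting with a teacher turn; `#` starts a comment.  Useful for testing
#' the mechanism against recorded or constructed dialogues.
#'
#' @param path Path to a transcript file, or lines via `text`.
#' @param config A [session_config()] (profile randomness is unused; the
#'   phonology, heuristic and vocabulary configuration apply).
#' @param text Optional character vector of transcript lines.
#' @return A `babble_session` (see [run_session()]).
#' @export
replay_transcript <- function(path = NULL, config = session_config(),
                              text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  state <- new.env(parent = emptyenv())
  state$table <- syllable_table()
  state$lexicon <- lexicon()
  state$prev_learner <- NULL
  rows <- vector("list", length(lines))
  turn <- 0L
  expect_speaker <- "T"
  for (i in seq_along(lines)) {
    line <- lines[i]
    m <- regmatches(line,
                    regexec("^(T|D)(\\[([^]]*)\\])?:\\s*(.*)$", line))[[1L]]
    if (!length(m))
      stop("malformed transcript line ", i, ": '", line, "'")
    speaker <- m[2L]
    heard <- if (nzchar(m[3L])) m[4L] else NA_character_
    body <- m[5L]
    if (speaker != expect_speaker)
      stop("transcript violates turn alternation at line ", i,
           ": expected ", expect_speaker)
    turn <- turn + 1L
    if (speaker == "T") {
      tokens <- tolower(strsplit(trimws(body), "[[:space:]]+")[[1L]])
      rows[[i]] <- .teacher_step(state, tokens, NA_character_, heard, turn,
                                 config)
      expect_speaker <- "D"
    } else {
      u <- parse_utterance(body, turn, config$inventory, config$clusters)
      state$prev_learner <- u
      rows[[i]] <- .transcript_row(turn, "learner", "speech",
                                   NA_character_,
                                   paste(u$syllables, collapse = " | "))
      expect_speaker <- "T"
    }
  }
  out <- structure(
    list(transcript = if (length(lines)) do.call(rbind, rows)
         else .empty_transcript(),
         lexicon = state$lexicon, table = state$table, config = config),
    class = "babble_session"
  )
  out$eval <- evaluate_session(out)
  out
}

#' Write a session transcript in replayable dialogue format
#'
#' Teacher rows become `T:` (or `T[heard]:`) phoneme-stream lines, learner
#' rows `D:` lines in dialogue notation.  The output can be fed back to
#' [replay_transcript()], which reproduces the same perception,
#' reinforcement events and final lexicon.
#'
#' @param session A `babble_session`.
#' @param path Output file path; if `NULL`, the lines are returned.
#' @return The transcript lines, invisibly if written to a file.
#' @export
write_transcript <- function(session, path = NULL) {
  ev <- session$transcript
  lines <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (ev$speaker[i] == "teacher") {
      tag <- if (!is.na(ev$heard_word[i]))
        paste0("T[", ev$heard_word[i], "]") else "T"
      lines[i] <- paste0(tag, ": ", ev$phonemes[i])
    } else {
      u <- utterance(strsplit(ev$phonemes[i], " | ", fixed = TRUE)[[1L]],
                     turn = ev$turn[i],
                     inventory = session$config$inventory,
                     clusters = session$config$clusters)
      lines[i] <- paste0("D: ", format_utterance(u))
    }
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
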