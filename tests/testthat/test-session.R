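test_that("identical seeds give byte-identical sessions", {
  cfg <- session_config(n_cycles = 15L, blocks = 1L, seed = 99)
  s1 <- run_session(cfg)
  s2 <- run_session(cfg)
  expect_identical(s1$transcript, s2$transcript)
  expect_identical(as.data.frame(s1$lexicon), as.data.frame(s2$lexicon))
  expect_identical(write_transcript(s1), write_transcript(s2))
  s3 <- run_session(session_config(n_cycles = 15L, blocks = 1L, seed = 100))
  expect_false(identical(s1$transcript, s3$transcript))
})

test_that("turns alternate strictly and reinforcement follows approval", {
  s <- run_session(session_config(seed = 5))
  ev <- s$transcript
  expect_equal(ev$turn, seq_len(nrow(ev)))
  expect_equal(unique(ev$speaker[ev$turn %% 2 == 1]), "teacher")
  expect_equal(unique(ev$speaker[ev$turn %% 2 == 0]), "learner")
  # reinforcement happens only in approval turns, which are teacher turns
  # directly following a learner utterance
  reinf <- ev[!is.na(ev$reinforced), ]
  expect_true(all(reinf$kind == "approval"))
  expect_true(all(reinf$speaker == "teacher"))
  prev <- ev[match(reinf$turn, ev$turn) - 1L, ]
  expect_true(all(prev$speaker == "learner"))
})

test_that("the lexicon conserves exactly the successful reinforcements", {
  for (seed in c(5, 23)) {
    s <- run_session(session_config(seed = seed,
                                    profile = cds_profile(
                                      hearing_prob = 0.6,
                                      overpraise_prob = 0.3)))
    ev <- s$transcript
    reinf <- ev$reinforced[!is.na(ev$reinforced)]
    df <- as.data.frame(s$lexicon)
    expect_setequal(unique(reinf), df$form)
    expect_equal(sum(df$reinforcement_count), length(reinf))
    # first_learned_turn is the turn of each form's first event
    firsts <- vapply(df$form, function(f)
      min(ev$turn[!is.na(ev$reinforced) & ev$reinforced == f]), numeric(1))
    expect_equal(df$first_learned_turn, as.integer(firsts[df$form]))
  }
})

test_that("blocks without carry-forward restart learning", {
  cfg <- session_config(n_cycles = 10L, blocks = 2L, seed = 77,
                        carry_forward = FALSE)
  s <- run_session(cfg)
  # entries can only stem from block-2 reinforcements (turns > 20)
  df <- as.data.frame(s$lexicon)
  if (nrow(df)) expect_true(all(df$first_learned_turn > 20L))
  cfg2 <- session_config(n_cycles = 10L, blocks = 2L, seed = 77,
                         carry_forward = TRUE)
  s2 <- run_session(cfg2)
  ev2 <- s2$transcript
  expect_equal(nrow(ev2), 40L)
})

test_that("the scripted 4A dialogue replays the printed trajectory", {
  lines <- synthetic_4a_transcript()
  s <- replay_transcript(text = lines)
  reinf <- s$transcript$reinforced[!is.na(s$transcript$reinforced)]
  expect_equal(reinf, c("r eh d", "m ao d l", "r ey n", "g r iy n",
                        "k r ao s", "s ih z"))
  # first printed snapshot: ilex directly after the "well done" turn
  upto <- replay_transcript(text = lines[1:10])
  expect_equal(lexicon_words(upto$lexicon), "r eh d")
  # second printed snapshot: the five words before the final over-praise
  upto2 <- replay_transcript(text = lines[1:30])
  expect_setequal(lexicon_words(upto2$lexicon),
                  c("r eh d", "m ao d l", "r ey n", "g r iy n", "k r ao s"))
  # one further non-word by session end
  expect_setequal(lexicon_words(s$lexicon),
                  c("r eh d", "m ao d l", "r ey n", "g r iy n", "k r ao s",
                    "s ih z"))
  # the same dialogue replays identically from a file
  tmp <- tempfile(fileext = ".txt")
  writeLines(lines, tmp)
  s2 <- replay_transcript(tmp)
  expect_identical(s$transcript, s2$transcript)
})

test_that("an empty transcript yields an empty session", {
  suppressWarnings(s <- replay_transcript(text = character()))
  expect_equal(lexicon_size(s$lexicon), 0L)
  expect_equal(nrow(s$transcript), 0L)
  expect_equal(s$eval$counts$produced_salient, 0L)
  expect_error(replay_transcript(text = c("D: ah", "T: r eh d")),
               "alternation")
  expect_error(replay_transcript(text = "X: nope"), "malformed")
})

test_that("a simulated session round-trips through its transcript", {
  cfg <- session_config(n_cycles = 20L, blocks = 1L, seed = 13,
                        profile = cds_profile(hearing_prob = 0.8,
                                              overpraise_prob = 0.2))
  s <- run_session(cfg)
  lines <- write_transcript(s)
  r <- replay_transcript(text = lines, config = cfg)
  expect_equal(as.data.frame(s$lexicon), as.data.frame(r$lexicon))
  expect_equal(s$transcript$reinforced, r$transcript$reinforced)
  expect_equal(s$transcript$phonemes, r$transcript$phonemes)
  expect_equal(as.data.frame(s$table), as.data.frame(r$table))
})

test_that("an attentive focused teacher produces word learning quickly", {
  learned <- 0L
  for (seed in 1:10) {
    s <- run_session(session_config(profile = ideal_profile(), seed = seed))
    learned <- learned + (s$eval$counts$tp >= 1L)
  }
  expect_gte(learned, 9L)
})
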