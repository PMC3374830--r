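test_that("approval terms are detected as contiguous subsequences", {
  expect_true(detect_approval(c("w", "eh", "l", "d", "ah", "n")))
  # "very good and" carries "good" inside a longer stream
  expect_true(detect_approval(
    c("v", "eh", "r", "iy", "d", "g", "uh", "d", "eh", "n", "d")))
  expect_false(detect_approval(character()))
  expect_false(detect_approval(c("g", "uh")))            # partial term
  expect_false(detect_approval(c("uh", "d", "g")))       # scrambled
  expect_true(detect_approval(c("Y", "EH", "S")))        # case-normalised
  custom <- approval_set("bravo", "b r aa v ow")
  expect_true(detect_approval(c("b", "r", "aa", "v", "ow"), custom))
  expect_false(detect_approval(c("g", "uh", "d"), custom))
})

test_that("the heuristic selects the highest-scoring CVC of the utterance", {
  # the only CVC present is chosen whenever it has been heard at all
  tab <- perceive_lines(rep("r eh d", 4))
  prev <- parse_utterance("(ao k s) (ow d z) ae (r eh d) (ao s)", 8L)
  expect_equal(heuristic_select(prev, tab, now = 9), "r eh d")
  # among several CVCs at equal recency, the dominant count wins
  tab2 <- perceive_lines(c(rep("k r ao s", 16), rep("r ey n", 3),
                           rep("m ao d l", 2),
                           "k r ao s r ey n m ao d l"))
  prev2 <- parse_utterance(
    "(iy n) (r ey n) (r ey n) (m ao d l) (k r ao s)", 30L)
  expect_equal(heuristic_select(prev2, tab2, now = 31), "k r ao s")
  # no CVC syllable, or none ever heard: no selection
  expect_null(heuristic_select(parse_utterance("ae (ao s) iy", 2L), tab, 3))
  expect_null(heuristic_select(parse_utterance("(s ah n)", 2L), tab, 3))
})

test_that("the score is count over (1 + elapsed turns), unheard scoring 0", {
  expect_equal(syllable_score(4, 2), 4 / 3)
  expect_equal(syllable_score(c(1, 3), c(0, 5)), c(1, 0.5))
  expect_equal(syllable_score(5, NA), 0)
  expect_equal(syllable_score(0, 1), 0)
  expect_equal(syllable_score(4, 2, method = "exp_decay", lambda = 0.5),
               4 * exp(-1))
})

test_that("heuristic selection matches a brute-force scoring oracle", {
  set.seed(55)
  words <- c("r eh d", "s ah n", "b ih g", "m uw n", "k r ao s",
             "b aa k s", "g r iy n", "hh aa r t")
  for (rep in 1:60) {
    lines <- sample(words, 12, replace = TRUE)
    tab <- perceive_lines(lines)
    syls <- sample(c(words, "ae", "ow d z", "iy n"), 5, replace = TRUE)
    prev <- utterance(syls, turn = 20L)
    now <- 13 + sample(0:5, 1)
    expect_equal(heuristic_select(prev, tab, now),
                 oracle_select(prev, tab, now))
  }
})

test_that("raising count or recency never demotes a syllable", {
  prev <- utterance(c("s ah n", "b ih g"), turn = 10L)
  # baseline at equal recency: count 1 vs 3, b ih g wins
  tab <- syllable_table()
  for (t in 1:3) perceive(tab, c("b", "ih", "g"), t)
  perceive(tab, c("s", "ah", "n"), 3L)
  expect_equal(heuristic_select(tab = tab, prev = prev, now = 4), "b ih g")
  # raising count(s ah n) to 4 at the same recency flips the selection
  tab2 <- syllable_table()
  for (t in 1:3) perceive(tab2, c("b", "ih", "g"), t)
  for (t in c(1, 2, 3, 3)) perceive(tab2, c("s", "ah", "n"), t)
  expect_equal(heuristic_select(tab = tab2, prev = prev, now = 4), "s ah n")
  # lowering elapsed time for s ah n alone also flips it:
  # b ih g count 3 last heard turn 3, s ah n count 2 last heard turn 5,
  # so at now = 6 the scores are 3/4 vs 2/2
  tab3 <- perceive_lines(c(rep("b ih g", 3), rep("s ah n", 2)))
  expect_equal(heuristic_select(tab = tab3, prev = prev, now = 6), "s ah n")
})

test_that("score ties resolve by recency, then fuller form, then order", {
  # equal score, different recency: later-heard wins
  tab <- syllable_table()
  perceive(tab, c("s", "ah", "n"), 2L)
  perceive(tab, c("b", "ih", "g"), 4L)
  prev <- utterance(c("s ah n", "b ih g"), turn = 6L)
  # now chosen so scores tie: 1/(1+5) vs 1/(1+3) -> no tie; use counts
  tabt <- syllable_table()
  perceive(tabt, c("s", "ah", "n"), 1L)
  perceive(tabt, c("s", "ah", "n"), 4L)
  perceive(tabt, c("b", "ih", "g"), 4L)
  # at now = 5: s ah n 2/2 = 1, b ih g 1/2 = 0.5
  expect_equal(heuristic_select(prev, tabt, now = 5), "s ah n")
  # a word and its always-co-extracted shadow tie on count and recency;
  # the fuller form is preferred
  tab2 <- perceive_lines(rep("b aa k s", 5))
  expect_equal(syllable_count(tab2, "b aa k", "CVC"),
               syllable_count(tab2, "b aa k s", "CVC"))
  prev2 <- utterance(c("b aa k", "b aa k s"), turn = 8L)
  expect_equal(heuristic_select(prev2, tab2, now = 9), "b aa k s")
  # full tie on score, recency and length: lexicographic
  tab3 <- perceive_lines("s ah n b ih g")   # one stream, same turn
  prev3 <- utterance(c("s ah n", "b ih g"), turn = 3L)
  expect_equal(heuristic_select(prev3, tab3, now = 4), "b ih g")
})

test_that("reinforcement stores CVC forms, idempotent in membership", {
  lex <- lexicon()
  expect_equal(lexicon_size(lex), 0L)
  reinforce(lex, "r eh d", 9L)
  expect_equal(lexicon_words(lex), "r eh d")
  df <- as.data.frame(lex)
  expect_equal(df$first_learned_turn, 9L)
  expect_equal(df$reinforcement_count, 1L)
  reinforce(lex, "r eh d", 15L)
  df <- as.data.frame(lex)
  expect_equal(nrow(df), 1L)
  expect_equal(df$reinforcement_count, 2L)
  expect_equal(df$first_learned_turn, 9L)
  expect_error(reinforce(lex, "r eh", 3L), "CVC")
  expect_error(reinforce(lex, "ao k s", 3L), "CVC")
  tmp <- tempfile(fileext = ".tsv")
  write_lexicon(lex, tmp, gloss = c("r eh d" = "red"))
  back <- utils::read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(back$form, "r eh d")
  expect_equal(back$gloss, "red")
})
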