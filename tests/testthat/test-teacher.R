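test_that("the shipped vocabulary is well-formed", {
  voc <- default_vocabulary()
  expect_true(all(voc$weight > 0))
  expect_true(all(voc$role %in% c("salient", "other_word", "function")))
  # salient words are canonical-only; function words carry variant pools
  expect_true(all(!nzchar(voc$variants[voc$role == "salient"])))
  n_var <- lengths(strsplit(voc$variants[voc$role == "function"], "|",
                            fixed = TRUE))
  expect_true(all(n_var >= 2))
  # every canonical form and variant uses inventory symbols only
  all_forms <- c(voc$phonemes,
                 unlist(strsplit(voc$variants[nzchar(voc$variants)], "|",
                                 fixed = TRUE)))
  for (f in all_forms)
    expect_silent(classify_phoneme(strsplit(f, " ")[[1]]))
})

test_that("profile validation catches inconsistent configurations", {
  expect_error(teacher_profile(hearing_prob = 1.2), "\\[0, 1\\]")
  expect_error(teacher_profile(canonical_prob_content = 0.3,
                               canonical_prob_function = 0.8),
               "canonical_prob_content")
  # canonical probability < 1 with an empty variant pool is a config error
  voc <- vocabulary(orth = c("red", "um"),
                    phonemes = c("r eh d", "ah m"),
                    role = c("salient", "function"),
                    weight = c(2, 1), variants = c("", ""))
  expect_error(teacher_profile(vocabulary = voc,
                               canonical_prob_function = 0.5),
               "variant pool")
})

test_that("pronunciation is canonical or a variant, at the stated rate", {
  voc <- default_vocabulary()
  prof <- cds_profile()
  red <- voc[voc$orth == "red", ]
  set.seed(61)
  reds <- replicate(50, paste(pronounce(red, prof), collapse = " "))
  expect_true(all(reds == "r eh d"))   # content words canonical by default
  the <- voc[voc$orth == "the", ]
  prof50 <- cds_profile(canonical_prob_function = 0.5)
  set.seed(62)
  n <- 1e4
  outs <- replicate(n, paste(pronounce(the, prof50), collapse = " "))
  expect_true(all(outs %in% c("dh ah", "dh iy", "dh eh")))
  frac_canon <- mean(outs == "dh ah")
  expect_lt(abs(frac_canon - 0.5), 3 * sqrt(0.25 / n))
})

test_that("recognizer noise substitutes within category and deletes", {
  prof <- cds_profile(sub_rate = 1, del_rate = 0)
  set.seed(63)
  toks <- c("r", "eh", "d")
  noisy <- apply_phoneme_noise(toks, prof)
  expect_length(noisy, 3L)
  expect_equal(classify_phoneme(noisy), classify_phoneme(toks))
  expect_true(all(noisy != toks))      # substitution excludes the original
  prof_del <- cds_profile(sub_rate = 0, del_rate = 1)
  expect_length(apply_phoneme_noise(toks, prof_del), 0L)
  prof_clean <- cds_profile(sub_rate = 0, del_rate = 0)
  expect_identical(apply_phoneme_noise(toks, prof_clean), toks)
})

test_that("a degenerate one-word vocabulary yields pure repetition", {
  voc <- vocabulary("red", "r eh d", "salient", 1)
  prof <- teacher_profile(vocabulary = voc, sub_rate = 0, del_rate = 0,
                          talkover_drop = 0, words_per_utterance = 4L)
  set.seed(64)
  tu <- generate_teacher_utterance(prof)
  expect_equal(tu$words, rep("red", 4))
  expect_equal(tu$tokens, rep(c("r", "eh", "d"), 4))
  expect_equal(tu$topic, "red")
})

test_that("a noise-free channel transmits canonical forms verbatim", {
  prof <- cds_profile(sub_rate = 0, del_rate = 0, talkover_drop = 0,
                      canonical_prob_function = 1)
  voc <- prof$vocabulary
  set.seed(65)
  for (i in 1:10) {
    tu <- generate_teacher_utterance(prof)
    want <- unlist(strsplit(voc$phonemes[match(tu$words, voc$orth)], " "))
    expect_equal(tu$tokens, want)
  }
})

test_that("teacher utterances are topic-coherent with filler words", {
  prof <- cds_profile(talkover_drop = 0, words_per_utterance = 8L)
  set.seed(66)
  tu <- generate_teacher_utterance(prof, topic = "green")
  expect_equal(tu$topic, "green")
  expect_equal(sum(tu$words == "green"), 4L)   # topic_share = 0.5
  voc <- prof$vocabulary
  other <- tu$words[tu$words != "green"]
  expect_true(all(voc$role[match(other, voc$orth)] != "salient"))
})

test_that("approval behaviour follows hearing and over-praise settings", {
  u <- utterance(c("ao k s", "r eh d", "ae"), turn = 4L)
  attentive <- cds_profile(hearing_prob = 1, overpraise_prob = 0)
  set.seed(67)
  a <- respond(u, attentive)
  expect_equal(a$heard_word, "red")
  expect_true(a$term %in% default_approvals()$term)
  expect_true(detect_approval(a$tokens))
  deaf <- cds_profile(hearing_prob = 0, overpraise_prob = 0)
  for (i in 1:20) expect_null(respond(u, deaf))
  gusher <- cds_profile(hearing_prob = 0, overpraise_prob = 1)
  b <- respond(utterance(c("ae", "ow"), turn = 4L), gusher)
  expect_false(is.null(b))
  expect_true(is.na(b$heard_word))
})

test_that("perceived CVC top ranks are dominated by salient forms", {
  # an 8-minute session's worth of child-directed speech
  voc <- default_vocabulary()
  sal_forms <- voc$phonemes[voc$role == "salient"]
  for (seed in c(71, 72)) {
    set.seed(seed)
    prof <- cds_profile()
    tab <- syllable_table()
    topic <- NULL
    for (i in 1:60) {
      if (i %% prof$topic_dwell == 1L) topic <- NULL
      tu <- generate_teacher_utterance(prof, topic = topic)
      topic <- tu$topic
      perceive(tab, tu$tokens, i)
    }
    top10 <- rank_syllables(tab, "CVC")$syllable[1:10]
    expect_gte(length(intersect(top10, sal_forms)), 2L)
  }
})
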