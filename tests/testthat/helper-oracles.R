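# Shared fixtures and independent brute-force oracles.

# pseudo-phoneme inventory: letters as phonemes (a/e/o vowels)
pseudo_inventory <- function() {
  phoneme_inventory(vowels = c("a", "e", "o"),
                    consonants = c("r", "d", "b", "x", "k", "s"))
}

single_mode <- function() cluster_inventory(mode = "single")
permissive_mode <- function() cluster_inventory(mode = "permissive")

# Independent syllable oracle: try every onset/coda split directly.
oracle_parse_type <- function(tokens, inventory, clusters) {
  n <- length(tokens)
  if (n == 0L) return(NULL)
  cat <- unname(inventory$category[tolower(tokens)])
  if (anyNA(cat)) stop("unknown symbol in oracle input")
  legal <- function(seq, edge) {
    m <- length(seq)
    if (m == 0L) return(TRUE)
    if (m > clusters$max_cluster_len) return(FALSE)
    if (any(unname(inventory$category[seq]) != "consonant")) return(FALSE)
    if (m == 1L) return(TRUE)
    switch(clusters$mode,
           permissive = TRUE,
           single = FALSE,
           list = paste(seq, collapse = " ") %in% clusters[[edge]])
  }
  for (v in seq_len(n)) {
    if (cat[v] != "vowel") next
    onset <- if (v > 1L) tolower(tokens[seq_len(v - 1L)]) else character()
    coda <- if (v < n) tolower(tokens[(v + 1L):n]) else character()
    if (sum(cat == "vowel") != 1L) return(NULL)  # exactly one vowel overall
    if (legal(onset, "onsets") && legal(coda, "codas")) {
      return(paste0(if (length(onset)) "C" else "", "V",
                    if (length(coda)) "C" else ""))
    }
    return(NULL)
  }
  NULL
}

# Exhaustive-substring extraction oracle: test all O(n^2) substrings.
oracle_extract <- function(tokens, inventory, clusters) {
  n <- length(tokens)
  syl <- character(0); sty <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      form <- parse_syllable(tokens[i:j], inventory, clusters)
      if (!is.null(form)) {
        syl <- c(syl, paste(form$phonemes, collapse = " "))
        sty <- c(sty, form$stype)
      }
    }
  }
  data.frame(syllable = syl, stype = sty)
}

# multiset comparison of extraction results
expect_same_multiset <- function(a, b) {
  expect_equal(sort(paste(a$stype, a$syllable)),
               sort(paste(b$stype, b$syllable)))
}

random_stream <- function(inventory, max_len = 12L, min_len = 1L) {
  n <- sample(min_len:max_len, 1L)
  pool <- c(inventory$vowels, inventory$consonants)
  sample(pool, n, replace = TRUE)
}

# build a syllable table by perceiving whole-utterance streams
perceive_lines <- function(lines, inventory = cmu_phonemes(),
                           clusters = english_clusters()) {
  tab <- syllable_table()
  utts <- read_corpus(text = lines)
  for (i in seq_along(utts)) perceive(tab, utts[[i]], i, inventory, clusters)
  tab
}

# brute-force reimplementation of the reinforcement selection
oracle_select <- function(prev, table, now) {
  cand <- unique(prev$syllables[prev$stypes == "CVC"])
  best <- NULL; best_key <- NULL
  for (s in cand) {
    cnt <- syllable_count(table, s, "CVC")
    lh <- last_heard(table, s, "CVC")
    if (cnt <= 0 || is.na(lh)) next
    dt <- now - lh
    sc <- cnt / (1 + dt)
    key <- list(sc, -dt, length(strsplit(s, " ")[[1L]]), s)
    better <- is.null(best_key) ||
      sc > best_key[[1]] ||
      (sc == best_key[[1]] && dt < -best_key[[2]]) ||
      (sc == best_key[[1]] && dt == -best_key[[2]] &&
         key[[3]] > best_key[[3]]) ||
      (sc == best_key[[1]] && dt == -best_key[[2]] &&
         key[[3]] == best_key[[3]] && s < best_key[[4]])
    if (better) { best <- s; best_key <- key }
  }
  best
}
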