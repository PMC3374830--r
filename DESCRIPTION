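Package: babblelex
Title: Word-Form Learning from Unsegmented Phoneme Streams in Babbling
    Dialogue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A symbolic simulator of early word-form acquisition: a
    babbling learner perceives child-directed speech as unsegmented
    streams of ARPAbet phonemes, enumerates every phonotactically legal
    overlapping syllable (V, CV, VC, CVC with consonant clusters),
    tracks per-syllable frequency and recency, produces
    frequency-biased quasi-random babble, and moves CVC forms into a
    lexicon when the teacher's approval is detected, using a
    frequency/recency selection heuristic.  Includes a configurable
    synthetic teacher (Zipf-like word frequencies, variable function-word
    pronunciation, phoneme-recognizer noise, imperfect approval
    behaviour), transcript replay, and precision/recall/F-measure
    evaluation of the acquired lexicon under real and simulated
    reinforcement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
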