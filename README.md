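# babblelex

**babblelex** simulates one mechanism by which a babbling learner can
acquire its first one-syllable word forms from completely unsegmented
speech.  It is aimed at researchers in developmental cognitive science,
language acquisition modelling and developmental robotics who want a
tested, seedable, symbol-level implementation of frequency-driven word-form
learning in a teaching dialogue.

## The mechanism

A teacher talks naturally about coloured shapes; the learner receives each
utterance as a flat stream of ARPAbet phonemes with no word or syllable
boundaries.  The learner:

1. **perceives exhaustively** — every contiguous substring that is a legal
   syllable (one vowel V, flanked by onset/coda consonant clusters C of up
   to three consonants; types V, CV, VC, CVC) is counted in per-type
   frequency tables together with the turn it was last heard.  The stream
   `a r e d b o x` (letters as pseudo-phonemes) yields the ten overlapping
   syllables *a, ar, re, red, e, ed, bo, box, o, ox*;
2. **babbles with frequency bias** — five syllables per turn, each slot a
   uniform draw over the four types plus the learnt words (so 2 lexicon
   entries make 6 candidates at 1/6), the chosen type filled proportionally
   to perceived counts (counts 1, 3, 6 ⇒ probabilities 0.1, 0.3, 0.6);
3. **learns on approval** — if the teacher's reply contains an approval
   term (*well done*, *good*, ...), the CVC syllable of the previous babble
   with the highest score

   `score(s) = count(s) / (1 + Δt(s))`,  `Δt` = turns since the teacher
   last said `s`,

   is stored in the lexicon (*ilex*), from where it is babbled more often.

Evaluation classifies lexicon entries as salient words (tp), other proper
words, or non-words, and reports the four F-measures
`F = 2·tp / (2·tp + fp + fn)` used to compare **real** reinforcement
(approval-gated, missed words are false negatives) against **simulated**
reinforcement (every salient word produced counts; fn = 0).  A synthetic
teacher reproduces the statistics of child-directed speech: Zipf-like word
frequencies, topic-coherent utterances, canonical salient words vs
variably-pronounced function words, phoneme-recognizer noise, missed
approvals and over-praise.

## Worked example

```r
library(babblelex)

# exhaustive overlapping perception of "this is a red box"
tab <- syllable_table()
perceive(tab, c("dh","ih","s","ih","z","ah","r","eh","d","b","aa","k","s"),
         turn = 1)
head(rank_syllables(tab, "CVC"), 5)
#>   rank syllable count last_heard
#> 1    1   b aa k     1          1
#> 2    2 b aa k s     1          1
#> 3    3  dh ih s     1          1
#> 4    4   r eh d     1          1
#> 5    5   s ih z     1          1
```

Note `s ih z` — a non-word syllable bridging "thi**s i**s" (the sandhi
effect) — and the fragment `b aa k` inside *box*: with no segmentation
knowledge, real words must out-compete such candidates on frequency.

Replaying the package's scripted reconstruction of an effective teaching
dialogue (`(r eh d)` reinforced after "well done", `(k r ao s)` after
"very good ...", one sandhi non-word over-praised at the end):

```r
s <- replay_transcript(text = synthetic_4a_transcript())
s$lexicon
#> <lexicon> 6 entries: (g r iy n) (k r ao s) (m ao d l) (r eh d) (r ey n) (s ih z)
s$eval
#> <session_eval> tp=3 fp_nonwords=3 fp_other=0 produced=3 missed=0 heuristic_failures=0
#>  variant tp fp fn rounded
#>     F1-1  3  3  0    0.67
#>     F1-2  3  3  0    0.67
#>     F2-1  3  3  0    0.67
#>     F2-2  3  3  0    0.67
```

Three real words learnt (*red, green, cross*), three non-words — and no
gap between real and simulated reinforcement because this teacher missed
nothing.  A fully simulated 2×4-minute session with the default
(imperfect) child-directed teacher:

```r
sim <- run_session(session_config(seed = 42))
sim$lexicon
#> <lexicon> 3 entries: (hh aa r) (r eh d) (r ih ng)
sim$eval
#> <session_eval> tp=2 fp_nonwords=1 fp_other=0 produced=4 missed=2 heuristic_failures=3
#>  variant tp fp fn rounded
#>     F1-1  2  1  2    0.57
#>     F1-2  4  1  0    0.89
#>     F2-1  2  1  2    0.57
#>     F2-2  4  1  0    0.89
```

Here *red* and *ring* were learnt, *heart* was produced but its
reinforcement was diverted to its own fragment `hh aa r` — the
real/simulated gap (0.57 vs 0.89) that motivates the two scoring
conditions.  `write_transcript(sim)` emits the dialogue in a replayable
format; `rank_frequency(sim$table, "CVC")` exports the Zipf-like
rank-frequency table (`plot_rank_frequency()` plots it log-log).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/babblelex run --seed 1 --out out/
Rscript inst/cli/babblelex replay --transcript dialogue.txt --out out/
Rscript inst/cli/babblelex zipf --corpus teacher.txt --stype CVC --out rf.csv
```

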