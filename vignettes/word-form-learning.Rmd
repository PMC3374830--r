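---
title: "From babble to word forms: the model behind babblelex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From babble to word forms: the model behind babblelex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(babblelex)
```

## The learning problem

babblelex simulates one candidate mechanism for the transition from
syllabic babbling to first word forms, in the setting of a naming game: a
teacher talks naturally about coloured shapes while a learner, starting
from random syllabic babble, must end up producing and storing
single-syllable word forms such as *red* or *cross* — without any prior
knowledge of word or syllable boundaries, and without acoustic processing
(the teacher's speech arrives as a symbolic stream of ARPAbet phonemes).

Four ingredients interact:

1. **Exhaustive perception.** Every teacher utterance is scanned for *all*
   phonotactically legal syllables — every contiguous substring containing
   exactly one vowel, flanked by onset/coda consonant clusters of up to
   three consonants.  Extracted syllables overlap heavily (the pseudo-stream
   `a r e d b o x` yields *a, ar, re, red, e, ed, bo, box, o, ox*); each
   occurrence increments a per-type frequency table (types V, CV, VC, CVC)
   and stamps the dialogue turn at which the syllable was last heard.
2. **Frequency-biased production.** Each babble turn emits five syllables.
   Each slot first draws a candidate uniformly from the four syllable types
   plus the current lexicon entries (so two learnt words make six candidates
   at 1/6 each); a type draw is then filled by a frequency-proportional
   sample from that type's table (counts 1, 3, 6 give probabilities 1/10,
   3/10, 6/10), or by a uniformly random legal syllable while the table is
   still empty.
3. **Approval-gated reinforcement.** When the teacher's next turn contains
   an approval term (*well done*, *good*, *clever*, *yes*, *very good*,
   matched as contiguous phoneme subsequences), one CVC syllable of the
   learner's immediately preceding utterance is stored in the lexicon
   ("ilex").  The stored syllable is the argmax of a frequency/recency
   score (below); only CVC forms are candidates, because almost all salient
   scenario words have that shape.
4. **Evaluation.** Lexicon entries are classified against the scenario
   vocabulary as salient words (true positives), other proper words
   (*this*, *that*), or non-words, and combined with production tallies
   into four F-measures: F1/F2 differ in whether other words count as false
   positives; the `-1` variants score *real* reinforcement (learning gated
   on teacher approval, with missed words as false negatives) and the `-2`
   variants *simulated* reinforcement (every salient word the learner
   produced counts, no false negatives — an upper bound).

## The selection heuristic

The published description states the score's ingredients — frequency,
recency of teacher use, syllable type — but not its functional form.  We
adopt the simplest form consistent with them,

    score(s) = count(s) / (1 + Δt(s)),

where `Δt` is the number of turns since the teacher last uttered `s`, and
syllables never heard from the teacher score 0.  The form is a swappable
strategy (`heuristic = "exp_decay"` gives `count · exp(−λΔt)`).

Ties are broken by smaller `Δt`, then by **longer form**, then
lexicographically.  The length step matters: exhaustive extraction means a
word with a cluster edge co-occurs with a fragment of itself at *identical*
count and recency — every perceived `b aa k s` (*box*) also yields
`b aa k`.  A length-blind tie-break can therefore systematically reinforce
the fragment instead of the word being taught; preferring the fuller form
removes that artifact while staying deterministic.

Recency is measured in discrete dialogue turns (one 4-second utterance per
turn), not wall-clock time, and streams are perceived per utterance —
syllables never span turns.

## The synthetic teacher

Real teaching dialogue is replaced by a configurable generator
(`teacher_profile()`), whose defaults emulate child-directed speech (CDS)
in the shapes-and-colours scenario:

* **Zipf-like word frequencies.** The shipped vocabulary weights mimic the
  skewed profile observed in effective teaching speech (top content word
  roughly 50 tokens in ~600 words, function words *a, thats, you, and*
  among the most frequent).
* **Topic coherence.** Each utterance devotes half its word slots
  (`topic_share = 0.5`) to one salient topic word, kept for six turns
  (`topic_dwell = 6`); the remaining slots are weight-proportional draws
  from the function/other vocabulary.  This mirrors how a teacher names the
  object currently shown ("thats a red one, red, you see") and is what
  makes the heuristic's recency term informative: the word being taught is
  the recently heard one.  With order-free sampling every target would be
  equally recent in every turn and selection would collapse onto raw
  frequency.
* **Pronunciation variability.** Salient content words are realised
  canonically (`canonical_prob_content = 1`; their perceptual variability
  is carried by the noise channel), while function and other words are
  canonical only with `canonical_prob_function = 0.4`, otherwise a uniform
  draw from a per-word variant pool (*that(s)* as `dh ae`, `dh ah`,
  `dh eh`, ...).  This encodes the observation that information-bearing
  words keep consistent canonical forms while common function words depart
  from them with regularity — the frequency mass of function words is
  diluted across renderings, raising the relative rank of salient forms.
* **Recognizer noise.** Each phoneme is independently substituted within
  its category (rate 0.08) and deleted (rate 0.05).  These rates place the
  recognition probability of a 4–5 phoneme salient word near 55–60%,
  mid-range of the 45–61% recognition rates reported for the original
  recognizer; they are tunable knobs, not estimates of that recognizer.
* **Imperfect approval.** A salient word in the learner's babble is noticed
  with `hearing_prob = 0.3` (the published outcome tables show roughly two
  thirds of produced words going unreinforced); approval may also be issued
  regardless of content with `overpraise_prob = 0.1` (some teachers praised
  everything, which is how non-words get reinforced); `talkover_drop =
  0.05` of teacher words are lost to turn overlap.  An approving turn
  *prepends* the approval term to a regular content utterance ("very good
  and ..."), as real approvals do — approval never displaces teaching
  content.

`ideal_profile()` is the noise-free limit used for property testing:
canonical-only pronunciation, perfect hearing, no over-praise, no
talk-over, and a compact focus set of five CVC targets (*red, green,
cross, heart, box*) — an idealised teacher concentrates a session on a
handful of words, as the effective participants did.

A session (`run_session()`) is two blocks of 30 teacher/learner cycles
(2 × 4 minutes at 4 s per utterance), with learning carried across blocks
by default.  All randomness flows from one seed; identical configurations
replay byte-identically, and `replay_transcript()` re-runs the identical
loop from a scripted dialogue file.

## What the synthetic data does and does not show

The generator reproduces the *structure* of the published inputs — skewed
word frequencies, canonical/variable pronunciation split, noisy
perception, sparse and imperfect approval — but not recorded human speech:
no prosody, no within-category acoustic confusability structure, no
syntax, and pronunciation variants are small hand-seeded pools rather than
the dozens of renderings observed for words like *and*.  Passing tests
show the mechanism behaves as specified under these statistical
conditions; they do not show that human teachers behave like the
generator.  The shipped per-participant and per-set outcome tables are the
published counts and are used as *inputs* to the evaluation engine, whose
recomputed F-measures match the published ones at two decimals — with one
documented exception: one set's F2-1 recomputes to 0.31 from the printed
counts where the published table prints 0.32, a rounding/counting
discrepancy in the source we assert at the recomputed value.

## An irreducible real/simulated gap: heuristic diversion

One property deserves explicit statement.  It is tempting to expect that
under `ideal_profile()` the real-reinforcement tallies equal the
simulated-reinforcement ones exactly (nothing the learner produces goes
unnoticed).  The first half is true and tested: every learner utterance
containing a salient word is approved.  But equality of tallies does not
follow, because approval stores the *argmax-scoring* CVC of the utterance,
which can be a different syllable than the word the teacher heard — a
higher-count co-produced target, or a sandhi syllable.  The published
outcome table itself records such heuristic failures as a small nonzero
column even for noticed, reinforced words.  In our measurements, 38 of 50
seeded ideal sessions show exact tally coincidence, and in every deviating
session each missed word is fully accounted for by approval diversion
(it appeared in approved utterances whose reinforcement went to a
higher-scoring syllable).  The acceptance suite asserts the premise, the
real ≤ simulated ordering, and the diversion accounting, rather than a
strict zero that the mechanism does not guarantee.

## Numerical and design choices

* Phoneme symbols are case-insensitive, normalised to lower case; unknown
  symbols are errors naming the token and position; an illegal syllable is
  a rejection (`NULL`), not an error.
* Cluster legality ships as editable onset/coda lists compiled from
  standard English phonotactics (the published system cites a demi-syllable
  corpus but prints no list); `permissive` (any ≤3-consonant cluster) and
  `single` (no clusters) modes support worked examples and stress tests.
  Codas include syllabic-l sequences (`d l`, `t l`) so forms like
  `m ao d l` parse as CVC.  Clusters of more than three consonants are
  always rejected.
* Per-type tables (V/CV/VC/CVC) rather than one global table, since
  production samples within a drawn type.
* Approval utterances are themselves perceived into the tables (nothing in
  the mechanism excludes them), which is why forms like `y eh s` can enter
  the CVC ranks.
* Rank ties in frequency tables are broken lexicographically for
  reproducible exports; `f_measure(0, 0, 0)` is defined as 0 with a
  warning; published-table comparisons round half-up to two decimals while
  raw values are retained.
* Problem sizes used by the test and acceptance suites — 50–100 seeded
  replicates of 60-cycle sessions, 10^5-draw sampling checks, 1000-stream
  extraction oracles — were chosen to give comfortable statistical margins
  (3 standard errors on every empirical frequency) at interactive runtimes.

## Known limitations

* The learner never unlearns: no negative feedback, no forgetting, no decay.
* Words are learnt as forms only; no grounding or meaning is modelled.
* The published syllabifier-filter condition (one experimental set used a
  trained syllable filter) is out of scope; its training corpus and rules
  are not available.
* The evaluator counts distinct word forms, matching canonical renderings
  only; idiosyncratic-but-recognisable renderings of real words classify
  as non-words, which slightly inflates false positives relative to a
  human judge.
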