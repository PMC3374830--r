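# Code-generated synthetic fixtures: reconstructions of one effective
# participant's published interaction (here called "4A"), at the level of
# the printed anchors only.  No recorded data ships with the package.

#' Synthetic 4A-style teacher corpus
#'
#' A constructed stand-in for the speech one effective participant directed
#' at the learner, built so that exhaustive syllable extraction reproduces
#' the headline perceived-frequency anchors of that dialogue: CVC counts
#' `r eh d` = 27, `g r iy n` = 25, `k r ao s` = 17 (making `r eh d` the
#' top-ranked CVC) and CV counts `r eh` = 51, `dh ae` = 34 (making `r eh`
#' the top-ranked CV).  It is synthetic: it does not reproduce every row of
#' the published frequency table, only the asserted anchors, because
#' exhaustive extraction constrains substring counts in ways the published
#' table does not obey row-for-row.
#'
#' @return Character vector of utterance lines (one teacher utterance per
#'   line), suitable for [read_corpus()] via `text =`.
#' @export
synthetic_4a_corpus <- function() {
  c(rep("r eh d", 27),
    rep("r eh", 24),        # brings the CV prefix of "red" to 51
    rep("g r iy n", 25),
    rep("k r ao s", 17),
    rep("dh ae", 34),       # variable function-word renderings of that(s)
    rep("dh ah", 16),
    rep("dh eh", 13),
    rep("hh ah t", 10),
    rep("k ah l", 13),
    rep("b l uw", 11),
    rep("y eh s", 8))
}

#' Synthetic 4A-style dialogue transcript
#'
#' A constructed dialogue in replayable transcript format (see
#' [replay_transcript()]) reproducing the printed learning trajectory of one
#' effective participant: the learner utterance `(ao k s) (ow d z) ae
#' (r eh d) (ao s)` answered by "well done" reinforces `(r eh d)` (the first
#' lexicon snapshot); after intermediate reinforcements of `(m ao d l)`,
#' `(r ey n)` and `(g r iy n)`, the utterance `(iy n) (r ey n) (r ey n)
#' (m ao d l) (k r ao s)` answered by "very good" reinforces `(k r ao s)`,
#' the frequency/recency heuristic preferring it over the co-occurring CVC
#' syllables (the second snapshot); one sandhi non-word (`s ih z`, bridging
#' "this is") is reinforced by over-praise at the end.
#'
#' @return Character vector of transcript lines.
#' @export
synthetic_4a_transcript <- function() {
  c("# synthetic reconstruction of an effective teaching dialogue",
    "T: dh ih s ih z ah b aa k s",
    "D: ah iy ow",
    "T: ih z ih t ah r eh d w ah n",
    "D: uw eh ah",
    "T: r eh d y eh s r eh d",
    "D: ah ow iy",
    "T: l uh k ae t dh ah r eh d b aa k s",
    "D: (ao k s) (ow d z) ae (r eh d) (ao s)",
    "T[red]: w eh l d ah n",
    "D: ah ow iy",
    "T: m ao d l m ao d l",
    "D: iy (m ao d l) ah ow uw",
    "T: g uh d",
    "D: ah iy",
    "T: r ey n r ey n ah r ey n",
    "D: ow (r ey n) iy ah uw",
    "T: w eh l d ah n",
    "D: eh ow",
    "T: g r iy n g r iy n ah g r iy n",
    "D: (g r iy n) ah ow iy uw",
    "T: y eh s",
    "D: ah ow",
    "T: k r ao s k r ao s k r ao s ah k r ao s",
    "D: iy ah",
    "T: k r ao s ah k r ao s ah k r ao s",
    "D: ow uw",
    "T: k r ao s r ey n m ao d l",
    "D: (iy n) (r ey n) (r ey n) (m ao d l) (k r ao s)",
    "T: v eh r iy d g uh d eh n d",
    "D: (s ih z) ah ow iy uw",
    "T: g uh d")
}
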