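# Phoneme inventory, vowel/consonant classification and phonotactic
# legality of (C)V(C) syllables, where "C" is a cluster of 1-3 consonants.

#' Construct a phoneme inventory
#'
#' An inventory maps phoneme symbols (short lower-case tokens such as `"aa"`
#' or `"k"`) to their category, vowel or consonant.  The default inventory
#' used throughout the package is the 39-symbol CMU/ARPAbet set, see
#' [cmu_phonemes()].
#'
#' @param vowels Character vector of vowel symbols (monophthongs and
#'   diphthongs).
#' @param consonants Character vector of consonant symbols.
#' @return An object of class `phoneme_inventory`.
#' @seealso [classify_phoneme()], [read_phoneme_inventory()]
#' @export
#' @examples
#' inv <- phoneme_inventory(vowels = c("a", "e", "o"),
#'                          consonants = c("r", "d", "b", "x"))
#' classify_phoneme("a", inv)
phoneme_inventory <- function(vowels, consonants) {
  vowels <- tolower(as.character(vowels))
  consonants <- tolower(as.character(consonants))
  if (anyDuplicated(c(vowels, consonants)))
    stop("phoneme symbols must be unique across categories")
  category <- c(
    stats::setNames(rep("vowel", length(vowels)), vowels),
    stats::setNames(rep("consonant", length(consonants)), consonants)
  )
  structure(
    list(vowels = vowels, consonants = consonants, category = category),
    class = "phoneme_inventory"
  )
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat("<phoneme_inventory> ", length(x$vowels), " vowels, ",
      length(x$consonants), " consonants\n", sep = "")
  invisible(x)
}

#' Read a phoneme inventory from a two-column text file
#'
#' The file has one `symbol<TAB>category` pair per line, category one of
#' `vowel`/`consonant`; `#` starts a comment.
#'
#' @param path Path to the inventory file.
#' @return A `phoneme_inventory`.
#' @export
read_phoneme_inventory <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("symbol", "category"))
  bad <- setdiff(unique(tab$category), c("vowel", "consonant"))
  if (length(bad))
    stop("unknown phoneme category in ", path, ": ",
         paste(bad, collapse = ", "))
  phoneme_inventory(vowels = tab$symbol[tab$category == "vowel"],
                    consonants = tab$symbol[tab$category == "consonant"])
}

# package-level cache for the shipped defaults
.babblelex_cache <- new.env(parent = emptyenv())

#' The 39-symbol CMU/ARPAbet phoneme inventory
#'
#' 15 vowels (including diphthongs): aa ae ah ao aw ay eh er ey ih iy ow oy
#' uh uw; the remaining 24 symbols are consonants.
#'
#' @return A `phoneme_inventory`.
#' @export
cmu_phonemes <- function() {
  if (is.null(.babblelex_cache$cmu)) {
    path <- system.file("extdata", "cmu_phonemes.tsv", package = "babblelex",
                        mustWork = TRUE)
    .babblelex_cache$cmu <- read_phoneme_inventory(path)
  }
  .babblelex_cache$cmu
}

#' Classify phoneme symbols as vowel or consonant
#'
#' Symbols are case-insensitive and normalised to lower case.  Unknown
#' symbols are an error identifying the offending token and its position.
#'
#' @param symbols Character vector of phoneme symbols.
#' @param inventory A [phoneme_inventory()]; defaults to [cmu_phonemes()].
#' @return Character vector of `"vowel"`/`"consonant"`, same length as
#'   `symbols`.
#' @export
#' @examples
#' classify_phoneme(c("aa", "k"))
classify_phoneme <- function(symbols, inventory = cmu_phonemes()) {
  symbols <- tolower(symbols)
  out <- unname(inventory$category[symbols])
  if (anyNA(out)) {
    i <- which(is.na(out))[1L]
    stop("unknown phoneme symbol '", symbols[i], "' at position ", i,
         call. = FALSE)
  }
  out
}

# validate + normalise a token vector; returns lower-cased tokens
.check_tokens <- function(tokens, inventory) {
  tokens <- tolower(tokens)
  known <- tokens %in% names(inventory$category)
  if (!all(known)) {
    i <- which(!known)[1L]
    stop("unknown phoneme symbol '", tokens[i], "' at position ", i,
         call. = FALSE)
  }
  tokens
}

#' Construct a consonant-cluster inventory
#'
#' Defines which consonant sequences are legal syllable-initially (onsets)
#' and syllable-finally (codas).  Every single consonant is always legal at
#' either edge; the lists supply the multi-consonant clusters.  Three modes
#' are supported:
#'
#' * `"list"`: a cluster of length > 1 is legal iff it is in the supplied
#'   list (the shipped English lists, see [english_clusters()]);
#' * `"permissive"`: any consonant sequence up to `max_cluster_len` is legal;
#' * `"single"`: only single consonants are legal (no clusters).
#'
#' Clusters longer than `max_cluster_len` (default 3, as in *glimpsed*) are
#' always rejected.
#'
#' @param onsets,codas Character vectors of space-separated consonant
#'   sequences (e.g. `"s k w"`); ignored unless `mode = "list"`.
#' @param mode One of `"list"`, `"permissive"`, `"single"`.
#' @param max_cluster_len Maximum cluster length (default 3).
#' @return An object of class `cluster_inventory`.
#' @export
cluster_inventory <- function(onsets = character(), codas = character(),
                              mode = c("list", "permissive", "single"),
                              max_cluster_len = 3L) {
  mode <- match.arg(mode)
  norm <- function(x) {
    x <- tolower(trimws(x))
    x <- x[nzchar(x)]
    n_c <- lengths(strsplit(x, " +"))
    if (any(n_c > max_cluster_len))
      stop("cluster longer than max_cluster_len: ",
           x[which(n_c > max_cluster_len)[1L]])
    gsub(" +", " ", x)
  }
  structure(
    list(mode = mode, max_cluster_len = as.integer(max_cluster_len),
         onsets = norm(onsets), codas = norm(codas)),
    class = "cluster_inventory"
  )
}

#' @export
print.cluster_inventory <- function(x, ...) {
  cat("<cluster_inventory> mode=", x$mode,
      ", max_cluster_len=", x$max_cluster_len, sep = "")
  if (x$mode == "list")
    cat(", ", length(x$onsets), " onsets, ", length(x$codas), " codas",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Read a cluster inventory from a sectioned text file
#'
#' One cluster per line (space-separated consonants) under `[onset]` and
#' `[coda]` section headers; `#` starts a comment.
#'
#' @param path Path to the cluster file.
#' @param max_cluster_len Maximum cluster length (default 3).
#' @return A `cluster_inventory` in `"list"` mode.
#' @export
read_cluster_inventory <- function(path, max_cluster_len = 3L) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- cumsum(lines %in% c("[onset]", "[coda]"))
  header <- lines[lines %in% c("[onset]", "[coda]")]
  if (!length(header)) stop("no [onset]/[coda] sections in ", path)
  body <- split(lines[!lines %in% c("[onset]", "[coda]")],
                header[section[!lines %in% c("[onset]", "[coda]")]])
  cluster_inventory(onsets = body[["[onset]"]], codas = body[["[coda]"]],
                    mode = "list", max_cluster_len = max_cluster_len)
}

#' The shipped English onset/coda cluster lists
#'
#' An implementer-compiled approximation of standard English phonotactics
#' (editable: see `system.file("extdata", "clusters_english.txt", package =
#' "babblelex")`).
#'
#' @return A `cluster_inventory` in `"list"` mode.
#' @export
english_clusters <- function() {
  if (is.null(.babblelex_cache$clusters_en)) {
    path <- system.file("extdata", "clusters_english.txt",
                        package = "babblelex", mustWork = TRUE)
    .babblelex_cache$clusters_en <- read_cluster_inventory(path)
  }
  .babblelex_cache$clusters_en
}

# edge = "onsets" or "codas"
.cluster_legal <- function(clusters, tokens, edge) {
  n <- length(tokens)
  if (n == 0L) return(TRUE)
  if (n > clusters$max_cluster_len) return(FALSE)
  if (n == 1L) return(TRUE)
  switch(clusters$mode,
         permissive = TRUE,
         single = FALSE,
         list = paste(tokens, collapse = " ") %in% clusters[[edge]])
}

#' Is a consonant sequence a legal onset (or coda)?
#'
#' @param clusters A [cluster_inventory()].
#' @param tokens Character vector of consonant symbols (possibly empty).
#' @return Logical scalar.
#' @export
is_legal_onset <- function(clusters, tokens)
  .cluster_legal(clusters, tokens, "onsets")

#' @rdname is_legal_onset
#' @export
is_legal_coda <- function(clusters, tokens)
  .cluster_legal(clusters, tokens, "codas")

#' Parse a phoneme sequence as a single syllable
#'
#' Accepts the sequence iff it matches onset? + vowel + coda? with a legal
#' onset and coda cluster: exactly one vowel, flanked by 0-3 consonants on
#' each side.  The syllable type tag is determined by which flanks are
#' non-empty: `V`, `CV`, `VC` or `CVC` (where `C` denotes a cluster of 1-3
#' consonants).
#'
#' @param phonemes Character vector of phoneme symbols.
#' @param inventory A [phoneme_inventory()].
#' @param clusters A [cluster_inventory()].
#' @return A `syllable_form` (list with elements `phonemes`, `stype`,
#'   `onset`, `nucleus`, `coda`), or `NULL` if the sequence is not a legal
#'   syllable (rejection, not an error).  Unknown symbols are an error.
#' @export
#' @examples
#' parse_syllable(c("s", "k", "w", "eh", "r"))$stype   # "CVC"
#' parse_syllable(c("k", "s"))                         # NULL: no vowel
parse_syllable <- function(phonemes, inventory = cmu_phonemes(),
                           clusters = english_clusters()) {
  tokens <- .check_tokens(phonemes, inventory)
  cat <- unname(inventory$category[tokens])
  v <- which(cat == "vowel")
  if (length(v) != 1L) return(NULL)
  n <- length(tokens)
  onset <- if (v > 1L) tokens[seq_len(v - 1L)] else character()
  coda <- if (v < n) tokens[(v + 1L):n] else character()
  if (!is_legal_onset(clusters, onset)) return(NULL)
  if (!is_legal_coda(clusters, coda)) return(NULL)
  stype <- paste0(if (length(onset)) "C" else "", "V",
                  if (length(coda)) "C" else "")
  structure(list(phonemes = tokens, stype = stype, onset = onset,
                 nucleus = tokens[v], coda = coda),
            class = "syllable_form")
}

#' @export
print.syllable_form <- function(x, ...) {
  cat("<syllable_form> (", paste(x$phonemes, collapse = " "), ") ",
      x$stype, "\n", sep = "")
  invisible(x)
}
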