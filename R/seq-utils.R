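# IUPAC nucleotide classes. A genome/input 'N' deliberately matches *no*
# class (not even pattern N): Ns mark variant positions and must never be
# called as part of a guide, PAM or off-target site.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_set <- function(code) {
  s <- IUPAC_SETS[[code]]
  if (is.null(s)) {
    abort(sprintf("unknown IUPAC code '%s'", code), class = "guidecraft_config_error")
  }
  s
}

#' Reverse complement of DNA strings
#'
#' Vectorised; handles IUPAC ambiguity codes (R<->Y, B<->V, D<->H, ...) and
#' leaves N as N.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                               "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x))
}

#' GC content of DNA strings, in percent
#'
#' @param x Character vector of DNA strings.
#' @return Numeric vector of GC percentages in \[0, 100\].
#' @export
gc_percent <- function(x) {
  100 * stringr::str_count(x, "[GCgc]") / nchar(x)
}

#' Match a fixed-length IUPAC pattern against DNA strings
#'
#' Each pattern position must admit the corresponding sequence base. An `N`
#' base in the *sequence* matches no pattern class (including pattern `N`):
#' masked/ambiguous genome positions are never called as PAM or site bases.
#'
#' @param pattern Single IUPAC pattern, e.g. `"NGG"`, `"NNGRRT"`, `"TTTV"`.
#' @param seq Character vector of sequences, each the same length as `pattern`.
#' @return Logical vector, one element per sequence.
#' @export
#' @examples
#' iupac_match("NGG", c("AGG", "ATG"))
iupac_match <- function(pattern, seq) {
  pl <- nchar(pattern)
  if (any(nchar(seq) != pl)) {
    abort("iupac_match: all sequences must have the pattern's length",
          class = "guidecraft_usage_error")
  }
  pat <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, length(seq))
  for (k in seq_len(pl)) {
    ok <- ok & substr(seq, k, k) %in% iupac_set(pat[k])
  }
  ok
}

# regex character class for one IUPAC code; excludes N in the subject by
# construction (N is not a member of any class)
iupac_regex <- function(pattern) {
  pat <- strsplit(pattern, "")[[1]]
  paste0(vapply(pat, function(p) {
    paste0("[", paste0(iupac_set(p), collapse = ""), "]")
  }, character(1)), collapse = "")
}

# 0-based start positions where `pattern` matches within the character
# vector `sv` (one element per base); vectorised sliding conjunction
match_positions0 <- function(sv, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  pl <- length(pat)
  n <- length(sv) - pl + 1L
  if (n < 1L) return(integer(0))
  ok <- rep(TRUE, n)
  for (k in seq_len(pl)) {
    ok <- ok & sv[k:(k + n - 1L)] %in% iupac_set(pat[k])
  }
  which(ok) - 1L
}

# split one string into a character vector of single bases
seq_chars <- function(s) strsplit(s, "")[[1]]

assert_dna <- function(x, what = "sequence", allow = "ACGTN") {
  bad <- stringr::str_detect(x, paste0("[^", allow, "]"))
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {%s}", what,
                  paste(seq_chars(allow), collapse = ",")),
          class = "guidecraft_usage_error")
  }
  invisible(x)
}
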