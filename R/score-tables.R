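#' Off-target score tables
#'
#' The MIT hit score uses a 20-long vector of position weights (position 1 =
#' PAM-distal, 20 = PAM-proximal). The CFD score uses per-position,
#' per-substitution mismatch penalties and a PAM-class penalty, all in
#' \[0, 1\]. `read_score_tables()` loads the three TSV dialects documented
#' below; `default_score_tables()` loads and caches the tables shipped with
#' the package. The shipped MIT weight vector is the standard published one;
#' the shipped CFD tables are *synthetic* defaults (smooth positional decay
#' toward the PAM times a transition/transversion factor) — drop in
#' experimentally derived tables with the same file layout to reproduce
#' published CFD values.
#'
#' File dialects (tab-separated, `#` comments allowed):
#' * mit weights: columns `position`, `weight`.
#' * cfd mismatch: columns `position`, `guide_base`, `off_base`, `penalty`
#'   (position 1 = PAM-distal; identity rows, penalty 1, may be present but
#'   are never looked up).
#' * cfd pam: columns `pam` (IUPAC pattern), `penalty`; matched in file
#'   order against an observed PAM of the same length.
#'
#' @param mit_path,cfd_mm_path,cfd_pam_path Paths to the three TSV tables.
#' @return A `score_tables` list with `mit_weights`, `cfd_mm` (tibble),
#'   `cfd_pam` (tibble) and an internal lookup key.
#' @export
read_score_tables <- function(mit_path, cfd_mm_path, cfd_pam_path) {
  rd <- function(p) readr::read_tsv(p, comment = "#", show_col_types = FALSE,
                                    progress = FALSE)
  mit <- rd(mit_path)
  stopifnot(all(c("position", "weight") %in% names(mit)))
  mit <- dplyr::arrange(mit, .data$position)
  w <- mit$weight
  if (any(w < 0 | w > 1)) {
    abort("MIT weights must lie in [0,1]", class = "guidecraft_config_error")
  }
  mm <- rd(cfd_mm_path)
  stopifnot(all(c("position", "guide_base", "off_base", "penalty") %in% names(mm)))
  pam <- rd(cfd_pam_path)
  stopifnot(all(c("pam", "penalty") %in% names(pam)))
  if (any(mm$penalty < 0 | mm$penalty > 1) || any(pam$penalty < 0 | pam$penalty > 1)) {
    abort("CFD penalties must lie in [0,1]", class = "guidecraft_config_error")
  }
  new_score_tables(w, mm, pam)
}

new_score_tables <- function(mit_weights, cfd_mm, cfd_pam) {
  key <- stats::setNames(cfd_mm$penalty,
                         paste(cfd_mm$position, cfd_mm$guide_base,
                               cfd_mm$off_base, sep = "|"))
  structure(list(mit_weights = mit_weights, cfd_mm = cfd_mm,
                 cfd_pam = cfd_pam, cfd_mm_key = key),
            class = "score_tables")
}

#' @rdname read_score_tables
#' @export
default_score_tables <- function() {
  if (is.null(the$score_tables)) {
    ext <- function(f) system.file("extdata", f, package = "guidecraft",
                                   mustWork = TRUE)
    the$score_tables <- read_score_tables(ext("mit_weights.tsv"),
                                          ext("cfd_mm_synthetic.tsv"),
                                          ext("cfd_pam_synthetic.tsv"))
  }
  the$score_tables
}

#' Uniform score tables for testing and sensitivity checks
#'
#' Every MIT weight equals `mit_weight`, every CFD mismatch penalty equals
#' `mm_penalty`, canonical PAM patterns get penalty 1 and all alternative
#' PAMs `alt_pam_penalty`.
#'
#' @param mit_weight,mm_penalty,alt_pam_penalty Scalar values in \[0, 1\].
#' @param guide_len Longest guide length to cover.
#' @return A `score_tables` object.
#' @export
uniform_score_tables <- function(mit_weight = 0.5, mm_penalty = 0.5,
                                 alt_pam_penalty = 0.5, guide_len = 23L) {
  bases <- c("A", "C", "G", "T")
  grid <- tidyr::expand_grid(position = seq_len(guide_len),
                             guide_base = bases, off_base = bases)
  grid$penalty <- ifelse(grid$guide_base == grid$off_base, 1, mm_penalty)
  pam <- tibble(pam = c("NGG", "NNGRRT", "TTTV", "NAG", "NGA"),
                penalty = c(1, 1, 1, alt_pam_penalty, alt_pam_penalty))
  new_score_tables(rep(mit_weight, 20L), grid, pam)
}

cfd_pam_penalty <- function(pam_seq, tables) {
  cand <- tables$cfd_pam[nchar(tables$cfd_pam$pam) == nchar(pam_seq), ]
  for (i in seq_len(nrow(cand))) {
    if (iupac_match(cand$pam[i], pam_seq)) return(cand$penalty[i])
  }
  abort(sprintf("no CFD PAM penalty entry matches PAM '%s'", pam_seq),
        class = "guidecraft_config_error")
}

# MIT weight for a PAM-distal position p of a guide of length g: the
# 20-vector is aligned at the PAM-proximal end; positions extending further
# PAM-distal than the table get weight 0 (distal mismatches well tolerated)
mit_weight_at <- function(p, guide_len, weights) {
  idx <- length(weights) - (guide_len - p)
  ifelse(idx >= 1 & idx <= length(weights), weights[pmax(idx, 1L)], 0)
}

# 1-based mismatch positions counted from the PAM-distal end
mismatch_positions_distal <- function(guide_seq, site_seq, pam_side) {
  g <- nchar(guide_seq)
  idx <- which(seq_chars(guide_seq) != seq_chars(site_seq))
  if (pam_side == "3p") sort(idx) else sort(g + 1L - idx)
}

#' MIT per-hit off-target score
#'
#' Penalty score in \[0, 100\] for one off-target site: the product of
#' `(1 - W[p])` over mismatched positions, damped by the mean pairwise
#' distance between mismatches and by `1/m^2`. 100 means a perfect match;
#' close-together, PAM-proximal mismatches give low scores (unlikely
#' cleavage).
#'
#' @param guide_seq,site_seq Equal-length protospacer sequences, 5'->3' with
#'   position 1 PAM-distal.
#' @param tables A `score_tables` object.
#' @return Numeric score in \[0, 100\].
#' @export
#' @examples
#' mit_hit_score("GACGTACGTACGTACGTACG", "GACGTACGTACGTACGTACG",
#'               uniform_score_tables())
mit_hit_score <- function(guide_seq, site_seq, tables = default_score_tables()) {
  if (nchar(guide_seq) != nchar(site_seq)) {
    abort("mit_hit_score: sequences must have equal length",
          class = "guidecraft_usage_error")
  }
  pos <- which(seq_chars(guide_seq) != seq_chars(site_seq))
  m <- length(pos)
  if (m == 0) return(100)
  w <- mit_weight_at(pos, nchar(guide_seq), tables$mit_weights)
  score <- 100 * prod(1 - w)
  if (m >= 2) {
    dbar <- mean(stats::dist(pos))
    score <- score * (1 / (((19 - dbar) / 19) * 4 + 1)) * (1 / m^2)
  }
  score
}

#' CFD (cutting frequency determination) off-target score
#'
#' Product of the per-position mismatch penalties and the PAM-class penalty,
#' in \[0, 1\]. Exactly 1 iff the site matches the guide perfectly and
#' carries a canonical PAM.
#'
#' @inheritParams mit_hit_score
#' @param pam_seq The site's observed PAM sequence.
#' @param pam_side `"3p"` or `"5p"`: which side of the protospacer the PAM
#'   sits on (fixes the PAM-distal position numbering).
#' @return Numeric score in \[0, 1\].
#' @export
cfd_score <- function(guide_seq, site_seq, pam_seq,
                      tables = default_score_tables(), pam_side = "3p") {
  if (nchar(guide_seq) != nchar(site_seq)) {
    abort("cfd_score: sequences must have equal length",
          class = "guidecraft_usage_error")
  }
  idx <- which(seq_chars(guide_seq) != seq_chars(site_seq))
  pen <- 1
  if (length(idx) > 0) {
    g <- nchar(guide_seq)
    pos <- if (pam_side == "3p") idx else g + 1L - idx
    keys <- paste(pos, substring(guide_seq, idx, idx),
                  substring(site_seq, idx, idx), sep = "|")
    vals <- tables$cfd_mm_key[keys]
    if (anyNA(vals)) {
      abort(sprintf("missing CFD mismatch table entry for key (%s)",
                    keys[which(is.na(vals))[1]]),
            class = "guidecraft_config_error")
    }
    pen <- prod(vals)
  }
  pen * cfd_pam_penalty(pam_seq, tables)
}

#' Aggregate guide specificity score
#'
#' `100 * 100 / (100 + sum(mit_hit))` over all off-target hits, excluding
#' the on-target site itself. 100 means no off-targets; every added hit
#' strictly lowers the score.
#'
#' @param hits Either a numeric vector of per-hit MIT scores or an
#'   off-target tibble from [find_offtargets()] (rows with
#'   `is_on_target == TRUE` are excluded).
#' @return Numeric score in \[0, 100\].
#' @export
specificity_score <- function(hits) {
  if (is.data.frame(hits)) {
    hits <- hits$mit_hit[!hits$is_on_target]
  }
  100 * 100 / (100 + sum(hits))
}

#' Traffic-light class for a specificity score
#'
#' @param spec_score Numeric vector of scores in \[0, 100\].
#' @param high Scores `>= high` are `"green"` (recommended).
#' @param low Scores `< low` are `"red"` (avoid); the boundary value itself
#'   is `"yellow"`.
#' @return Character vector in `{green, yellow, red}`.
#' @export
color_class <- function(spec_score, high = 50, low = 30) {
  dplyr::case_when(spec_score >= high ~ "green",
                   spec_score < low ~ "red",
                   TRUE ~ "yellow")
}

#' Mismatch-count histogram string
#'
#' Counts hits (excluding the on-target) with 0, 1, ..., `max_mm`
#' mismatches, formatted `"c0-c1-...-cK"`.
#'
#' @param hits Off-target tibble from [find_offtargets()].
#' @param max_mm Largest mismatch count in the histogram.
#' @return A single string.
#' @export
mismatch_histogram <- function(hits, max_mm = 4L) {
  mm <- hits$mismatches[!hits$is_on_target]
  paste(vapply(0:max_mm, function(k) sum(mm == k), integer(1)), collapse = "-")
}
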