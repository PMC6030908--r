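#' Find microhomology patterns around a cut site
#'
#' A microhomology pattern is a pair of identical substrings (length >=
#' `min_len`) with the left copy ending at or before the cut and the right
#' copy starting at or after it, both within `window` bases of the cut.
#' Such a pair can template a deletion of `right_start - left_start` bases
#' by microhomology-mediated end joining. Patterns whose (sequence,
#' deletion length) are contained in a longer reported pattern with the same
#' deletion are suppressed as redundant sub-patterns.
#'
#' The cut sits between context offsets `cut - 1` and `cut` (0-based), i.e.
#' bases with offset `< cut` are left of the cut.
#'
#' @param context DNA string around the cut (plus strand).
#' @param cut 0-based offset of the first base right of the cut.
#' @param window Bases considered on each side of the cut (default 30),
#'   truncated at the context bounds.
#' @param min_len Minimum microhomology length (default 2).
#' @return Tibble with columns `left_start`, `right_start` (0-based offsets
#'   in `context`), `length`, `deletion_len`, `mh_seq`, sorted by
#'   `deletion_len`, `left_start`.
#' @export
#' @examples
#' find_microhomologies("AAGATCCTTTGATCAA", cut = 8)
find_microhomologies <- function(context, cut, window = 30L, min_len = 2L) {
  L <- nchar(context)
  if (cut < 0 || cut > L) {
    abort("cut must lie within the context", class = "guidecraft_usage_error")
  }
  lo <- max(0L, cut - window)
  hi <- min(L, cut + window)
  left <- substr(context, lo + 1L, cut)      # offsets [lo, cut)
  right <- substr(context, cut + 1L, hi)     # offsets [cut, hi)
  nl <- nchar(left); nr <- nchar(right)
  res <- list()
  for (len in seq.int(min_len, max(min_len, min(nl, nr)))) {
    if (len > nl || len > nr) break
    # all length-len substrings of each side
    ls <- substring(left, 1:(nl - len + 1L), len:nl)
    rs <- substring(right, 1:(nr - len + 1L), len:nr)
    hit <- outer(ls, rs, `==`)
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      res[[length(res) + 1L]] <- tibble(
        left_start = lo + idx[, 1L] - 1L,
        right_start = cut + idx[, 2L] - 1L,
        length = len,
        mh_seq = ls[idx[, 1L]]
      )
    }
  }
  if (length(res) == 0) {
    return(tibble(left_start = integer(), right_start = integer(),
                  length = integer(), deletion_len = integer(),
                  mh_seq = character()))
  }
  pat <- bind_rows(res) |>
    mutate(deletion_len = .data$right_start - .data$left_start) |>
    filter(.data$deletion_len > 0)
  # collapse identical (mh_seq, deletion_len) at shifted offsets to the
  # leftmost, then drop sub-patterns contained in a longer pattern with the
  # same deletion length
  pat <- pat |>
    group_by(.data$mh_seq, .data$deletion_len) |>
    arrange(.data$left_start, .by_group = TRUE) |>
    slice_head(n = 1L) |>
    ungroup()
  keep <- map_lgl(seq_len(nrow(pat)), function(i) {
    j <- which(pat$deletion_len == pat$deletion_len[i] &
                 pat$length > pat$length[i])
    !any(stringr::str_detect(pat$mh_seq[j], stringr::fixed(pat$mh_seq[i])))
  })
  pat[keep, c("left_start", "right_start", "length", "deletion_len", "mh_seq")] |>
    arrange(.data$deletion_len, .data$left_start)
}

mh_pattern_score <- function(deletion_len, mh_seq) {
  gc <- stringr::str_count(mh_seq, "[GC]")
  at <- nchar(mh_seq) - gc
  100 * round(exp(-deletion_len / 20), 3) * (2 * gc + at)
}

#' Microhomology out-of-frame score
#'
#' Each pattern from [find_microhomologies()] gets a weight
#' `100 * round(exp(-deletion_len/20), 3) * (2*GC + AT)` — longer deletions
#' decay exponentially, GC-paired microhomologies count double. The
#' out-of-frame score is 100 times the weight fraction carried by patterns
#' whose deletion length is not a multiple of 3, i.e. the predicted share
#' of MMEJ deletions that shift the reading frame (favouring knockouts).
#' With no patterns at all the score is unavailable (`NA`).
#'
#' @inheritParams find_microhomologies
#' @return Numeric score in \[0, 100\], or `NA` when no pattern exists.
#' @export
out_of_frame_score <- function(context, cut, window = 30L, min_len = 2L) {
  pat <- find_microhomologies(context, cut, window, min_len)
  if (nrow(pat) == 0) return(NA_real_)
  s <- mh_pattern_score(pat$deletion_len, pat$mh_seq)
  tot <- sum(s)
  if (tot == 0) return(NA_real_)
  100 * sum(s[pat$deletion_len %% 3 != 0]) / tot
}

#' Out-of-frame scores for a guide table
#'
#' @param guides Guide tibble from [scan_guides()] (uses `context`; the cut
#'   sits at the context midpoint).
#' @param window,min_len Passed to [out_of_frame_score()].
#' @return `guides` with an `oof_score` column (NA when context is
#'   unavailable or repeat-free).
#' @export
oof_score_guides <- function(guides, window = 30L, min_len = 2L) {
  guides$oof_score <- map_dbl(guides$context, function(ctx) {
    if (is.na(ctx)) return(NA_real_)
    out_of_frame_score(ctx, nchar(ctx) %/% 2L, window, min_len)
  })
  guides
}
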