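#' Select guides for a saturating-mutagenesis pool
#'
#' Keeps every scored guide meeting the minimal criteria — specificity and
#' efficiency at or above the thresholds, and no overlap with N-masked
#' variant positions — ordered by position along the input. The maximum gap
#' between adjacent retained cut sites is attached as attribute
#' `max_cut_gap` (NA with fewer than two guides) so coverage of the tiled
#' region can be judged.
#'
#' @param guides Guide tibble carrying `spec_score` and `eff_score` columns
#'   (see [design_guides()]).
#' @param min_spec,min_eff Minimal scores in \[0, 100\].
#' @return Filtered tibble ordered by `start`, with attribute
#'   `max_cut_gap`; empty selections produce a warning.
#' @export
saturating_selection <- function(guides, min_spec = 0, min_eff = 0) {
  sel <- guides |>
    filter(.data$spec_score >= min_spec,
           !is.na(.data$eff_score) & .data$eff_score >= min_eff,
           !stringr::str_detect(.data$flags, "OVERLAPS_N")) |>
    arrange(.data$start)
  if (nrow(sel) == 0) {
    warning("no guide passes the saturating-mutagenesis criteria", call. = FALSE)
  }
  gap <- if (nrow(sel) >= 2) max(diff(sort(sel$cut))) else NA_integer_
  attr(sel, "max_cut_gap") <- gap
  sel
}

check_subpools <- function(subpools) {
  stopifnot(all(c("id", "fwd_barcode", "rev_barcode") %in% names(subpools)))
  bcs <- c(subpools$fwd_barcode, subpools$rev_barcode)
  if (anyDuplicated(bcs)) {
    abort(sprintf("duplicate subpool barcode '%s'", bcs[duplicated(bcs)][1]),
          class = "guidecraft_config_error")
  }
  if (any(nchar(bcs) < 6)) {
    abort("subpool barcodes must be at least 6 bases",
          class = "guidecraft_config_error")
  }
  invisible(subpools)
}

#' Assemble a barcoded synthesis-oligo pool
#'
#' Each guide becomes one synthesis oligo:
#' `fwd_barcode + left_adapter + insert + right_adapter + revcomp(rev_barcode)`
#' where the insert is the protospacer after the expression profile's
#' 5'-prefix rule (same rule as cloning, default `bbsI_U6`'s
#' `add_G_if_absent`) and the barcodes are the guide's subpool's PCR-primer
#' landing sites (the reverse barcode is appended as the reverse complement
#' of the subpool's reverse primer, so each subpool amplifies with its own
#' primer pair). The layout is fixed so that oligos decode uniquely back to
#' (subpool, guide) — see [decode_pool()].
#'
#' @param guides Guide tibble (needs `guide_id`, `protospacer`).
#' @param subpools Tibble with columns `id`, `fwd_barcode`, `rev_barcode`;
#'   barcodes pairwise distinct, length >= 6.
#' @param assignment Named character vector mapping `guide_id` ->
#'   subpool id; every guide must be assigned exactly once. Default: all
#'   guides into the first subpool.
#' @param adapters Length-2 character vector `(left, right)` of constant
#'   adapter sequences flanking the insert.
#' @param expression_profile Cloning profile supplying the prefix rule.
#' @return Tibble `subpool_id`, `guide_id`, `oligo_seq`, `total_len`. A
#'   warning lists subpools whose oligos differ in length (mixed-length
#'   inserts).
#' @export
assemble_pool <- function(guides, subpools, assignment = NULL,
                          adapters = c("GTGGAAAGGACGAAACACCG", "GTTTTAGAGCTAGAAATAGCAAG"),
                          expression_profile = "bbsI_U6") {
  check_subpools(subpools)
  if (anyDuplicated(guides$guide_id)) {
    abort("duplicate guide_id in pool input", class = "guidecraft_usage_error")
  }
  if (is.null(assignment)) {
    assignment <- stats::setNames(rep(subpools$id[1], nrow(guides)),
                                  guides$guide_id)
  }
  if (anyDuplicated(names(assignment))) {
    abort(sprintf("guide '%s' assigned to more than one subpool",
                  names(assignment)[duplicated(names(assignment))][1]),
          class = "guidecraft_assignment_error")
  }
  missing <- setdiff(guides$guide_id, names(assignment))
  if (length(missing) > 0) {
    abort(sprintf("guide '%s' not assigned to a subpool", missing[1]),
          class = "guidecraft_assignment_error")
  }
  bad <- setdiff(unname(assignment[guides$guide_id]), subpools$id)
  if (length(bad) > 0) {
    abort(sprintf("unknown subpool id '%s' in assignment", bad[1]),
          class = "guidecraft_assignment_error")
  }
  profile <- cloning_profile(expression_profile)
  insert <- adjust_insert(guides$protospacer, profile$prepend_g_rule)
  sp <- subpools[match(assignment[guides$guide_id], subpools$id), ]
  oligo <- paste0(sp$fwd_barcode, adapters[1], insert, adapters[2],
                  revcomp(sp$rev_barcode))
  n_insert <- stringr::str_count(oligo, stringr::fixed(insert))
  if (any(n_insert != 1)) {
    warning(sprintf("insert of guide %s occurs %d times in its oligo",
                    guides$guide_id[n_insert != 1][1],
                    n_insert[n_insert != 1][1]), call. = FALSE)
  }
  out <- tibble(subpool_id = sp$id, guide_id = guides$guide_id,
                oligo_seq = oligo, total_len = nchar(oligo))
  lens <- out |> group_by(.data$subpool_id) |>
    summarise(n_len = dplyr::n_distinct(.data$total_len), .groups = "drop")
  if (any(lens$n_len > 1)) {
    warning(sprintf("subpool(s) %s contain oligos of unequal length",
                    paste(lens$subpool_id[lens$n_len > 1], collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Decode pool oligos back to (subpool, guide)
#'
#' Inverts the fixed [assemble_pool()] layout from the sequence alone: the
#' forward barcode is identified by prefix match, the reverse barcode by
#' suffix match against its reverse complement, adapters are stripped, and
#' the insert is matched against the guides' prefix-adjusted protospacers.
#'
#' @param oligos Character vector of oligo sequences (or an
#'   [assemble_pool()] tibble).
#' @param guides Guide tibble used for assembly.
#' @param subpools Subpool tibble used for assembly.
#' @inheritParams assemble_pool
#' @return Tibble `oligo_seq`, `subpool_id`, `guide_id` (NA where a
#'   component cannot be identified).
#' @export
decode_pool <- function(oligos, guides, subpools,
                        adapters = c("GTGGAAAGGACGAAACACCG", "GTTTTAGAGCTAGAAATAGCAAG"),
                        expression_profile = "bbsI_U6") {
  if (is.data.frame(oligos)) oligos <- oligos$oligo_seq
  profile <- cloning_profile(expression_profile)
  insert <- adjust_insert(guides$protospacer, profile$prepend_g_rule)
  dec <- map(oligos, function(o) {
    fwd <- which(startsWith(o, subpools$fwd_barcode))
    rev <- which(endsWith(o, revcomp(subpools$rev_barcode)))
    sp <- intersect(fwd, rev)
    if (length(sp) != 1) {
      return(list(subpool_id = NA_character_, guide_id = NA_character_))
    }
    core <- substr(o, nchar(subpools$fwd_barcode[sp]) + 1L,
                   nchar(o) - nchar(subpools$rev_barcode[sp]))
    if (!startsWith(core, adapters[1]) || !endsWith(core, adapters[2])) {
      return(list(subpool_id = subpools$id[sp], guide_id = NA_character_))
    }
    ins <- substr(core, nchar(adapters[1]) + 1L, nchar(core) - nchar(adapters[2]))
    gi <- which(insert == ins)
    list(subpool_id = subpools$id[sp],
         guide_id = if (length(gi) == 1) guides$guide_id[gi] else NA_character_)
  })
  tibble(oligo_seq = oligos,
         subpool_id = map_chr(dec, "subpool_id"),
         guide_id = map_chr(dec, "guide_id"))
}

#' Read a subpool configuration TSV
#'
#' @param path TSV with columns `id`, `fwdBarcode`, `revBarcode` (or
#'   `fwd_barcode`/`rev_barcode`).
#' @return Tibble `id`, `fwd_barcode`, `rev_barcode`, validated.
#' @export
read_subpools <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  names(tb) <- sub("^fwdBarcode$", "fwd_barcode",
                   sub("^revBarcode$", "rev_barcode", names(tb)))
  check_subpools(tb)
  tb
}
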