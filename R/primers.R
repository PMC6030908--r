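has_homopolymer_run <- function(seq) {
  grepl("AAAA|TTTT|GGGG|CCCC", seq)
}

# enumerate candidate primers in a plus-strand region [lo, hi) of contig
# sequence S; direction "left" takes plus-strand substrings, "right" takes
# reverse complements. Returns start0/end0 (plus-strand, 0-based half-open),
# seq and tm, already filtered on the per-primer rules.
enumerate_primers <- function(S, lo, hi, direction, tm_target, tm_tol,
                              len_range = c(18L, 27L)) {
  starts <- integer(0); lens <- integer(0)
  for (len in seq.int(len_range[1], len_range[2])) {
    if (hi - lo < len) next
    st <- seq.int(lo, hi - len)
    starts <- c(starts, st)
    lens <- c(lens, rep(len, length(st)))
  }
  if (length(starts) == 0) {
    return(tibble(start0 = integer(), end0 = integer(), seq = character(),
                  tm = numeric()))
  }
  plus <- substring(S, starts + 1L, starts + lens)
  seqs <- if (direction == "left") plus else revcomp(plus)
  keep <- !grepl("N", seqs, fixed = TRUE) & !has_homopolymer_run(seqs) &
    substring(seqs, nchar(seqs), nchar(seqs)) %in% c("G", "C")
  out <- tibble(start0 = starts[keep], end0 = starts[keep] + lens[keep],
                seq = seqs[keep])
  if (nrow(out) == 0) { out$tm <- numeric(0); return(out) }
  out$tm <- melting_temperature(out$seq)
  filter(out, abs(.data$tm - tm_target) <= tm_tol)
}

#' Design validation primers flanking a target site
#'
#' Deterministic greedy search: all candidate primers of length 18-27 in the
#' flanks are enumerated; candidates with homopolymer runs (AAAA/TTTT/GGGG/
#' CCCC), a non-G/C 3' end, or a Tm outside `tm_target +/- tm_tol` are
#' discarded; among pairs whose product covers the site and falls inside
#' `product_range`, the pair minimising the summed |Tm - target| is
#' returned (ties broken by smaller product, then leftmost coordinates).
#' Identical inputs always return the identical pair.
#'
#' @param genome A [genome_index].
#' @param contig Contig holding the site.
#' @param site_start,site_end 0-based half-open plus-strand interval that
#'   the amplicon must contain (primers bind outside it).
#' @param product_range Allowed amplicon length `(min, max)`; default
#'   600-1000 bp (Sanger validation).
#' @param tm_target,tm_tol Target primer Tm in degrees C and tolerance.
#' @param name_prefix Prefix for primer names (`<prefix>_F` / `<prefix>_R`),
#'   typically the guide id.
#' @return One-row tibble: `name_prefix`, `left_seq`, `right_seq`,
#'   `left_start` (0-based), `right_end` (0-based exclusive), `tm_left`,
#'   `tm_right`, `product_len`, `contig`.
#' @export
design_flanking_primers <- function(genome, contig, site_start, site_end,
                                    product_range = c(600L, 1000L),
                                    tm_target = 60, tm_tol = 3,
                                    name_prefix = "target") {
  S <- unclass(genome)[[contig]]
  if (is.null(S)) {
    abort(sprintf("contig '%s' not in genome", contig),
          class = "guidecraft_usage_error")
  }
  L <- nchar(S)
  max_prod <- product_range[2]
  lo_l <- max(0L, site_end - max_prod)
  left <- enumerate_primers(S, lo_l, site_start, "left", tm_target, tm_tol)
  right <- enumerate_primers(S, site_end, min(L, site_start + max_prod),
                             "right", tm_target, tm_tol)
  if (nrow(left) == 0 || nrow(right) == 0) {
    side <- if (nrow(left) == 0) "left" else "right"
    abort(sprintf(paste0("no feasible %s primer for %s:%d-%d (flank too short,",
                         " or no candidate passes the run/3'-GC/Tm %g+-%g rules)"),
                  side, contig, site_start, site_end, tm_target, tm_tol),
          class = "guidecraft_primer_error")
  }
  prod_len <- outer(right$end0, left$start0, `-`)           # rows: right
  feasible <- prod_len >= product_range[1] & prod_len <= product_range[2]
  if (!any(feasible)) {
    abort(sprintf("no primer pair for %s:%d-%d yields a product in [%d, %d] bp",
                  contig, site_start, site_end, product_range[1], product_range[2]),
          class = "guidecraft_primer_error")
  }
  idx <- which(feasible, arr.ind = TRUE)
  ri_all <- idx[, 1L]; li_all <- idx[, 2L]
  cost <- abs(right$tm[ri_all] - tm_target) + abs(left$tm[li_all] - tm_target)
  # deterministic tie-breaks: cost, then product length, then coordinates
  best <- order(cost, prod_len[idx], left$start0[li_all], right$end0[ri_all])[1]
  ri <- ri_all[best]; li <- li_all[best]
  tibble(
    name_prefix = name_prefix, contig = contig,
    left_seq = left$seq[li], right_seq = right$seq[ri],
    left_start = left$start0[li], right_end = right$end0[ri],
    tm_left = left$tm[li], tm_right = right$tm[ri],
    product_len = right$end0[ri] - left$start0[li]
  )
}

#' Batch primer design for every off-target
#'
#' One flanking pair per hit where feasible, sized for high-throughput
#' amplicon sequencing (default 200-280 bp products). Hits are ranked by
#' descending CFD and primers named `"<guideId>_ot<rank>_F/R"`; per-hit
#' failures are returned as data in a skip list, never raised.
#'
#' @param hits Off-target tibble from [find_offtargets()].
#' @param genome A [genome_index].
#' @param product_range,tm_target,tm_tol Passed to
#'   [design_flanking_primers()].
#' @return List with `pairs` (tibble of designed pairs, plus `ot_rank`) and
#'   `skipped` (tibble `contig`, `start`, `ot_rank`, `reason`);
#'   `nrow(pairs) + nrow(skipped) == nrow(hits)`.
#' @export
offtarget_primer_batch <- function(hits, genome, product_range = c(200L, 280L),
                                   tm_target = 60, tm_tol = 3) {
  hits <- arrange(hits, desc(.data$cfd), .data$contig, .data$start)
  hits$ot_rank <- seq_len(nrow(hits))
  pairs <- list(); skipped <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    res <- tryCatch(
      design_flanking_primers(genome, h$contig, h$start,
                              h$start + nchar(h$site_seq),
                              product_range, tm_target, tm_tol,
                              name_prefix = sprintf("%s_ot%d", h$guide_id,
                                                    h$ot_rank)),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <- tibble(contig = h$contig,
                                                start = h$start,
                                                ot_rank = h$ot_rank,
                                                reason = res)
    } else {
      res$ot_rank <- h$ot_rank
      pairs[[length(pairs) + 1L]] <- res
    }
  }
  list(
    pairs = bind_rows(pairs),
    skipped = if (length(skipped)) bind_rows(skipped)
              else tibble(contig = character(), start = integer(),
                          ot_rank = integer(), reason = character())
  )
}

#' CRISPResso amplicon manifest
#'
#' One row per designed amplicon with the plus-strand genomic product
#' sequence and the guide protospacer (no PAM), the input format of the
#' CRISPResso amplicon-sequencing analysis tool. Every row is validated:
#' the guide must occur in the amplicon on either strand.
#'
#' @param pairs Primer-pair tibble from [design_flanking_primers()] /
#'   [offtarget_primer_batch()] (needs `name_prefix`, `contig`,
#'   `left_start`, `right_end`).
#' @param genome A [genome_index].
#' @param guide_seq Protospacer sequence each amplicon interrogates: the
#'   guide itself for on-target amplicons, the genomic site's protospacer
#'   for off-target amplicons (length 1 or `nrow(pairs)`).
#' @return Tibble with columns `name`, `amplicon_seq`, `guide_seq`.
#' @export
crispresso_manifest <- function(pairs, genome, guide_seq) {
  guide_seq <- rep_len(guide_seq, nrow(pairs))
  amp <- pmap_chr(list(pairs$contig, pairs$left_start, pairs$right_end),
                  function(cn, a, b) substr(unclass(genome)[[cn]], a + 1L, b))
  ok <- stringr::str_detect(amp, stringr::fixed(guide_seq)) |
    stringr::str_detect(amp, stringr::fixed(revcomp(guide_seq)))
  if (!all(ok)) {
    abort(sprintf("amplicon '%s' does not contain the guide on either strand",
                  pairs$name_prefix[which(!ok)[1]]),
          class = "guidecraft_validation_error")
  }
  tibble(name = pairs$name_prefix, amplicon_seq = amp, guide_seq = guide_seq)
}

#' Primer table in long (one row per oligo) form
#'
#' @param pairs Primer-pair tibble.
#' @return Tibble `name`, `seq`, `tm`, `start1`, `strand`, `productLen`.
#' @export
primer_table <- function(pairs) {
  bind_rows(
    tibble(name = paste0(pairs$name_prefix, "_F"), seq = pairs$left_seq,
           tm = pairs$tm_left, start1 = pairs$left_start + 1L, strand = "+",
           productLen = pairs$product_len),
    tibble(name = paste0(pairs$name_prefix, "_R"), seq = pairs$right_seq,
           tm = pairs$tm_right, start1 = pairs$right_end - nchar(pairs$right_seq) + 1L,
           strand = "-", productLen = pairs$product_len)
  ) |>
    arrange(.data$name)
}
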