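ot_columns <- function() {
  tibble(guide_id = character(), contig = character(), start = integer(),
         strand = character(), site_seq = character(), pam_seq = character(),
         mismatches = integer(), mm_positions = character(),
         pam_canonical = logical(), mit_hit = numeric(), cfd = numeric(),
         is_on_target = logical())
}

active_pams <- function(nuclease, alt_pams) {
  c(nuclease$pam, if (alt_pams) nuclease$alt_pams)
}

# shared per-hit annotation and canonical ordering for both search routes
finish_hits <- function(raw, guide_seq, guide_id, nuclease, tables, on_target) {
  if (nrow(raw) == 0) {
    return(ot_columns())
  }
  g <- nchar(guide_seq)
  raw <- raw |>
    mutate(
      guide_id = guide_id,
      mismatches = map_int(.data$site_seq, function(s) {
        sum(seq_chars(s) != seq_chars(guide_seq))
      }),
      mm_positions = map_chr(.data$site_seq, function(s) {
        paste(mismatch_positions_distal(guide_seq, s, nuclease$pam_side),
              collapse = ",")
      }),
      pam_canonical = iupac_match(nuclease$pam, .data$pam_seq),
      mit_hit = map_dbl(.data$site_seq, mit_hit_score, guide_seq = guide_seq,
                        tables = tables),
      cfd = map2_dbl(.data$site_seq, .data$pam_seq, function(s, p) {
        cfd_score(guide_seq, s, p, tables, nuclease$pam_side)
      })
    )
  if (!is.null(on_target)) {
    raw$is_on_target <- raw$mismatches == 0 &
      raw$contig == on_target$contig &
      raw$start == on_target$start &
      raw$strand == on_target$strand
  } else {
    perfect <- which(raw$mismatches == 0 & raw$pam_canonical)
    raw$is_on_target <- FALSE
    if (length(perfect) == 1) raw$is_on_target[perfect] <- TRUE
  }
  raw |>
    arrange(.data$mismatches, desc(.data$cfd), .data$contig, .data$start) |>
    select("guide_id", "contig", "start", "strand", "site_seq", "pam_seq",
           "mismatches", "mm_positions", "pam_canonical", "mit_hit", "cfd",
           "is_on_target")
}

check_ot_args <- function(guide_seq, nuclease, max_mm) {
  if (nchar(guide_seq) != nuclease$guide_len) {
    abort(sprintf("guide length %d does not match %s guide length %d",
                  nchar(guide_seq), nuclease$name, nuclease$guide_len),
          class = "guidecraft_usage_error")
  }
  if (max_mm < 0 || max_mm > 5) {
    abort("max_mm must be in 0..5", class = "guidecraft_usage_error")
  }
  assert_dna(guide_seq, "guide", allow = "ACGT")
}

#' Enumerate genomic off-targets of a guide
#'
#' Finds every site on either strand of the genome where (a) the PAM matches
#' the nuclease's canonical pattern — or one of its alternative patterns
#' when `alt_pams` is on — and (b) the protospacer differs from the guide at
#' no more than `max_mm` positions. Sites containing N (masked/ambiguous
#' bases) are never reported. The on-target site itself appears in the
#' output, flagged `is_on_target` when it is locatable (`on_target` given,
#' or a unique perfect canonical-PAM match exists); downstream aggregation
#' ([specificity_score()], [mismatch_histogram()]) excludes it.
#'
#' The search is a PAM-anchored vectorised Hamming scan: PAM occurrences are
#' located first (every reportable hit must carry one), then the adjacent
#' protospacer window is verified base by base. [brute_force_offtargets()]
#' implements the identical contract by an independent windowed scan and is
#' used as the test oracle.
#'
#' @param guide_seq Protospacer sequence, 5'->3', ACGT only, length equal to
#'   the nuclease's guide length.
#' @param genome A [genome_index].
#' @param nuclease A [nuclease_profile()] (or its name).
#' @param max_mm Mismatch budget, 0..5 (default 4).
#' @param alt_pams Also scan the profile's alternative PAMs (default TRUE).
#' @param tables Score tables, see [read_score_tables()].
#' @param on_target Optional `list(contig=, start=, strand=)` naming the
#'   submitted locus (0-based protospacer start on the plus strand).
#' @param guide_id Identifier copied into the output rows.
#' @return Tibble with one row per hit: `guide_id`, `contig`, `start`
#'   (0-based protospacer start, plus strand), `strand`, `site_seq` and
#'   `pam_seq` (guide orientation), `mismatches`, `mm_positions` (1-based
#'   from the PAM-distal end), `pam_canonical`, `mit_hit`, `cfd`,
#'   `is_on_target`; sorted by (mismatches, -cfd, contig, start).
#' @export
find_offtargets <- function(guide_seq, genome, nuclease = nuclease_profile("spcas9"),
                            max_mm = 4L, alt_pams = TRUE,
                            tables = default_score_tables(),
                            on_target = NULL, guide_id = NA_character_) {
  nuclease <- nuclease_profile(nuclease)
  check_ot_args(guide_seq, nuclease, max_mm)
  g <- nchar(guide_seq)
  pams <- active_pams(nuclease, alt_pams)
  pl <- nchar(nuclease$pam)
  gch <- seq_chars(guide_seq)
  rch <- seq_chars(revcomp(guide_seq))

  hamming_keep <- function(sv, starts0, ref) {
    # starts0: 0-based protospacer starts; returns those within budget and N-free
    if (length(starts0) == 0) return(integer(0))
    mm <- integer(length(starts0))
    has_n <- logical(length(starts0))
    for (k in seq_len(g)) {
      b <- sv[starts0 + k]
      mm <- mm + (b != ref[k])
      has_n <- has_n | b == "N"
    }
    starts0[mm <= max_mm & !has_n]
  }

  out <- vector("list", 2L * length(genome))
  li <- 0L
  for (cn in names(genome)) {
    S <- unclass(genome)[[cn]]
    sv <- seq_chars(S)
    L <- length(sv)
    pam_at <- sort(unique(unlist(lapply(pams, function(p) match_positions0(sv, p)))))
    rc_at <- sort(unique(unlist(lapply(pams, function(p) {
      match_positions0(sv, revcomp(p))
    }))))
    if (nuclease$pam_side == "3p") {
      p_starts <- hamming_keep(sv, pam_at[pam_at - g >= 0] - g, gch)
      m_cand <- rc_at[rc_at + pl + g <= L] + pl
      m_starts <- hamming_keep(sv, m_cand, rch)
      p_pam0 <- p_starts + g
      m_pam0 <- m_starts - pl
    } else {
      p_cand <- pam_at[pam_at + pl + g <= L] + pl
      p_starts <- hamming_keep(sv, p_cand, gch)
      m_starts <- hamming_keep(sv, rc_at[rc_at - g >= 0] - g, rch)
      p_pam0 <- p_starts - pl
      m_pam0 <- m_starts + g
    }
    if (length(p_starts) > 0) {
      li <- li + 1L
      out[[li]] <- tibble(
        contig = cn, start = as.integer(p_starts), strand = "+",
        site_seq = substring(S, p_starts + 1L, p_starts + g),
        pam_seq = substring(S, p_pam0 + 1L, p_pam0 + pl)
      )
    }
    if (length(m_starts) > 0) {
      li <- li + 1L
      out[[li]] <- tibble(
        contig = cn, start = as.integer(m_starts), strand = "-",
        site_seq = revcomp(substring(S, m_starts + 1L, m_starts + g)),
        pam_seq = revcomp(substring(S, m_pam0 + 1L, m_pam0 + pl))
      )
    }
  }
  finish_hits(bind_rows(out[seq_len(li)]), guide_seq, guide_id, nuclease,
              tables, on_target)
}

#' Brute-force off-target scan (reference oracle)
#'
#' Same contract as [find_offtargets()], implemented as the obvious
#' window-by-window scan with no indexing shortcuts: every
#' protospacer+PAM-sized window on each strand is extracted as a string, the
#' PAM is tested with an anchored IUPAC regex, and mismatches are counted on
#' the full window. The minus strand is scanned on the reverse-complemented
#' contig. Used in tests as the independent oracle and available from the
#' CLI via `--brute-force`.
#'
#' @inheritParams find_offtargets
#' @return As [find_offtargets()].
#' @export
brute_force_offtargets <- function(guide_seq, genome,
                                   nuclease = nuclease_profile("spcas9"),
                                   max_mm = 4L, alt_pams = TRUE,
                                   tables = default_score_tables(),
                                   on_target = NULL, guide_id = NA_character_) {
  nuclease <- nuclease_profile(nuclease)
  check_ot_args(guide_seq, nuclease, max_mm)
  g <- nchar(guide_seq)
  pl <- nchar(nuclease$pam)
  wl <- g + pl
  pams <- active_pams(nuclease, alt_pams)
  pam_res <- paste0("^", vapply(pams, iupac_regex, character(1)), "$")
  gch <- seq_chars(guide_seq)

  scan_one <- function(Tseq) {
    L <- nchar(Tseq)
    n <- L - wl + 1L
    if (n < 1L) {
      return(tibble(t_start = integer(), site_seq = character(),
                    pam_seq = character()))
    }
    win <- substring(Tseq, 1:n, wl:L)
    if (nuclease$pam_side == "3p") {
      proto <- substring(win, 1L, g); pam <- substring(win, g + 1L, wl)
    } else {
      pam <- substring(win, 1L, pl); proto <- substring(win, pl + 1L, wl)
    }
    ok <- Reduce(`|`, lapply(pam_res, function(re) grepl(re, pam)))
    ok <- ok & !grepl("N", proto, fixed = TRUE)
    idx <- which(ok)
    if (length(idx) == 0) {
      return(tibble(t_start = integer(), site_seq = character(),
                    pam_seq = character()))
    }
    mat <- matrix(unlist(strsplit(proto[idx], "")), nrow = g)
    mm <- colSums(mat != gch)
    idx <- idx[mm <= max_mm]
    w0 <- idx - 1L
    p0 <- if (nuclease$pam_side == "3p") w0 else w0 + pl
    tibble(t_start = as.integer(p0), site_seq = proto[idx], pam_seq = pam[idx])
  }

  out <- list()
  for (cn in names(genome)) {
    S <- unclass(genome)[[cn]]
    L <- nchar(S)
    fwd <- scan_one(S)
    if (nrow(fwd) > 0) {
      out[[length(out) + 1L]] <- mutate(fwd, contig = cn, strand = "+",
                                        start = .data$t_start)
    }
    rev <- scan_one(revcomp(S))
    if (nrow(rev) > 0) {
      out[[length(out) + 1L]] <- mutate(rev, contig = cn, strand = "-",
                                        start = L - .data$t_start - g)
    }
  }
  raw <- bind_rows(out)
  if (nrow(raw) > 0) raw <- select(raw, -"t_start")
  finish_hits(raw, guide_seq, guide_id, nuclease, tables, on_target)
}

#' Filter off-target hits by exon overlap and contig
#'
#' Annotates hits with `in_exon` (when an annotation is supplied) and
#' `same_contig` (when a target contig is named), then applies the requested
#' filters; the two filters compose.
#'
#' @param hits Off-target tibble from [find_offtargets()].
#' @param annotation Exon annotation tibble from [read_bed()], or NULL.
#' @param exonic_only Keep only hits overlapping at least one exon interval
#'   (requires `annotation`).
#' @param same_contig_only Keep only hits on `target_contig`.
#' @param target_contig Contig name of the submitted target.
#' @return Filtered tibble with added `in_exon` (logical or NA) and
#'   `same_contig` (logical or NA) columns.
#' @export
filter_hits <- function(hits, annotation = NULL, exonic_only = FALSE,
                        same_contig_only = FALSE, target_contig = NULL) {
  if (exonic_only && is.null(annotation)) {
    abort("exonic_only requires an exon annotation", class = "guidecraft_usage_error")
  }
  if (nrow(hits) == 0) {
    hits$in_exon <- logical(0); hits$same_contig <- logical(0)
    return(hits)
  }
  if (!is.null(annotation) && nrow(annotation) > 0) {
    hr <- GenomicRanges::GRanges(hits$contig,
                                 IRanges::IRanges(hits$start + 1L,
                                                  hits$start + nchar(hits$site_seq)))
    ar <- GenomicRanges::GRanges(annotation$contig,
                                 IRanges::IRanges(annotation$start + 1L,
                                                  annotation$end))
    hits$in_exon <- IRanges::overlapsAny(hr, ar)
  } else {
    hits$in_exon <- if (is.null(annotation)) NA else FALSE
  }
  hits$same_contig <- if (is.null(target_contig)) NA else hits$contig == target_contig
  if (exonic_only) hits <- filter(hits, .data$in_exon)
  if (same_contig_only) {
    if (is.null(target_contig)) {
      abort("same_contig_only requires target_contig", class = "guidecraft_usage_error")
    }
    hits <- filter(hits, .data$same_contig)
  }
  hits
}
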