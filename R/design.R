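locate_input <- function(genome, input) {
  # exact plus-strand search; N-masked input bases match any genome base
  pat <- gsub("N", ".", input$seq, fixed = TRUE)
  for (cn in names(genome)) {
    m <- regexpr(pat, unclass(genome)[[cn]])
    if (m[1] != -1) return(list(contig = cn, offset = as.integer(m[1]) - 1L))
  }
  NULL
}

#' Design and score all guides for an input sequence
#'
#' The full pipeline: scan the input for PAM sites, enumerate off-targets
#' for every candidate in the genome, score each hit (MIT hit score, CFD),
#' aggregate per-guide specificity, add efficiency and microhomology
#' out-of-frame scores, and classify guides by the green/yellow/red
#' traffic-light scheme. When the input sequence has a unique exact
#' plus-strand match in the genome, guide loci are mapped onto it and the
#' on-target hit is excluded from specificity aggregation.
#'
#' @param input Input sequence (string, or [parse_input_sequence()] result).
#' @param genome A [genome_index] (or FASTA path).
#' @param nuclease A [nuclease_profile()] or its name.
#' @param max_mm Off-target mismatch budget (default 4).
#' @param alt_pams Scan alternative PAMs for off-targets (default TRUE).
#' @param tables Score tables ([default_score_tables()]).
#' @param annotation Optional exon annotation ([read_bed()]) used to
#'   annotate hits with `in_exon`.
#' @param gc_low,gc_high GC warning thresholds (percent).
#' @param color_high,color_low Specificity colour thresholds
#'   ([color_class()]).
#' @param eff_model Efficiency model name; default `"pam_proximal_gc"`
#'   (its 5'-PAM variant is picked automatically for Cpf1).
#' @param brute_force Use the brute-force oracle scanner instead of the
#'   fast path (identical results, for verification runs).
#' @return A `guide_design` object: list with `guides` (scored tibble),
#'   `hits` (all off-target rows), `input`, `nuclease`, `target` (locus of
#'   the input in the genome or NULL), and the parameters used.
#' @export
design_guides <- function(input, genome, nuclease = nuclease_profile("spcas9"),
                          max_mm = 4L, alt_pams = TRUE,
                          tables = default_score_tables(), annotation = NULL,
                          gc_low = 25, gc_high = 75,
                          color_high = 50, color_low = 30,
                          eff_model = NULL, brute_force = FALSE) {
  if (is.character(input)) input <- parse_input_sequence(input)
  if (!inherits(genome, "genome_index")) {
    genome <- if (is.character(genome) && length(genome) == 1 &&
                    file.exists(genome)) {
      read_genome_fasta(genome)
    } else {
      genome_index(genome)
    }
  }
  nuclease <- nuclease_profile(nuclease)
  eff_model <- eff_model %||%
    if (nuclease$pam_side == "5p") "pam_proximal_gc_5p" else "pam_proximal_gc"
  guides <- scan_guides(input, nuclease, gc_low = gc_low, gc_high = gc_high)
  target <- locate_input(genome, input)
  scan_fn <- if (brute_force) brute_force_offtargets else find_offtargets
  hit_list <- vector("list", nrow(guides))
  spec <- numeric(nrow(guides))
  mmc <- character(nrow(guides))
  for (i in seq_len(nrow(guides))) {
    on_target <- if (!is.null(target)) {
      list(contig = target$contig, start = target$offset + guides$start[i],
           strand = guides$strand[i])
    }
    h <- scan_fn(guides$protospacer[i], genome, nuclease, max_mm = max_mm,
                 alt_pams = alt_pams, tables = tables, on_target = on_target,
                 guide_id = guides$guide_id[i])
    h <- filter_hits(h, annotation = annotation,
                     target_contig = if (!is.null(target)) target$contig)
    hit_list[[i]] <- h
    spec[i] <- specificity_score(h)
    mmc[i] <- mismatch_histogram(h, max_mm = max_mm)
  }
  guides$spec_score <- spec
  guides$mm_counts <- mmc
  guides <- efficiency_score(guides, eff_model)
  guides <- oof_score_guides(guides)
  guides$color <- color_class(guides$spec_score, high = color_high, low = color_low)
  guides <- guides |>
    arrange(desc(.data$spec_score), .data$pam_start1, .data$strand)
  hits <- if (nrow(guides) == 0) {
    filter_hits(ot_columns(), annotation = annotation)
  } else {
    bind_rows(hit_list)
  }
  structure(
    list(guides = guides, hits = hits, input = input,
         nuclease = nuclease, target = target,
         params = list(max_mm = max_mm, alt_pams = alt_pams, gc_low = gc_low,
                       gc_high = gc_high, color_high = color_high,
                       color_low = color_low, eff_model = eff_model,
                       brute_force = brute_force)),
    class = "guide_design"
  )
}

#' @export
print.guide_design <- function(x, ...) {
  cat(sprintf("<guide_design> %s (%s): %d guide(s), %d off-target row(s)\n",
              x$input$name, x$nuclease$name, nrow(x$guides), nrow(x$hits)))
  print(head(x$guides[, c("guide_id", "protospacer", "strand", "spec_score",
                          "eff_score", "oof_score", "color")], 10))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a guide design into its per-guide table
#'
#' @param x A `guide_design` from [design_guides()].
#' @param ... Unused.
#' @return The scored guide tibble.
#' @method tidy guide_design
#' @export
tidy.guide_design <- function(x, ...) x$guides

#' One-row summary of a guide design
#'
#' @param x A `guide_design` from [design_guides()].
#' @param ... Unused.
#' @return Tibble with guide counts per colour class and score summaries.
#' @method glance guide_design
#' @export
glance.guide_design <- function(x, ...) {
  g <- x$guides
  tibble(
    n_guides = nrow(g),
    n_green = sum(g$color == "green"),
    n_yellow = sum(g$color == "yellow"),
    n_red = sum(g$color == "red"),
    n_offtargets = sum(!x$hits$is_on_target),
    median_spec = stats::median(g$spec_score),
    median_eff = stats::median(g$eff_score, na.rm = TRUE)
  )
}

round_or_na <- function(x) ifelse(is.na(x), NA_integer_, as.integer(round(x)))

guide_table <- function(design) {
  g <- design$guides
  tibble(
    guideId = g$guide_id,
    targetSeq = paste(g$protospacer, g$pam_seq),
    strand = g$strand,
    start1 = g$start + 1L,
    specScore = round_or_na(g$spec_score),
    effScore = round_or_na(g$eff_score),
    outOfFrameScore = round_or_na(g$oof_score),
    mmCounts = g$mm_counts,
    flags = g$flags,
    enzymes = g$enzymes
  )
}

#' Write the guide table TSV
#'
#' Columns (in order): guideId, targetSeq (protospacer and PAM separated by
#' a space), strand, start1 (1-based), specScore, effScore, outOfFrameScore,
#' mmCounts ("c0-c1-c2-c3-c4"), flags, enzymes. Rows keep the design's
#' order: specificity descending, ties by position then strand. Scores are
#' rounded to integers for display; the `guide_design` object keeps full
#' precision.
#'
#' @param design A `guide_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guide_table <- function(design, path) {
  readr::write_tsv(guide_table(design), path, progress = FALSE)
  invisible(path)
}

#' Write the off-target table TSV
#'
#' Columns: guideId, contig, start1 (1-based), strand, siteSeq, pamSeq,
#' mismatches, mitHit, cfd, inExon (0/1/NA), sameContig (0/1/NA). Per
#' guide, at most `cap` highest-CFD hits are written (the guide table's
#' mmCounts column always reflects the full count).
#'
#' @param design A `guide_design`.
#' @param path Output path.
#' @param cap Per-guide row cap (default 1000).
#' @return `path`, invisibly.
#' @export
write_offtarget_table <- function(design, path, cap = 1000L) {
  h <- design$hits
  h <- h |>
    group_by(.data$guide_id) |>
    arrange(desc(.data$cfd), .data$mismatches, .data$contig, .data$start,
            .by_group = TRUE) |>
    slice_head(n = cap) |>
    ungroup() |>
    arrange(.data$guide_id, .data$mismatches, desc(.data$cfd), .data$contig,
            .data$start)
  tb <- tibble(
    guideId = h$guide_id, contig = h$contig, start1 = h$start + 1L,
    strand = h$strand, siteSeq = h$site_seq, pamSeq = h$pam_seq,
    mismatches = h$mismatches, mitHit = round(h$mit_hit, 2),
    cfd = round(h$cfd, 4),
    inExon = ifelse(is.na(h$in_exon), NA_integer_, as.integer(h$in_exon)),
    sameContig = ifelse(is.na(h$same_contig), NA_integer_,
                        as.integer(h$same_contig))
  )
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Export a design as a GenBank flat file
#'
#' One `misc_bind` feature per guide (protospacer interval,
#' `complement(...)` for minus-strand guides) with `/label` set to the
#' guide id and `/note` carrying the three scores.
#'
#' @param design A `guide_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(design, path) {
  s <- design$input$seq
  L <- nchar(s)
  g <- design$guides
  con <- file(path, "w")
  on.exit(close(con))
  name <- gsub("[^A-Za-z0-9_.-]", "_", design$input$name)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   UNA", name, L), con)
  writeLines(sprintf("DEFINITION  guide candidates for %s (%s)", name,
                     design$nuclease$name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (i in seq_len(nrow(g))) {
    loc <- sprintf("%d..%d", g$start[i] + 1L, g$start[i] + nchar(g$protospacer[i]))
    if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     misc_bind       %s", loc), con)
    writeLines(sprintf("                     /label=%s", g$guide_id[i]), con)
    writeLines(sprintf("                     /note=\"specScore=%s;effScore=%s;outOfFrameScore=%s\"",
                       round_or_na(g$spec_score[i]), round_or_na(g$eff_score[i]),
                       round_or_na(g$oof_score[i])), con)
  }
  writeLines("ORIGIN", con)
  low <- tolower(s)
  for (off in seq(1L, L, by = 60L)) {
    chunk <- substr(low, off, min(L, off + 59L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    writeLines(sprintf("%9d %s", off, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
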