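#' Scan an input sequence for guide candidates
#'
#' Both strands are scanned for occurrences of the nuclease's PAM whose full
#' protospacer lies inside the input. Each candidate gets an identifier
#' `"<pos><forw|rev>"` where `<pos>` is the 1-based plus-strand coordinate
#' of the leftmost PAM base — the identifier later names primers and oligos.
#' Flags are annotated with [annotate_guide_flags()]; guides overlapping
#' N-masked positions (variants) are dropped from the default output.
#'
#' @param input An `input_seq` from [parse_input_sequence()] (a bare string
#'   is accepted and parsed).
#' @param nuclease A [nuclease_profile()] or its name.
#' @param gc_low,gc_high GC-content warning thresholds in percent.
#' @param enzymes Restriction enzyme table (tibble `name`, `site`) used to
#'   report screening enzymes whose unique recognition site spans the cut;
#'   NULL to skip.
#' @param context_len Plus-strand window captured around the cut site
#'   (default 50) for restriction screening, microhomology and primer work.
#' @param include_n_overlaps Keep guides flagged `OVERLAPS_N` (default
#'   FALSE, matching the behaviour of dropping variant-overlapping guides).
#' @return Tibble with one row per candidate: `guide_id`, `protospacer`,
#'   `pam_seq` (both 5'->3' in guide orientation), `strand`, `start`
#'   (0-based plus-strand protospacer start), `pam_start1`, `cut` (0-based
#'   plus-strand offset of the first base right of the cut), `context`
#'   (plus-strand, NA near the input edges), `gc_pct`, `flags` (comma
#'   list), `enzymes` (comma list, NA when context unavailable); ordered by
#'   PAM position then strand (+ before -).
#' @export
#' @examples
#' scan_guides("GTTTAGAGCTAGAAATAGCAAGG")
scan_guides <- function(input, nuclease = nuclease_profile("spcas9"),
                        gc_low = 25, gc_high = 75,
                        enzymes = default_enzymes(), context_len = 50L,
                        include_n_overlaps = FALSE) {
  if (is.character(input)) input <- parse_input_sequence(input)
  nuclease <- nuclease_profile(nuclease)
  g <- nuclease$guide_len
  pl <- nchar(nuclease$pam)
  S <- input$seq
  sv <- seq_chars(S)
  L <- length(sv)
  if (L < g + pl) {
    abort(sprintf("input too short for %s (< %d bases)", nuclease$name, g + pl),
          class = "guidecraft_usage_error")
  }
  pam_at <- match_positions0(sv, nuclease$pam)
  rc_at <- match_positions0(sv, revcomp(nuclease$pam))
  if (nuclease$pam_side == "3p") {
    pam_at <- pam_at[pam_at - g >= 0]
    rc_at <- rc_at[rc_at + pl + g <= L]
    p_start <- pam_at - g
    m_start <- rc_at + pl
  } else {
    pam_at <- pam_at[pam_at + pl + g <= L]
    rc_at <- rc_at[rc_at - g >= 0]
    p_start <- pam_at + pl
    m_start <- rc_at - g
  }
  ci <- cut_index(nuclease)
  empty <- tibble(strand = character(), start = integer(), pam0 = integer(),
                  protospacer = character(), pam_seq = character(),
                  cut = integer())
  plus <- if (length(p_start) == 0) empty else tibble(
    strand = "+", start = as.integer(p_start), pam0 = as.integer(pam_at),
    protospacer = substring(S, p_start + 1L, p_start + g),
    pam_seq = substring(S, pam_at + 1L, pam_at + pl),
    cut = as.integer(p_start + ci)
  )
  minus <- if (length(m_start) == 0) empty else tibble(
    strand = "-", start = as.integer(m_start), pam0 = as.integer(rc_at),
    protospacer = revcomp(substring(S, m_start + 1L, m_start + g)),
    pam_seq = revcomp(substring(S, rc_at + 1L, rc_at + pl)),
    cut = as.integer(m_start + g - ci)
  )
  guides <- bind_rows(plus, minus)
  if (nrow(guides) == 0) {
    guides$pam_start1 <- integer(); guides$guide_id <- character()
    guides$gc_pct <- numeric(); guides$context <- character()
    guides$flags <- character(); guides$enzymes <- character()
    return(select(guides, "guide_id", "protospacer", "pam_seq", "strand",
                  "start", "pam_start1", "cut", "context", "gc_pct", "flags",
                  "enzymes"))
  }
  # genome N matches no IUPAC class, so PAMs containing N were never called;
  # protospacers crossing Ns are flagged below instead
  guides <- guides |>
    mutate(
      pam_start1 = .data$pam0 + 1L,
      guide_id = paste0(.data$pam_start1,
                        ifelse(.data$strand == "+", "forw", "rev")),
      gc_pct = gc_percent(.data$protospacer)
    ) |>
    arrange(.data$pam_start1, .data$strand)
  half <- context_len %/% 2L
  ok_ctx <- guides$cut - half >= 0 & guides$cut + half <= L
  guides$context <- ifelse(ok_ctx,
                           substring(S, guides$cut - half + 1L, guides$cut + half),
                           NA_character_)
  guides <- annotate_guide_flags(guides, input, gc_low = gc_low,
                                 gc_high = gc_high, guide_len = g, pam_len = pl)
  if (!is.null(enzymes)) {
    guides$enzymes <- map_chr(guides$context, function(ctx) {
      if (is.na(ctx)) return(NA_character_)
      paste(restriction_overlap(ctx, half, enzymes), collapse = ",")
    })
  } else {
    guides$enzymes <- NA_character_
  }
  if (!include_n_overlaps) {
    guides <- filter(guides, !stringr::str_detect(.data$flags, "OVERLAPS_N"))
  }
  select(guides, "guide_id", "protospacer", "pam_seq", "strand", "start",
         "pam_start1", "cut", "context", "gc_pct", "flags", "enzymes")
}

#' Annotate guide warning flags
#'
#' Adds/recomputes the `flags` column: `HIGH_GC` (protospacer GC% strictly
#' above `gc_high`), `LOW_GC` (strictly below `gc_low`), `TTTT` (the Pol III
#' terminator TTTT occurs in the protospacer), `OVERLAPS_N` (any protospacer
#' or PAM base falls on an N-masked input position).
#'
#' @param guides Guide tibble from [scan_guides()] (needs `protospacer`,
#'   `strand`, `start`, `pam_start1`).
#' @param input The `input_seq` the guides came from.
#' @param gc_low,gc_high Thresholds in percent, `0 <= gc_low < gc_high <= 100`.
#' @param guide_len,pam_len Lengths used to reconstruct plus-strand
#'   intervals (defaults from the sequences themselves).
#' @return `guides` with a `flags` column (comma-separated, `""` if none).
#' @export
annotate_guide_flags <- function(guides, input, gc_low = 25, gc_high = 75,
                                 guide_len = NULL, pam_len = NULL) {
  if (!(gc_low >= 0 && gc_low < gc_high && gc_high <= 100)) {
    abort("need 0 <= gc_low < gc_high <= 100", class = "guidecraft_usage_error")
  }
  g <- guide_len %||% nchar(guides$protospacer[1])
  pl <- pam_len %||% nchar(guides$pam_seq[1])
  gc <- gc_percent(guides$protospacer)
  npos <- input$n_positions
  overlaps_n <- pmap(list(guides$start, guides$pam_start1 - 1L), function(s, p0) {
    any(c(seq.int(s, s + g - 1L), seq.int(p0, p0 + pl - 1L)) %in% npos)
  })
  flags <- pmap_chr(list(gc, guides$protospacer, overlaps_n),
                    function(gcv, proto, ovn) {
    f <- c(if (gcv > gc_high) "HIGH_GC",
           if (gcv < gc_low) "LOW_GC",
           if (grepl("TTTT", proto, fixed = TRUE)) "TTTT",
           if (ovn) "OVERLAPS_N")
    paste(f, collapse = ",")
  })
  guides$flags <- flags
  guides
}

#' Filter guides by 5' prefix
#'
#' Expression promoters impose 5' base preferences on the guide (U6: G-,
#' T7: GG-, U3: A-); this keeps guides whose protospacer already starts
#' with the required bases.
#'
#' @param guides Guide tibble.
#' @param mode One of `"none"`, `"G-"`, `"GG-"`, `"A-"` (trailing dash
#'   optional).
#' @return Filtered tibble (`mode = "none"` is the identity).
#' @export
prefix_filter <- function(guides, mode = "none") {
  mode <- sub("-$", "", mode)
  if (!mode %in% c("none", "G", "GG", "A")) {
    abort(sprintf("unknown prefix filter mode '%s'", mode),
          class = "guidecraft_usage_error")
  }
  if (mode == "none") return(guides)
  filter(guides, startsWith(.data$protospacer, mode))
}

#' Restriction enzymes usable to screen for cleavage
#'
#' Returns the enzymes whose recognition site (on either strand) spans the
#' predicted cut position *and* occurs exactly once within the given
#' context window, so loss of the site reports successful editing.
#'
#' @param context DNA context string (plus strand).
#' @param cut 0-based offset of the first base right of the cut within
#'   `context`.
#' @param enzymes Tibble with columns `name` and `site` (IUPAC).
#' @return Character vector of enzyme names (possibly empty).
#' @export
restriction_overlap <- function(context, cut, enzymes = default_enzymes()) {
  sv <- seq_chars(context)
  hits <- character(0)
  for (i in seq_len(nrow(enzymes))) {
    site <- enzymes$site[i]
    len <- nchar(site)
    occ <- union(match_positions0(sv, site), match_positions0(sv, revcomp(site)))
    if (length(occ) == 1 && occ < cut && occ + len > cut) {
      hits <- c(hits, enzymes$name[i])
    }
  }
  hits
}

#' Restriction enzyme tables
#'
#' `read_enzyme_table()` reads a 2-column TSV (`name`, IUPAC `site`);
#' `default_enzymes()` returns the 16 common 6-8-cutters shipped with the
#' package.
#'
#' @param path Path to a TSV file with columns `name` and `site`.
#' @return Tibble with columns `name`, `site`.
#' @export
read_enzyme_table <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("name", "site") %in% names(tb))) {
    abort("enzyme table needs columns 'name' and 'site'",
          class = "guidecraft_format_error")
  }
  tb
}

#' @rdname read_enzyme_table
#' @export
default_enzymes <- function() {
  if (is.null(the$enzymes)) {
    the$enzymes <- read_enzyme_table(system.file("extdata", "enzymes.tsv",
                                                 package = "guidecraft",
                                                 mustWork = TRUE))
  }
  the$enzymes
}
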