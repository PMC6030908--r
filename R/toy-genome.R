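#' Generate a synthetic genome with planted off-target sites
#'
#' Builds a random A/C/G/T genome and plants, for each plan entry, a copy of
#' the guide mutated at exactly `mismatches` protospacer positions next to a
#' concrete canonical PAM, on the requested strand. After planting, the
#' brute-force scanner verifies that the genome contains *exactly* the
#' planted sites within the checked mismatch budget; on any accidental
#' extra (or clobbered) site the background is regenerated, up to
#' `max_tries` times. The result is a pure function of the arguments,
#' including `seed`.
#'
#' @param guide Protospacer to plant (ACGT, length = nuclease guide length).
#' @param plan Data frame with columns `mismatches` (0..5) and `strand`
#'   (`"+"`/`"-"`), one row per site to plant.
#' @param nuclease A [nuclease_profile()] or its name.
#' @param n_contigs,contig_len Genome shape (each contig `contig_len` >= 100
#'   random bases).
#' @param seed Integer seed; identical arguments give identical genomes.
#' @param alt_pams Scan alternative PAMs during the cleanliness check, so
#'   fixtures are clean under default search settings.
#' @param check_mm Mismatch budget used for the cleanliness check (default:
#'   at least 4, or the largest planted `mismatches`).
#' @param max_tries Background regenerations before failing loudly.
#' @return List with `genome` (a [genome_index]) and `sites`, a tibble of
#'   planted records: `contig`, `start` (0-based plus-strand protospacer
#'   start), `strand`, `mismatches`, `site_seq`, `pam_seq` (guide
#'   orientation).
#' @export
#' @examples
#' fx <- generate_toy_genome("GACGTAGCTAGCTAGGATCC",
#'   plan = data.frame(mismatches = 0, strand = "+"), seed = 7)
#' fx$sites
generate_toy_genome <- function(guide, plan, nuclease = nuclease_profile("spcas9"),
                                n_contigs = 1L, contig_len = 3000L, seed = 1L,
                                alt_pams = TRUE, check_mm = NULL,
                                max_tries = 20L) {
  nuclease <- nuclease_profile(nuclease)
  g <- nuclease$guide_len
  pl <- nchar(nuclease$pam)
  site_len <- g + pl
  assert_dna(guide, "guide", allow = "ACGT")
  if (nchar(guide) != g) {
    abort(sprintf("guide length %d != %s guide length %d", nchar(guide),
                  nuclease$name, g), class = "guidecraft_usage_error")
  }
  plan <- as.data.frame(plan)
  stopifnot(all(c("mismatches", "strand") %in% names(plan)),
            all(plan$mismatches %in% 0:5), all(plan$strand %in% c("+", "-")),
            contig_len >= 100)
  check_mm <- check_mm %||% max(4L, max(plan$mismatches))
  bases <- c("A", "C", "G", "T")

  withr::with_seed(seed, {
    for (try_i in seq_len(max_tries)) {
      contigs <- vapply(seq_len(n_contigs), function(i) {
        paste(sample(bases, contig_len, replace = TRUE), collapse = "")
      }, character(1))
      names(contigs) <- paste0("c", seq_len(n_contigs))
      used <- lapply(contigs, function(x) integer(0))
      sites <- vector("list", nrow(plan))
      placed_ok <- TRUE
      for (i in seq_len(nrow(plan))) {
        m <- plan$mismatches[i]
        strand <- plan$strand[i]
        proto <- seq_chars(guide)
        if (m > 0) {
          at <- sample.int(g, m)
          for (p in at) proto[p] <- sample(setdiff(bases, proto[p]), 1)
        }
        proto <- paste(proto, collapse = "")
        pam <- paste(vapply(seq_chars(nuclease$pam),
                            function(ch) sample(iupac_set(ch), 1), character(1)),
                     collapse = "")
        site <- if (nuclease$pam_side == "3p") paste0(proto, pam) else paste0(pam, proto)
        if (strand == "-") site_ins <- revcomp(site) else site_ins <- site
        # pick a non-overlapping slot (5-base margin between planted sites)
        slot <- NULL
        for (attempt in seq_len(50L)) {
          cn <- sample(names(contigs), 1)
          s0 <- sample.int(contig_len - site_len + 1L, 1) - 1L
          win <- seq.int(s0, s0 + site_len - 1L)
          if (!any(win %in% used[[cn]])) { slot <- list(cn = cn, s0 = s0); break }
        }
        if (is.null(slot)) { placed_ok <- FALSE; break }
        cn <- slot$cn; s0 <- slot$s0
        substr(contigs[[cn]], s0 + 1L, s0 + site_len) <- site_ins
        used[[cn]] <- c(used[[cn]],
                        seq.int(max(0L, s0 - 5L),
                                min(contig_len - 1L, s0 + site_len + 4L)))
        proto_start <- if (xor(nuclease$pam_side == "3p", strand == "-")) {
          s0                      # protospacer at the left end of the window
        } else {
          s0 + pl
        }
        sites[[i]] <- tibble(contig = cn, start = as.integer(proto_start),
                             strand = strand, mismatches = as.integer(m),
                             site_seq = proto, pam_seq = pam)
      }
      if (!placed_ok) next
      sites <- bind_rows(sites)
      genome <- genome_index(contigs)
      hits <- brute_force_offtargets(guide, genome, nuclease,
                                     max_mm = check_mm, alt_pams = alt_pams,
                                     tables = uniform_score_tables())
      want <- sites[sites$mismatches <= check_mm, c("contig", "start", "strand",
                                                    "mismatches")]
      got <- hits[, c("contig", "start", "strand", "mismatches")]
      key <- function(d) sort(paste(d$contig, d$start, d$strand, d$mismatches))
      if (identical(key(want), key(got))) {
        return(list(genome = genome,
                    sites = arrange(sites, .data$contig, .data$start)))
      }
    }
    abort(sprintf("could not build a clean fixture in %d tries", max_tries),
          class = "guidecraft_fixture_error")
  })
}
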