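#' Reproducible run configuration
#'
#' Bundles every parameter of a design run. The configuration is serialised
#' to `run.json` in the output directory, and `run_design()` accepts either
#' the object or the path to a `run.json`, so any output directory can be
#' reproduced byte-identically from its config alone.
#'
#' @param genome Path to the genome FASTA.
#' @param input Path to the input sequence (plain text or FASTA).
#' @param out Output directory.
#' @param nuclease Nuclease name (`spcas9`, `sacas9`, `cpf1`).
#' @param bed Optional exon annotation BED path.
#' @param max_mm Off-target mismatch budget.
#' @param alt_pams Scan alternative PAMs.
#' @param gc_low,gc_high,color_high,color_low Thresholds, see
#'   [design_guides()].
#' @param tm_target,tm_tol Primer melting-temperature settings.
#' @param product_range Validation amplicon length range.
#' @param ot_product_range Off-target amplicon length range.
#' @param eff_model Efficiency model name (NULL = nuclease default).
#' @param genbank Also write a GenBank export.
#' @param brute_force Use the brute-force off-target scanner.
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic; the seed feeds fixture generation).
#' @return A `run_config` list.
#' @export
run_config <- function(genome, input, out, nuclease = "spcas9", bed = NULL,
                       max_mm = 4L, alt_pams = TRUE, gc_low = 25, gc_high = 75,
                       color_high = 50, color_low = 30, tm_target = 60,
                       tm_tol = 3, product_range = c(600L, 1000L),
                       ot_product_range = c(200L, 280L), eff_model = NULL,
                       genbank = FALSE, brute_force = FALSE, seed = 1L) {
  structure(list(genome = genome, input = input, out = out,
                 nuclease = nuclease, bed = bed, max_mm = as.integer(max_mm),
                 alt_pams = isTRUE(alt_pams), gc_low = gc_low,
                 gc_high = gc_high, color_high = color_high,
                 color_low = color_low, tm_target = tm_target,
                 tm_tol = tm_tol, product_range = as.integer(product_range),
                 ot_product_range = as.integer(ot_product_range),
                 eff_model = eff_model, genbank = isTRUE(genbank),
                 brute_force = isTRUE(brute_force), seed = as.integer(seed)),
            class = "run_config")
}

load_run_config <- function(config) {
  if (is.character(config)) {
    lst <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(run_config, lst[!vapply(lst, is.null, logical(1))])
  }
  stopifnot(inherits(config, "run_config"))
  config
}

write_run_json <- function(config, dir) {
  jsonlite::write_json(unclass(config), file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

config_design <- function(config) {
  if (!file.exists(config$genome)) {
    abort(sprintf("genome FASTA not found: %s", config$genome),
          class = "guidecraft_usage_error")
  }
  if (!file.exists(config$input)) {
    abort(sprintf("input sequence not found: %s", config$input),
          class = "guidecraft_usage_error")
  }
  genome <- read_genome_fasta(config$genome)
  input <- parse_input_sequence(readr::read_file(config$input))
  annotation <- if (!is.null(config$bed)) read_bed(config$bed)
  design_guides(input, genome, nuclease = config$nuclease,
                max_mm = config$max_mm, alt_pams = config$alt_pams,
                annotation = annotation, gc_low = config$gc_low,
                gc_high = config$gc_high, color_high = config$color_high,
                color_low = config$color_low, eff_model = config$eff_model,
                brute_force = config$brute_force)
}

#' Run the design command
#'
#' Scans, scores and writes `guides.tsv`, `offtargets.tsv`, `run.json` and
#' (optionally) `design.gb` into the configured output directory. Reruns
#' with the same configuration are byte-identical.
#'
#' @param config A [run_config()] or path to a `run.json`.
#' @return Invisibly, a list with `status` (0 = guides found, 3 = zero
#'   guides) and the `guide_design` object.
#' @export
run_design <- function(config) {
  config <- load_run_config(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  design <- config_design(config)
  write_run_json(config, config$out)
  write_guide_table(design, file.path(config$out, "guides.tsv"))
  write_offtarget_table(design, file.path(config$out, "offtargets.tsv"))
  if (config$genbank) write_genbank(design, file.path(config$out, "design.gb"))
  status <- if (nrow(design$guides) > 0) 0L else 3L
  message(sprintf("design: %d guide(s), %d off-target row(s) -> %s",
                  nrow(design$guides), nrow(design$hits), config$out))
  invisible(list(status = status, design = design))
}

#' Run batch off-target primer design for one guide
#'
#' Recomputes the design, designs one amplicon-sequencing primer pair per
#' off-target of `guide_id` plus a validation pair and an
#' amplicon-sequencing pair for the on-target locus, and writes
#' `primers.tsv`, `validation_primers.tsv`, `crispresso_manifest.tsv` and
#' `primer_skips.tsv`. The manifest holds one row per amplicon
#' (on-target first), in CRISPResso's `name`/`amplicon_seq`/`guide_seq`
#' input format.
#'
#' @param config A [run_config()] or path to a `run.json`.
#' @param guide_id Guide identifier from the design's guide table.
#' @return Invisibly, a list with `pairs`, `skipped`, `manifest`,
#'   `validation`.
#' @export
run_offtarget_primers <- function(config, guide_id) {
  config <- load_run_config(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  design <- config_design(config)
  if (!guide_id %in% design$guides$guide_id) {
    abort(sprintf("unknown guide_id '%s'", guide_id),
          class = "guidecraft_usage_error")
  }
  genome <- read_genome_fasta(config$genome)
  gd <- design$guides[design$guides$guide_id == guide_id, ]
  hits <- design$hits[design$hits$guide_id == guide_id, ]
  on_hit <- hits[hits$is_on_target, ]
  ot_hits <- hits[!hits$is_on_target, ]
  batch <- offtarget_primer_batch(ot_hits, genome,
                                  product_range = config$ot_product_range,
                                  tm_target = config$tm_target,
                                  tm_tol = config$tm_tol)
  pairs <- batch$pairs
  validation <- NULL
  if (nrow(on_hit) == 1) {
    try_pair <- function(range, prefix) {
      tryCatch(
        design_flanking_primers(genome, on_hit$contig, on_hit$start,
                                on_hit$start + nchar(on_hit$site_seq),
                                product_range = range,
                                tm_target = config$tm_target,
                                tm_tol = config$tm_tol, name_prefix = prefix),
        error = function(e) {
          message(sprintf("on-target pair '%s' skipped: %s", prefix,
                          conditionMessage(e)))
          NULL
        })
    }
    on_pair <- try_pair(config$ot_product_range, paste0(guide_id, "_on"))
    if (!is.null(on_pair)) pairs <- bind_rows(on_pair, pairs)
    validation <- try_pair(config$product_range, guide_id)
    if (!is.null(validation)) {
      readr::write_tsv(primer_table(validation),
                       file.path(config$out, "validation_primers.tsv"),
                       progress = FALSE)
    }
  } else {
    message("on-target locus not locatable; validation primers skipped")
  }
  ot_sites <- arrange(ot_hits, desc(.data$cfd), .data$contig, .data$start)$site_seq
  pair_guide <- ifelse(grepl("_on$", pairs$name_prefix), gd$protospacer,
                       ot_sites[pairs$ot_rank])
  manifest <- crispresso_manifest(pairs, genome, pair_guide)
  readr::write_tsv(primer_table(pairs), file.path(config$out, "primers.tsv"),
                   progress = FALSE)
  readr::write_tsv(manifest, file.path(config$out, "crispresso_manifest.tsv"),
                   progress = FALSE)
  readr::write_tsv(batch$skipped, file.path(config$out, "primer_skips.tsv"),
                   progress = FALSE)
  write_run_json(config, config$out)
  message(sprintf("primers: %d pair(s), %d skipped, %d manifest row(s) -> %s",
                  nrow(pairs), nrow(batch$skipped), nrow(manifest), config$out))
  invisible(list(pairs = pairs, skipped = batch$skipped, manifest = manifest,
                 validation = validation))
}

#' Run the saturating-mutagenesis assistant
#'
#' Recomputes the design, keeps guides passing the minimal specificity /
#' efficiency criteria, assembles the barcoded synthesis pool (guides split
#' in positional order across the subpools, as evenly as possible) and
#' writes `pool.tsv`, `satmut_guides.tsv` and the companion
#' `crispresso_satmut.tsv` manifest (amplicon = the input sequence).
#'
#' @param config A [run_config()] or path to a `run.json`.
#' @param min_spec,min_eff Minimal scores (see [saturating_selection()]).
#' @param subpools Subpool tibble or path to a subpool TSV
#'   ([read_subpools()]).
#' @param adapters,expression_profile Passed to [assemble_pool()].
#' @return Invisibly, a list with `selection`, `pool`, `manifest`.
#' @export
run_satmut <- function(config, min_spec = 0, min_eff = 0, subpools,
                       adapters = c("GTGGAAAGGACGAAACACCG", "GTTTTAGAGCTAGAAATAGCAAG"),
                       expression_profile = "bbsI_U6") {
  config <- load_run_config(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  if (is.character(subpools)) subpools <- read_subpools(subpools)
  design <- config_design(config)
  sel <- saturating_selection(design$guides, min_spec = min_spec,
                              min_eff = min_eff)
  if (nrow(sel) == 0) {
    readr::write_tsv(tibble(subpoolId = character(), guideId = character(),
                            oligoSeq = character(), len = integer()),
                     file.path(config$out, "pool.tsv"), progress = FALSE)
    return(invisible(list(selection = sel, pool = NULL, manifest = NULL)))
  }
  assignment <- stats::setNames(
    subpools$id[ceiling(seq_len(nrow(sel)) / ceiling(nrow(sel) / nrow(subpools)))],
    sel$guide_id)
  pool <- assemble_pool(sel, subpools, assignment = assignment,
                        adapters = adapters,
                        expression_profile = expression_profile)
  manifest <- tibble(name = sel$guide_id, amplicon_seq = design$input$seq,
                     guide_seq = sel$protospacer)
  ok <- map2_lgl(manifest$amplicon_seq, manifest$guide_seq, function(a, g) {
    grepl(g, a, fixed = TRUE) || grepl(revcomp(g), a, fixed = TRUE)
  })
  stopifnot(all(ok))
  readr::write_tsv(tibble(subpoolId = pool$subpool_id, guideId = pool$guide_id,
                          oligoSeq = pool$oligo_seq, len = pool$total_len),
                   file.path(config$out, "pool.tsv"), progress = FALSE)
  sel_out <- guide_table(structure(list(guides = sel), class = "guide_design"))
  readr::write_tsv(sel_out, file.path(config$out, "satmut_guides.tsv"),
                   progress = FALSE)
  readr::write_tsv(manifest, file.path(config$out, "crispresso_satmut.tsv"),
                   progress = FALSE)
  write_run_json(config, config$out)
  message(sprintf("satmut: %d guide(s) in %d subpool(s), max cut gap %s -> %s",
                  nrow(pool), length(unique(pool$subpool_id)),
                  format(attr(sel, "max_cut_gap")), config$out))
  invisible(list(selection = sel, pool = pool, manifest = manifest))
}

#' Write a synthetic fixture (genome, plan, input) to disk
#'
#' Generates a toy genome with [generate_toy_genome()] and writes
#' `genome.fa`, `plan.tsv` (contig, start, strand, mismatches) and
#' `input.fa` (the plus-strand region around the planted perfect-match
#' site, ready to use as design input).
#'
#' @param out Output directory.
#' @param guide Protospacer to plant.
#' @param plan Plant plan (see [generate_toy_genome()]).
#' @param nuclease,n_contigs,contig_len,seed Passed to
#'   [generate_toy_genome()].
#' @param input_flank Bases of genomic flank around the on-target site
#'   written to `input.fa`.
#' @return Invisibly, the [generate_toy_genome()] result.
#' @export
write_fixture <- function(out, guide, plan, nuclease = "spcas9",
                          n_contigs = 2L, contig_len = 3000L, seed = 1L,
                          input_flank = 150L) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  nuclease <- nuclease_profile(nuclease)
  fx <- generate_toy_genome(guide, plan, nuclease, n_contigs = n_contigs,
                            contig_len = contig_len, seed = seed)
  write_genome_fasta(fx$genome, file.path(out, "genome.fa"))
  readr::write_tsv(fx$sites[, c("contig", "start", "strand", "mismatches")],
                   file.path(out, "plan.tsv"), progress = FALSE)
  on_site <- fx$sites[fx$sites$mismatches == 0, ][1, ]
  S <- unclass(fx$genome)[[on_site$contig]]
  lo <- max(0L, on_site$start - input_flank)
  hi <- min(nchar(S), on_site$start + nchar(guide) + input_flank)
  readr::write_lines(c(">fixture_target", substr(S, lo + 1L, hi)),
                     file.path(out, "input.fa"))
  invisible(fx)
}
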