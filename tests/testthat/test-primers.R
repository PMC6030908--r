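test_that("nearest-neighbor Tm matches an independent hand evaluation", {
  # independent step-by-step sum straight off the shipped parameter file
  tbl <- readr::read_tsv(system.file("extdata", "nn_params.tsv",
                                     package = "guidecraft"),
                         comment = "#", show_col_types = FALSE)
  dH <- setNames(tbl$dH, tbl$dinucleotide)
  dS <- setNames(tbl$dS, tbl$dinucleotide)
  hand_tm <- function(s) {
    n <- nchar(s)
    h <- 0; sds <- 0
    for (i in 1:(n - 1)) {
      st <- substr(s, i, i + 1)
      h <- h + dH[[st]]; sds <- sds + dS[[st]]
    }
    for (term in c(substr(s, 1, 1), substr(s, n, n))) {
      key <- if (term %in% c("G", "C")) "init.GC" else "init.AT"
      h <- h + dH[[key]]; sds <- sds + dS[[key]]
    }
    1000 * h / (sds + 1.987 * log(50e-9 / 4)) - 273.15 + 16.6 * log10(0.05)
  }
  probe <- "ACGTGCTAGCTAGGCTAGCT"
  expect_equal(melting_temperature(probe), hand_tm(probe))
  withr::local_seed(121)
  for (i in 1:20) {
    s <- rand_seq(sample(8:36, 1))
    expect_equal(melting_temperature(s), hand_tm(s))
    # duplex symmetry
    expect_equal(melting_temperature(s), melting_temperature(revcomp(s)))
  }
  expect_error(melting_temperature("ACGTNCG"), class = "guidecraft_usage_error")
})

test_that("appending GC never lowers the Tm of a random primer", {
  withr::local_seed(131)
  for (i in 1:50) {
    s <- rand_seq(18)
    expect_true(melting_temperature(paste0(s, "GC")) >= melting_temperature(s))
  }
})

test_that("flanking primer pairs satisfy every stated constraint, deterministically", {
  withr::local_seed(141)
  gn <- genome_index(c(c1 = rand_seq(3000)))
  pr <- design_flanking_primers(gn, "c1", 1480, 1520, name_prefix = "33forw")
  S <- unclass(gn)[["c1"]]
  # substring identity on both strands
  expect_identical(substr(S, pr$left_start + 1, pr$left_start + nchar(pr$left_seq)),
                   pr$left_seq)
  expect_identical(revcomp(substr(S, pr$right_end - nchar(pr$right_seq) + 1,
                                  pr$right_end)), pr$right_seq)
  # product spans the site within the requested range
  expect_true(pr$left_start + nchar(pr$left_seq) <= 1480)
  expect_true(pr$right_end - nchar(pr$right_seq) >= 1520)
  expect_identical(pr$product_len, pr$right_end - pr$left_start)
  expect_true(pr$product_len >= 600 && pr$product_len <= 1000)
  # Tm tolerance, runs, 3' ends
  for (p in c(pr$left_seq, pr$right_seq)) {
    expect_true(abs(melting_temperature(p) - 60) <= 3)
    expect_false(grepl("AAAA|TTTT|GGGG|CCCC", p))
    expect_true(substr(p, nchar(p), nchar(p)) %in% c("G", "C"))
  }
  # determinism
  expect_identical(design_flanking_primers(gn, "c1", 1480, 1520,
                                           name_prefix = "33forw"), pr)
  # primer naming follows the guide id
  pt <- primer_table(pr)
  expect_setequal(pt$name, c("33forw_F", "33forw_R"))
  # no flank: explicit feasibility failure
  expect_error(design_flanking_primers(gn, "c1", 5, 30),
               class = "guidecraft_primer_error")
})

test_that("batch off-target primers conserve hits and amplify their sites", {
  fx <- generate_toy_genome(demo_guide,
                            data.frame(mismatches = c(0, 2, 4),
                                       strand = c("+", "-", "+")),
                            seed = 45, contig_len = 3000)
  hits <- find_offtargets(demo_guide, fx$genome,
                          tables = uniform_score_tables())
  batch <- offtarget_primer_batch(hits, fx$genome)
  expect_identical(nrow(batch$pairs) + nrow(batch$skipped), nrow(hits))
  ranked <- dplyr::arrange(hits, dplyr::desc(cfd), contig, start)
  for (i in seq_len(nrow(batch$pairs))) {
    p <- batch$pairs[i, ]
    h <- ranked[p$ot_rank, ]
    expect_true(p$product_len >= 200 && p$product_len <= 280)
    # the product contains its off-target site
    expect_true(p$left_start + nchar(p$left_seq) <= h$start)
    expect_true(p$right_end - nchar(p$right_seq) >= h$start + nchar(h$site_seq))
  }
  # an edge hit lands in the skip list
  edge_hits <- hits
  edge_hits$start <- 2L
  b2 <- offtarget_primer_batch(edge_hits[1, ], fx$genome)
  expect_identical(nrow(b2$pairs), 0L)
  expect_identical(nrow(b2$skipped), 1L)
  expect_match(b2$skipped$reason, "no feasible|flank")
})

test_that("CRISPResso manifests always contain the interrogated protospacer", {
  fx <- generate_toy_genome(demo_guide,
                            data.frame(mismatches = c(0, 3), strand = c("+", "-")),
                            seed = 47, contig_len = 3000)
  hits <- find_offtargets(demo_guide, fx$genome,
                          tables = uniform_score_tables())
  batch <- offtarget_primer_batch(hits, fx$genome)
  sites <- dplyr::arrange(hits, dplyr::desc(cfd), contig, start)$site_seq
  man <- crispresso_manifest(batch$pairs, fx$genome, sites[batch$pairs$ot_rank])
  expect_identical(nrow(man), nrow(batch$pairs))
  for (i in seq_len(nrow(man))) {
    expect_true(grepl(man$guide_seq[i], man$amplicon_seq[i], fixed = TRUE) ||
                  grepl(revcomp(man$guide_seq[i]), man$amplicon_seq[i],
                        fixed = TRUE))
  }
  # amplicons are rediscoverable at their genomic coordinates
  for (i in seq_len(nrow(batch$pairs))) {
    p <- batch$pairs[i, ]
    expect_identical(substr(unclass(fx$genome)[[p$contig]], p$left_start + 1,
                            p$right_end), man$amplicon_seq[i])
  }
  # a guide absent from the amplicon is a validation error
  expect_error(crispresso_manifest(batch$pairs, fx$genome, strrep("T", 20)),
               class = "guidecraft_validation_error")
})

test_that("cloning oligos apply promoter prefix rules and anneal correctly", {
  co_g <- cloning_oligos("GACGTAGCTAGCTAGGATCC", "bbsI_U6")
  expect_identical(co_g$fwd_oligo, paste0("ACCG", "GACGTAGCTAGCTAGGATCC"))
  co_a <- cloning_oligos("ACGTAGCTAGCTAGGATCCA", "bbsI_U6")
  expect_identical(nchar(co_a$insert), 21L)
  expect_identical(substr(co_a$insert, 1, 1), "G")
  # duplex identity: rev oligo minus overhang is the revcomp of the insert
  for (co in list(co_g, co_a)) {
    expect_identical(revcomp(sub("^AAAC", "", co$rev_oligo)), co$insert)
  }
  # T7 requires GG
  co_t7 <- cloning_oligos(c("GGACGTAGCTAGCTAGGATC", "GACGTAGCTAGCTAGGATCC",
                            "ACGTAGCTAGCTAGGATCCA"), "t7_invitro")
  expect_true(all(startsWith(co_t7$insert, "GG")))
  expect_identical(nchar(co_t7$insert), c(20L, 21L, 22L))
  expect_error(cloning_oligos("ACGT", "no_such_profile"),
               class = "guidecraft_usage_error")
})
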