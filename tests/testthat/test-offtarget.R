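toy_tables <- uniform_score_tables()

test_that("planted sites are recovered with exact mismatch counts and budgets apply", {
  plan <- data.frame(mismatches = c(0, 2, 4), strand = c("+", "-", "+"))
  fx <- generate_toy_genome(demo_guide, plan, seed = 13, contig_len = 2500)
  hits <- find_offtargets(demo_guide, fx$genome, tables = toy_tables)
  expect_identical(nrow(hits), 3L)
  expect_setequal(paste(hits$contig, hits$start, hits$strand, hits$mismatches),
                  paste(fx$sites$contig, fx$sites$start, fx$sites$strand,
                        fx$sites$mismatches))
  # budget subsets
  expect_identical(nrow(find_offtargets(demo_guide, fx$genome, max_mm = 0,
                                        tables = toy_tables)), 1L)
  expect_identical(nrow(find_offtargets(demo_guide, fx$genome, max_mm = 2,
                                        tables = toy_tables)), 2L)
  # mm_positions length agrees with the count
  expect_identical(hits$mismatches,
                   vapply(strsplit(hits$mm_positions, ","),
                          function(x) length(x[nzchar(x)]), integer(1)))
  expect_error(find_offtargets("ACGT", fx$genome), class = "guidecraft_usage_error")
})

test_that("fast scan equals the brute-force oracle on random genomes, all budgets", {
  withr::local_seed(61)
  for (i in 1:12) {
    gn <- genome_index(c(c1 = rand_seq(8000), c2 = rand_seq(4000)))
    gd <- rand_seq(20)
    mm <- (i - 1) %% 5
    a <- find_offtargets(gd, gn, max_mm = mm, tables = toy_tables)
    b <- brute_force_offtargets(gd, gn, max_mm = mm, tables = toy_tables)
    expect_identical(as.data.frame(a), as.data.frame(b))
  }
  # other nucleases, with planted sites so hit lists are non-trivial
  for (nuc in c("sacas9", "cpf1")) {
    prof <- nuclease_profile(nuc)
    gd <- rand_seq(prof$guide_len)
    fx <- generate_toy_genome(gd, data.frame(mismatches = c(0, 1, 3),
                                             strand = c("+", "-", "-")),
                              nuclease = prof, seed = 17, contig_len = 2500)
    a <- find_offtargets(gd, fx$genome, prof, tables = toy_tables)
    b <- brute_force_offtargets(gd, fx$genome, prof, tables = toy_tables)
    expect_identical(as.data.frame(a), as.data.frame(b))
    expect_setequal(a$mismatches, c(0L, 1L, 3L))
  }
})

test_that("genome Ns are never part of reported sites", {
  fx <- generate_toy_genome(demo_guide,
                            data.frame(mismatches = c(0, 1), strand = c("+", "+")),
                            seed = 23, contig_len = 1200)
  S <- unclass(fx$genome)[["c1"]]
  # mask one base inside the m=1 planted protospacer
  site <- fx$sites[fx$sites$mismatches == 1, ]
  substr(S, site$start + 3, site$start + 3) <- "N"
  gnN <- genome_index(c(c1 = S))
  hits <- find_offtargets(demo_guide, gnN, tables = toy_tables)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$mismatches, 0L)
  expect_identical(as.data.frame(hits),
                   as.data.frame(brute_force_offtargets(demo_guide, gnN,
                                                        tables = toy_tables)))
})

test_that("MIT hit score follows the damped product formula", {
  g <- strrep("A", 20)
  expect_equal(mit_hit_score(g, g, toy_tables), 100)
  # single mismatch at position p: 100 * (1 - W[p]) with uniform W = 0.5
  s1 <- paste0("C", strrep("A", 19))
  expect_equal(mit_hit_score(g, s1, toy_tables), 50)
  # two mismatches at 1 and 20: dbar = 19 -> distance term 1, 1/m^2 = 1/4
  s2 <- paste0("C", strrep("A", 18), "C")
  expect_equal(mit_hit_score(g, s2, toy_tables), 100 * 0.25 * 1 * 0.25)
  # adjacent mismatches at 10,11: dbar = 1 -> 1/(((19-1)/19)*4+1)
  s3 <- paste0(strrep("A", 9), "CC", strrep("A", 9))
  expect_equal(mit_hit_score(g, s3, toy_tables),
               100 * 0.25 / (((19 - 1) / 19) * 4 + 1) / 4)
  expect_error(mit_hit_score(g, "ACGT"), class = "guidecraft_usage_error")
})

test_that("CFD is a product of penalties and is 1 only for perfect canonical sites", {
  g <- strrep("A", 20)
  expect_equal(cfd_score(g, g, "AGG", toy_tables), 1)
  s1 <- paste0("C", strrep("A", 19))
  expect_equal(cfd_score(g, s1, "AGG", toy_tables), 0.5)
  s3 <- paste0("CCC", strrep("A", 17))
  expect_equal(cfd_score(g, s3, "AGG", toy_tables), 0.125)
  # non-canonical PAM caps the score below 1 even at zero mismatches
  expect_equal(cfd_score(g, g, "AAG", toy_tables), 0.5)
  # missing table entry is a configuration error naming the key
  broken <- uniform_score_tables()
  broken$cfd_mm_key <- broken$cfd_mm_key[names(broken$cfd_mm_key) != "1|A|C"]
  expect_error(cfd_score(g, s1, "AGG", broken), class = "guidecraft_config_error")
})

test_that("specificity aggregates hits and decreases monotonically", {
  expect_equal(specificity_score(numeric(0)), 100)
  expect_equal(specificity_score(100), 50)
  withr::local_seed(71)
  for (i in 1:20) {
    hits <- runif(sample(1:30, 1), 0, 100)
    s0 <- specificity_score(hits)
    expect_true(s0 <= 100 && s0 > 0)
    expect_true(specificity_score(c(hits, runif(1, 0.01, 100))) < s0)
    expect_equal(specificity_score(sample(hits)), s0)
  }
})

test_that("colour classes honour thresholds with yellow at the red boundary", {
  expect_identical(color_class(100), "green")
  expect_identical(color_class(0), "red")
  expect_identical(color_class(30), "yellow")
  expect_identical(color_class(50), "green")
  expect_identical(color_class(49.9), "yellow")
  expect_identical(color_class(29.9), "red")
})

test_that("hit filters match the interval-overlap oracle and compose", {
  withr::local_seed(81)
  fx <- generate_toy_genome(demo_guide,
                            data.frame(mismatches = c(0, 1, 2, 3, 4),
                                       strand = c("+", "-", "+", "-", "+")),
                            n_contigs = 2, seed = 27, contig_len = 2500)
  hits <- find_offtargets(demo_guide, fx$genome, tables = toy_tables)
  start <- sample.int(2400, 60)
  bed <- tibble::tibble(contig = sample(c("c1", "c2"), 60, TRUE),
                        start = start, end = start + sample.int(120, 60),
                        name = ".", strand = ".")
  ann <- filter_hits(hits, annotation = bed)
  expect_identical(ann$in_exon, oracle_in_exon(hits, bed))
  ex <- filter_hits(hits, annotation = bed, exonic_only = TRUE)
  expect_identical(nrow(ex), sum(oracle_in_exon(hits, bed)))
  sc <- filter_hits(hits, same_contig_only = TRUE, target_contig = "c1")
  expect_true(all(sc$contig == "c1"))
  both <- filter_hits(hits, annotation = bed, exonic_only = TRUE,
                      same_contig_only = TRUE, target_contig = "c1")
  expect_identical(nrow(both), sum(oracle_in_exon(hits, bed) & hits$contig == "c1"))
  expect_error(filter_hits(hits, exonic_only = TRUE),
               class = "guidecraft_usage_error")
})

test_that("on-target marking and the mismatch histogram exclude the submitted locus", {
  fx <- generate_toy_genome(demo_guide,
                            data.frame(mismatches = c(0, 0, 2), strand = c("+", "+", "-")),
                            seed = 33, contig_len = 2500)
  on <- fx$sites[fx$sites$mismatches == 0, ][1, ]
  hits <- find_offtargets(demo_guide, fx$genome, tables = toy_tables,
                          on_target = list(contig = on$contig, start = on$start,
                                           strand = on$strand))
  expect_identical(sum(hits$is_on_target), 1L)
  expect_identical(hits$start[hits$is_on_target], on$start)
  # the duplicate perfect site counts as an off-target
  expect_identical(mismatch_histogram(hits), "1-0-1-0-0")
  # histogram sums to the number of non-on-target hits
  expect_identical(sum(as.integer(strsplit(mismatch_histogram(hits), "-")[[1]])),
                   sum(!hits$is_on_target))
  # without a submitted locus, two perfect sites are ambiguous: none marked
  h2 <- find_offtargets(demo_guide, fx$genome, tables = toy_tables)
  expect_identical(sum(h2$is_on_target), 0L)
})
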