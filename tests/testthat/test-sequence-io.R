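test_that("FASTA reading normalises case, maps U/ambiguity codes, rejects bad files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 some description", "acgt"), f)
  g <- read_genome_fasta(f)
  expect_identical(unclass(g), c(c1 = "ACGT"))
  expect_identical(genome_lengths(g), c(c1 = 4L))

  writeLines(c(">c1", "ACGU", ">c2", "ACRT"), f)
  expect_warning(g2 <- read_genome_fasta(f), "mapped to N")
  expect_identical(unname(unclass(g2)), c("ACGT", "ACNT"))

  writeLines(c(">c1", "ACGT", ">c1", "AAAA"), f)
  expect_error(read_genome_fasta(f), class = "guidecraft_format_error")
  writeLines(character(0), f)
  expect_error(read_genome_fasta(f), class = "guidecraft_format_error")
})

test_that("FASTA write/read round-trips a 50 kb genome exactly", {
  withr::local_seed(101)
  g <- genome_index(c(chrA = rand_seq(50000), chrB = rand_seq(1234)))
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  g2 <- read_genome_fasta(f)
  expect_identical(unclass(g2), unclass(g))
})

test_that("input parsing records case, Ns, strips numbering, validates", {
  s <- parse_input_sequence(paste0("ACGTacgtNN", strrep("A", 13)))
  expect_identical(which(s$case_mask), 5:8)
  expect_identical(s$n_positions, c(8L, 9L))
  expect_identical(substr(s$seq, 1, 10), "ACGTACGTNN")

  s2 <- parse_input_sequence("1 ACGT\n2 TTTT", min_len = 8)
  expect_identical(s2$seq, "ACGTTTTT")

  expect_error(parse_input_sequence("ACGTXZ"), class = "guidecraft_usage_error")
  expect_error(parse_input_sequence("ACGT"), class = "guidecraft_usage_error")

  # FASTA input, single record only; header names the sequence
  s3 <- parse_input_sequence(">tgt descr\nACGTACGTACGTACGTACGTACG")
  expect_identical(s3$name, "tgt")
  expect_error(parse_input_sequence(">a\nACGT\n>b\nACGT"),
               class = "guidecraft_format_error")

  # planted Ns recovered at planted offsets
  withr::local_seed(7)
  base <- rand_seq(100)
  at <- sort(sample(100, 3))
  sc <- strsplit(base, "")[[1]]; sc[at] <- "N"
  s4 <- parse_input_sequence(paste(sc, collapse = ""))
  expect_identical(s4$n_positions, as.integer(at - 1))

  # uppercase inputs have an empty case mask
  expect_false(any(parse_input_sequence(toupper(base))$case_mask))
})

test_that("BED parsing keeps half-open intervals, errors carry line numbers", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t10\t20\tex1\t0\t+", f)
  b <- read_bed(f)
  expect_identical(b$start, 10L)
  expect_identical(b$end, 20L)
  expect_identical(b$strand, "+")

  writeLines(c("c1\t5\t9", "c1\t20\t10"), f)
  expect_error(read_bed(f), "line 2", class = "guidecraft_format_error")
  writeLines("c1\tx\t10", f)
  expect_error(read_bed(f), "line 1", class = "guidecraft_format_error")

  # round trip of random intervals
  withr::local_seed(5)
  n <- 100
  start <- sample.int(1e6, n)
  bed <- tibble::tibble(contig = sample(c("c1", "c2"), n, TRUE),
                        start = start, end = start + sample.int(500, n),
                        name = paste0("iv", seq_len(n)),
                        strand = sample(c("+", "-", "."), n, TRUE))
  write_bed(bed, f)
  expect_identical(as.data.frame(read_bed(f)), as.data.frame(bed))
})

test_that("toy genomes are deterministic and carry exactly the planted sites", {
  plan <- data.frame(mismatches = c(0, 2, 4), strand = c("+", "-", "+"))
  fx1 <- generate_toy_genome(demo_guide, plan, seed = 3, contig_len = 2000)
  fx2 <- generate_toy_genome(demo_guide, plan, seed = 3, contig_len = 2000)
  expect_identical(unclass(fx1$genome), unclass(fx2$genome))
  expect_identical(as.data.frame(fx1$sites), as.data.frame(fx2$sites))

  # the brute-force scan recovers the plan exactly
  hits <- brute_force_offtargets(demo_guide, fx1$genome,
                                 tables = uniform_score_tables())
  expect_setequal(paste(hits$contig, hits$start, hits$strand, hits$mismatches),
                  paste(fx1$sites$contig, fx1$sites$start, fx1$sites$strand,
                        fx1$sites$mismatches))
  expect_setequal(hits$mismatches, c(0L, 2L, 4L))

  # single perfect site by construction
  one <- generate_toy_genome(demo_guide,
                             data.frame(mismatches = 0, strand = "+"),
                             seed = 9, contig_len = 500)
  expect_identical(nrow(one$sites), 1L)
  h1 <- brute_force_offtargets(demo_guide, one$genome, max_mm = 0,
                               tables = uniform_score_tables())
  expect_identical(h1$start, one$sites$start)
})
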