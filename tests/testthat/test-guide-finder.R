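test_that("IUPAC matching agrees with set-membership enumeration over all 6-mers", {
  expect_true(iupac_match("NGG", "AGG"))
  expect_true(iupac_match("NNGRRT", "ATGAGT"))
  expect_false(iupac_match("NNGRRT", "ATGACT"))
  expect_error(iupac_match("QGG", "AGG"), class = "guidecraft_config_error")

  bases <- c("A", "C", "G", "T")
  all6 <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases, bases,
                                      stringsAsFactors = FALSE))
  for (pat in c("TTTVNN", "NNGRRT")) {
    got <- iupac_match(pat, all6)
    want <- vapply(all6, oracle_iupac_match, logical(1), pattern = pat,
                   USE.NAMES = FALSE)
    expect_identical(got, want)
  }
  # sequence N matches no class, not even pattern N
  expect_false(iupac_match("NGG", "NGG"))
})

test_that("guide scanning matches construction and is strand-symmetric", {
  s23 <- "GTTTAGAGCTAGAAATAGCAAGG"
  g <- scan_guides(s23)
  expect_identical(nrow(g), 1L)
  expect_identical(g$protospacer, substr(s23, 1, 20))
  expect_identical(g$pam_seq, "AGG")
  expect_identical(g$strand, "+")
  expect_identical(g$guide_id, "21forw")

  g2 <- scan_guides(revcomp(s23))
  expect_identical(g2$strand, "-")
  expect_identical(g2$protospacer, g$protospacer)
})

test_that("guide scan equals the exhaustive double-loop oracle on random fixtures", {
  withr::local_seed(21)
  for (nuc in c("spcas9", "sacas9", "cpf1")) {
    prof <- nuclease_profile(nuc)
    s <- rand_seq(2000)
    got <- scan_guides(s, prof, enzymes = NULL)
    want <- oracle_scan_guides(s, prof)
    key <- function(d) sort(paste(d$start, d$strand, d$protospacer, d$pam_seq))
    expect_identical(key(got), key(want))
    # every emitted PAM satisfies the profile pattern; minus PAMs too
    expect_true(all(iupac_match(prof$pam, got$pam_seq)))
    # reverse-complement symmetry: protospacer multiset with strands swapped
    rcg <- scan_guides(revcomp(s), prof, enzymes = NULL)
    expect_identical(sort(got$protospacer[got$strand == "+"]),
                     sort(rcg$protospacer[rcg$strand == "-"]))
    expect_identical(sort(got$protospacer), sort(rcg$protospacer))
  }
})

test_that("flags follow the GC/TTTT/N rules and N-overlapping guides are hidden", {
  gg <- paste0(strrep("G", 20), "AGG")
  expect_match(scan_guides(gg, enzymes = NULL)$flags, "HIGH_GC")
  at <- paste0("ATATATATATATTTTTATAT", "AGG")
  f <- scan_guides(at, enzymes = NULL)
  expect_match(f$flags[f$strand == "+"][1], "LOW_GC")
  expect_match(f$flags[f$strand == "+"][1], "TTTT")

  # plant an N inside exactly one guide's protospacer
  withr::local_seed(31)
  s <- rand_seq(300)
  guides_all <- scan_guides(s, enzymes = NULL)
  pick <- guides_all[guides_all$strand == "+", ][1, ]
  sc <- strsplit(s, "")[[1]]
  sc[pick$start + 5] <- "N"
  masked <- paste(sc, collapse = "")
  with_n <- scan_guides(masked, enzymes = NULL, include_n_overlaps = TRUE)
  flagged <- with_n[grepl("OVERLAPS_N", with_n$flags), ]
  expect_true(pick$guide_id %in% flagged$guide_id)
  # all flagged guides genuinely cover the masked base or lost their PAM
  deflt <- scan_guides(masked, enzymes = NULL)
  expect_false(any(grepl("OVERLAPS_N", deflt$flags)))
  expect_false(pick$guide_id %in% deflt$guide_id)
})

test_that("prefix filtering keeps exactly the guides starting with the prefix", {
  withr::local_seed(41)
  g <- scan_guides(rand_seq(1500), enzymes = NULL)
  for (mode in c("G-", "GG-", "A-")) {
    kept <- prefix_filter(g, mode)
    pre <- sub("-$", "", mode)
    expect_identical(kept$guide_id,
                     g$guide_id[startsWith(g$protospacer, pre)])
  }
  expect_identical(prefix_filter(g, "none"), g)
  expect_error(prefix_filter(g, "T-"), class = "guidecraft_usage_error")
})

test_that("restriction screening requires a unique cut-spanning site", {
  enz <- default_enzymes()
  # GAATTC occupies offsets 21..26 and spans the cut at offset 24
  ctx <- paste0(strrep("CAT", 7), "GAATTC", strrep("TCA", 9))
  expect_identical(restriction_overlap(ctx, 24, enz), "EcoRI")
  # duplicated site: no longer usable as a screen
  ctx2 <- paste0("GAATTC", strrep("CAT", 5), "GAATTC", strrep("TCA", 9))
  expect_identical(restriction_overlap(ctx2, 24, enz), character(0))

  withr::local_seed(51)
  for (i in 1:50) {
    ctx <- rand_seq(50)
    expect_identical(restriction_overlap(ctx, 25, enz),
                     oracle_restriction(ctx, 25, enz))
  }
})

test_that("Cpf1 profile scans 5'-side TTTV PAMs with 23-nt guides", {
  s <- paste0("TTTA", strrep("ACGTG", 5), "ACG")  # TTTV then 23 bases + spare
  g <- scan_guides(paste0(s, strrep("C", 10)), "cpf1", enzymes = NULL)
  plus <- g[g$strand == "+" & g$pam_start1 == 1, ]
  expect_identical(plus$pam_seq, "TTTA")
  expect_identical(nchar(plus$protospacer), 23L)
  expect_identical(plus$start, 4L)
})
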