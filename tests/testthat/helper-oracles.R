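# Independent reference implementations used as oracles. These are written
# from first principles (plain loops, own IUPAC map) and must not call into
# the package's scanning internals.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rc_str <- function(x) {
  # independent reverse complement (no IUPAC needed for ACGTN fixtures)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_iupac_match <- function(pattern, s) {
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  if (length(pc) != length(sc)) return(FALSE)
  all(vapply(seq_along(pc), function(k) sc[k] %in% ORACLE_IUPAC[[pc[k]]],
             logical(1)))
}

# exhaustive position-by-position guide scan on one strand of a string;
# returns protospacer starts (0-based, in the scanned string's coordinates)
oracle_scan_one <- function(s, pam, guide_len, pam_side) {
  pl <- nchar(pam); L <- nchar(s)
  out <- list()
  for (w0 in 0:(L - guide_len - pl)) {
    if (pam_side == "3p") {
      proto <- substr(s, w0 + 1, w0 + guide_len)
      pamseq <- substr(s, w0 + guide_len + 1, w0 + guide_len + pl)
      p0 <- w0
    } else {
      pamseq <- substr(s, w0 + 1, w0 + pl)
      proto <- substr(s, w0 + pl + 1, w0 + pl + guide_len)
      p0 <- w0 + pl
    }
    if (oracle_iupac_match(pam, pamseq) && !grepl("N", proto, fixed = TRUE)) {
      out[[length(out) + 1]] <- list(start = p0, protospacer = proto,
                                     pam_seq = pamseq)
    }
  }
  out
}

# both-strand guide scan oracle: tibble of (start, strand, protospacer, pam_seq)
oracle_scan_guides <- function(s, profile) {
  L <- nchar(s)
  g <- profile$guide_len
  fw <- oracle_scan_one(s, profile$pam, g, profile$pam_side)
  rv <- oracle_scan_one(rc_str(s), profile$pam, g, profile$pam_side)
  rows <- c(
    lapply(fw, function(x) tibble::tibble(start = x$start, strand = "+",
                                          protospacer = x$protospacer,
                                          pam_seq = x$pam_seq)),
    lapply(rv, function(x) tibble::tibble(start = L - x$start - g, strand = "-",
                                          protospacer = x$protospacer,
                                          pam_seq = x$pam_seq))
  )
  dplyr::bind_rows(rows)
}

# quadratic enzyme-site scan: all offsets x all enzymes, both strands
oracle_restriction <- function(context, cut, enzymes) {
  hits <- character(0)
  for (i in seq_len(nrow(enzymes))) {
    site <- enzymes$site[i]; len <- nchar(site)
    occ <- integer(0)
    for (off in 0:(nchar(context) - len)) {
      sub <- substr(context, off + 1, off + len)
      if (oracle_iupac_match(site, sub) ||
            oracle_iupac_match(site, rc_str(sub))) {
        occ <- c(occ, off)
      }
    }
    if (length(occ) == 1 && occ < cut && occ + len > cut) {
      hits <- c(hits, enzymes$name[i])
    }
  }
  hits
}

# exhaustive microhomology enumeration with the same dedup rule, written
# as plain nested loops
oracle_microhomologies <- function(context, cut, window = 30, min_len = 2) {
  L <- nchar(context)
  lo <- max(0, cut - window); hi <- min(L, cut + window)
  pats <- list()
  if (cut - min_len < lo || hi - min_len < cut) {
    return(tibble::tibble(left_start = integer(), right_start = integer(),
                          length = integer(), deletion_len = integer(),
                          mh_seq = character()))
  }
  for (a in lo:(cut - min_len)) {
    if (a < lo) next
    for (b in cut:(hi - min_len)) {
      maxlen <- min(cut - a, hi - b)
      if (maxlen < min_len) next
      for (len in min_len:maxlen) {
        sa <- substr(context, a + 1, a + len)
        sb <- substr(context, b + 1, b + len)
        if (sa == sb && b - a > 0) {
          pats[[length(pats) + 1]] <- list(left_start = a, right_start = b,
                                           length = len, deletion_len = b - a,
                                           mh_seq = sa)
        }
      }
    }
  }
  if (length(pats) == 0) {
    return(tibble::tibble(left_start = integer(), right_start = integer(),
                          length = integer(), deletion_len = integer(),
                          mh_seq = character()))
  }
  df <- dplyr::bind_rows(lapply(pats, tibble::as_tibble))
  # collapse identical (mh_seq, deletion_len) to the leftmost occurrence
  df <- df[order(df$left_start), ]
  df <- df[!duplicated(df[, c("mh_seq", "deletion_len")]), ]
  keep <- vapply(seq_len(nrow(df)), function(i) {
    for (j in seq_len(nrow(df))) {
      if (j != i && df$deletion_len[j] == df$deletion_len[i] &&
            df$length[j] > df$length[i] &&
            grepl(df$mh_seq[i], df$mh_seq[j], fixed = TRUE)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  df <- df[keep, ]
  df[order(df$deletion_len, df$left_start),
     c("left_start", "right_start", "length", "deletion_len", "mh_seq")]
}

oracle_oof <- function(context, cut, window = 30, min_len = 2) {
  p <- oracle_microhomologies(context, cut, window, min_len)
  if (nrow(p) == 0) return(NA_real_)
  sc <- vapply(seq_len(nrow(p)), function(i) {
    gc <- nchar(gsub("[^GC]", "", p$mh_seq[i]))
    at <- nchar(p$mh_seq[i]) - gc
    100 * round(exp(-p$deletion_len[i] / 20), 3) * (2 * gc + at)
  }, numeric(1))
  100 * sum(sc[p$deletion_len %% 3 != 0]) / sum(sc)
}

# quadratic interval-overlap oracle for hit filtering
oracle_in_exon <- function(hits, bed) {
  vapply(seq_len(nrow(hits)), function(i) {
    s <- hits$start[i]; e <- s + nchar(hits$site_seq[i])
    any(bed$contig == hits$contig[i] & bed$start < e & bed$end > s)
  }, logical(1))
}

hit_key <- function(h) {
  paste(h$contig, h$start, h$strand, h$mismatches, h$site_seq, h$pam_seq,
        sep = "/")
}

# build a repeat-free context (no microhomology of min_len within window)
repeat_free_context <- function(len, cut, window = 30, min_len = 2,
                                max_tries = 200) {
  for (i in seq_len(max_tries)) {
    ctx <- rand_seq(len)
    if (nrow(oracle_microhomologies(ctx, cut, window, min_len)) == 0) {
      return(ctx)
    }
  }
  stop("could not build a repeat-free context")
}

demo_subpools <- function() {
  tibble::tibble(id = c("sp1", "sp2"),
                 fwd_barcode = c("ACCTGAAC", "GTTCGCAA"),
                 rev_barcode = c("TGGTCTGC", "CAACGGAT"))
}

demo_guide <- "GACGTAGCTAGCTAGGATCC"

demo_fixture_cfg <- function(dir, seed = 11L, ...) {
  write_fixture(file.path(dir, "fx"), demo_guide,
                data.frame(mismatches = c(0, 2, 4), strand = c("+", "-", "+")),
                seed = seed)
  run_config(genome = file.path(dir, "fx", "genome.fa"),
             input = file.path(dir, "fx", "input.fa"),
             out = file.path(dir, "out"), ...)
}
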