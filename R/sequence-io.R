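#' Genome container
#'
#' A `genome_index` is a named character vector of uppercase contig
#' sequences over the alphabet {A,C,G,T,N}. IUPAC ambiguity codes and any
#' other letters are mapped to N (and are never matched by guides or PAMs);
#' U is mapped to T.
#'
#' @param contigs Named character vector of DNA sequences.
#' @return A `genome_index` object.
#' @export
#' @examples
#' g <- genome_index(c(chr1 = "acgtACGT"))
#' genome_lengths(g)
genome_index <- function(contigs) {
  if (length(contigs) == 0 || is.null(names(contigs)) || any(names(contigs) == "")) {
    abort("genome_index: contigs must be a non-empty named character vector",
          class = "guidecraft_format_error")
  }
  if (anyDuplicated(names(contigs))) {
    dup <- names(contigs)[duplicated(names(contigs))][1]
    abort(sprintf("duplicate contig name '%s'", dup),
          class = "guidecraft_format_error")
  }
  seqs <- toupper(contigs)
  seqs <- chartr("U", "T", seqs)
  other <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(other)) {
    warning(sprintf("%d contig(s) contain non-ACGTN letters; mapped to N",
                    sum(other)), call. = FALSE)
    seqs[other] <- gsub("[^ACGTN]", "N", seqs[other])
  }
  structure(seqs, class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> %d contig(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in head(names(x), 10)) {
    cat(sprintf("  %s: %d bp\n", nm, nchar(x[[nm]])))
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @rdname genome_index
#' @param genome A `genome_index`.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

#' Read a genome from FASTA
#'
#' Records are keyed by the first whitespace-delimited token of the header.
#' Sequences are uppercased, U mapped to T, and any other non-ACGTN letter
#' mapped to N with a warning.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A [genome_index].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "guidecraft_usage_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("not a valid FASTA file: %s (%s)", path,
                                      conditionMessage(e)),
                              class = "guidecraft_format_error")
  )
  if (length(set) == 0) {
    abort(sprintf("FASTA file has no records: %s", path),
          class = "guidecraft_format_error")
  }
  seqs <- as.character(set)
  names(seqs) <- stringr::word(names(set), 1)
  genome_index(seqs)
}

#' Write a genome to FASTA (60-column wrap)
#'
#' @param genome A [genome_index].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Parse a target/input sequence
#'
#' Accepts a plain pasted sequence (whitespace and line numbers are
#' stripped, so numbered GenBank-style dumps paste cleanly) or a
#' single-record FASTA. Lowercase letters are meaningful: they mark regions
#' the user wants to keep track of and are recorded in `case_mask`. `N`
#' bases mark variant positions; their 0-based offsets are recorded in
#' `n_positions` and guides overlapping them are dropped downstream. IUPAC
#' ambiguity codes are mapped to N and masked the same way.
#'
#' @param text Raw sequence text (possibly multi-line, possibly FASTA).
#' @param name Optional sequence name; a FASTA header wins over this.
#' @param min_len Minimum accepted length (default 23, one SpCas9 site).
#' @return An `input_seq` list with fields `name`, `seq` (uppercase),
#'   `case_mask` (logical per base), `n_positions` (0-based integer).
#' @export
#' @examples
#' s <- parse_input_sequence("ACGTacgtNNACGTACGTACGTACG")
#' s$n_positions
parse_input_sequence <- function(text, name = NULL, min_len = 23L) {
  text <- paste(text, collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) > 0 && startsWith(trimws(lines[1]), ">")) {
    extra <- which(startsWith(trimws(lines[-1]), ">"))
    if (length(extra) > 0) {
      abort("input sequence must be plain text or single-record FASTA",
            class = "guidecraft_format_error")
    }
    name <- stringr::word(sub("^>", "", trimws(lines[1])), 1)
    lines <- lines[-1]
  }
  raw <- paste(lines, collapse = "")
  raw <- gsub("[0-9[:space:]]", "", raw)
  if (stringr::str_detect(raw, "[^ACGTURYSWKMBDHVNacgturyswkmbdhvn]")) {
    abort("input sequence contains non-IUPAC characters",
          class = "guidecraft_usage_error")
  }
  if (nchar(raw) < min_len) {
    abort(sprintf("input sequence too short (%d < %d bases)", nchar(raw), min_len),
          class = "guidecraft_usage_error")
  }
  case_mask <- seq_chars(raw) %in% c(letters)
  up <- chartr("U", "T", toupper(raw))
  up <- gsub("[^ACGTN]", "N", up)
  n_positions <- which(seq_chars(up) == "N") - 1L
  structure(
    list(name = name %||% "input", seq = up, case_mask = case_mask,
         n_positions = as.integer(n_positions)),
    class = "input_seq"
  )
}

#' @export
print.input_seq <- function(x, ...) {
  cat(sprintf("<input_seq> %s: %d bp, %d lowercase, %d N-masked\n",
              x$name, nchar(x$seq), sum(x$case_mask), length(x$n_positions)))
  invisible(x)
}

#' Read exon annotation from BED
#'
#' BED3+ (tab-separated), 0-based half-open, preserved exactly. Lines
#' starting with `#`, `track` or `browser` are skipped. Missing name/strand
#' become `"."`.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `contig`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("BED file not found: %s", path), class = "guidecraft_usage_error")
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  name = character(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED line %d has fewer than 3 tab-separated fields",
                  lineno[which(nf < 3)[1]]), class = "guidecraft_format_error")
  }
  get <- function(i, default) map_chr(fields, function(f) {
    if (length(f) >= i && nzchar(f[i])) f[i] else default
  })
  start_chr <- get(2, ""); end_chr <- get(3, "")
  bad_int <- !grepl("^[0-9]+$", start_chr) | !grepl("^[0-9]+$", end_chr)
  if (any(bad_int)) {
    abort(sprintf("BED line %d has non-integer coordinates", lineno[which(bad_int)[1]]),
          class = "guidecraft_format_error")
  }
  start <- as.integer(start_chr); end <- as.integer(end_chr)
  bad_ord <- start >= end
  if (any(bad_ord)) {
    abort(sprintf("BED line %d has start >= end", lineno[which(bad_ord)[1]]),
          class = "guidecraft_format_error")
  }
  strand <- get(6, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  tibble(contig = get(1, "."), start = start, end = end,
         name = get(4, "."), strand = strand)
}

#' Write exon annotation to BED6
#'
#' @param annotation Tibble as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotation, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", annotation$contig,
                   annotation$start, annotation$end, annotation$name,
                   annotation$strand)
  readr::write_lines(lines, path)
  invisible(path)
}
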