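read_nn_table <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  stopifnot(all(c("dinucleotide", "dH", "dS") %in% names(tb)))
  list(dH = stats::setNames(tb$dH, tb$dinucleotide),
       dS = stats::setNames(tb$dS, tb$dinucleotide))
}

default_nn_table <- function() {
  if (is.null(the$nn)) {
    the$nn <- read_nn_table(system.file("extdata", "nn_params.tsv",
                                        package = "guidecraft", mustWork = TRUE))
  }
  the$nn
}

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm from a nearest-neighbor enthalpy/entropy sum over dinucleotide
#' steps plus terminal initiation terms (the unified parameter set shipped
#' as `inst/extdata/nn_params.tsv`; dH in kcal/mol, dS in cal/(K*mol)):
#' `Tm = 1000*dH / (dS + R*ln(C/4)) - 273.15 + 16.6*log10([Na+])`
#' with R = 1.987 cal/(K*mol), primer concentration `C` and monovalent salt
#' `[Na+]`.
#'
#' @param seq Character vector of primer sequences (ACGT, 8-36 bases).
#' @param conc_nM Primer concentration in nM (default 50).
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param nn Thermodynamic table from [read_nn_table] internals; default the
#'   shipped unified set.
#' @return Numeric vector of Tm values in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("ACGTGCTAGCTAGGCTAGCT")
melting_temperature <- function(seq, conc_nM = 50, na_mM = 50,
                                nn = default_nn_table()) {
  seq <- toupper(seq)
  if (any(nchar(seq) < 8 | nchar(seq) > 36)) {
    abort("primer length must be 8..36 bases", class = "guidecraft_usage_error")
  }
  assert_dna(seq, "primer", allow = "ACGT")
  rln <- 1.987 * log(conc_nM * 1e-9 / 4)
  salt <- 16.6 * log10(na_mM * 1e-3)
  vapply(seq, function(s) {
    n <- nchar(s)
    steps <- substring(s, 1:(n - 1L), 2:n)
    init <- paste0("init.", ifelse(c(substr(s, 1, 1), substr(s, n, n)) %in%
                                     c("G", "C"), "GC", "AT"))
    dH <- sum(nn$dH[steps]) + sum(nn$dH[init])
    dS <- sum(nn$dS[steps]) + sum(nn$dS[init])
    1000 * dH / (dS + rln) - 273.15 + salt
  }, numeric(1), USE.NAMES = FALSE)
}
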