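BUILTIN_NUCLEASES <- list(
  spcas9 = list(
    name = "spcas9", pam = "NGG", pam_side = "3p", guide_len = 20L,
    # cut 3 bp 5' of the PAM: blunt cut between protospacer positions 17/18
    cut_offset = -3L, blunt = TRUE, alt_pams = c("NAG", "NGA")
  ),
  sacas9 = list(
    name = "sacas9", pam = "NNGRRT", pam_side = "3p", guide_len = 20L,
    cut_offset = -3L, blunt = TRUE, alt_pams = character(0)
  ),
  cpf1 = list(
    name = "cpf1", pam = "TTTV", pam_side = "5p", guide_len = 23L,
    # staggered, PAM-distal cut; the protospacer-strand nick after base 18
    # is used as the reference cut for primers and microhomology
    cut_offset = 18L, blunt = FALSE, alt_pams = character(0)
  )
)

#' Nuclease profiles
#'
#' A profile bundles everything position-dependent about a nuclease: the PAM
#' IUPAC pattern and which side of the protospacer it sits on, the guide
#' (protospacer) length, the reference cut position, whether the cut is
#' blunt, and the alternative PAMs tolerated during off-target scanning.
#'
#' Built-ins: `spcas9` (NGG, 3' PAM, 20-nt guide, blunt cut 3 bp 5' of the
#' PAM, off-target alt PAMs NAG/NGA), `sacas9` (NNGRRT, 3' PAM, 20-nt guide),
#' `cpf1` (TTTV, 5' PAM, 23-nt guide, staggered PAM-distal cut).
#'
#' @param name Profile name (case-insensitive) or a profile list to validate.
#' @return A `nuclease_profile` list.
#' @export
#' @examples
#' nuclease_profile("spcas9")$pam
nuclease_profile <- function(name = "spcas9") {
  if (is.list(name)) {
    prof <- name
  } else {
    prof <- BUILTIN_NUCLEASES[[tolower(name)]]
    if (is.null(prof)) {
      abort(sprintf("unknown nuclease '%s' (built-ins: %s)", name,
                    paste(names(BUILTIN_NUCLEASES), collapse = ", ")),
            class = "guidecraft_usage_error")
    }
  }
  stopifnot(nchar(prof$pam) >= 1, prof$guide_len >= 17,
            prof$pam_side %in% c("3p", "5p"))
  structure(prof, class = "nuclease_profile")
}

#' @export
print.nuclease_profile <- function(x, ...) {
  cat(sprintf("<nuclease_profile> %s: PAM %s (%s of protospacer), guide %d nt, %s cut\n",
              x$name, x$pam, if (x$pam_side == "3p") "3'" else "5'",
              x$guide_len, if (x$blunt) "blunt" else "staggered"))
  invisible(x)
}

#' @rdname nuclease_profile
#' @export
list_nucleases <- function() names(BUILTIN_NUCLEASES)

# number of protospacer bases 5' (guide orientation) of the cut
cut_index <- function(profile) {
  if (profile$pam_side == "3p") profile$guide_len + profile$cut_offset
  else profile$cut_offset
}
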