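#' Cloning profiles and annealed-oligo design
#'
#' A cloning profile describes how a protospacer becomes a pair of
#' overlapping oligos for guide expression: 4-base sticky-end overhangs for
#' ligation into the digested vector, and a 5'-prefix rule imposed by the
#' expression promoter. `add_G_if_absent` prepends one G unless the guide
#' already starts with G (U6 needs a 5' G; prepending instead of mutating
#' avoids introducing a mismatching base only when necessary);
#' `require_GG` prepends G until the insert starts with GG (T7 in vitro
#' transcription); `none` leaves the protospacer unchanged.
#'
#' Built-ins: `bbsI_U6` (overhangs ACCG/AAAC, `add_G_if_absent`) and
#' `t7_invitro` (generic placeholder overhangs TATA/AAAC, `require_GG`);
#' register your vector's own overhangs with `register_cloning_profile()`.
#'
#' @param name Profile name.
#' @param fwd_overhang,rev_overhang 4-base overhang sequences.
#' @param prepend_g_rule One of `"none"`, `"add_G_if_absent"`,
#'   `"require_GG"`.
#' @return `register_cloning_profile()` returns `name` invisibly;
#'   `cloning_profile()` returns the profile list.
#' @export
register_cloning_profile <- function(name, fwd_overhang, rev_overhang,
                                     prepend_g_rule = "none") {
  if (nchar(fwd_overhang) != 4 || nchar(rev_overhang) != 4) {
    abort("overhangs must be 4 bases", class = "guidecraft_config_error")
  }
  if (!prepend_g_rule %in% c("none", "add_G_if_absent", "require_GG")) {
    abort("unknown prepend_g_rule", class = "guidecraft_config_error")
  }
  the$cloning_profiles[[name]] <- list(name = name, fwd_overhang = fwd_overhang,
                                       rev_overhang = rev_overhang,
                                       prepend_g_rule = prepend_g_rule)
  invisible(name)
}

#' @rdname register_cloning_profile
#' @export
cloning_profile <- function(name) {
  p <- the$cloning_profiles[[name]]
  if (is.null(p)) {
    abort(sprintf("unknown cloning profile '%s' (registered: %s)", name,
                  paste(list_cloning_profiles(), collapse = ", ")),
          class = "guidecraft_usage_error")
  }
  p
}

#' @rdname register_cloning_profile
#' @export
list_cloning_profiles <- function() names(the$cloning_profiles)

register_default_cloning_profiles <- function() {
  the$cloning_profiles <- list()
  register_cloning_profile("bbsI_U6", "ACCG", "AAAC", "add_G_if_absent")
  register_cloning_profile("t7_invitro", "TATA", "AAAC", "require_GG")
}

# apply a profile's promoter prefix rule to a protospacer
adjust_insert <- function(protospacer, prepend_g_rule) {
  switch(prepend_g_rule,
    none = protospacer,
    add_G_if_absent = ifelse(startsWith(protospacer, "G"), protospacer,
                             paste0("G", protospacer)),
    require_GG = {
      out <- protospacer
      fix <- !startsWith(out, "GG")
      out[fix] <- ifelse(startsWith(out[fix], "G"), paste0("G", out[fix]),
                         paste0("GG", out[fix]))
      out
    },
    abort("unknown prepend_g_rule", class = "guidecraft_config_error")
  )
}

#' Overlapping oligos for guide cloning
#'
#' The forward oligo is the profile's forward overhang plus the
#' prefix-adjusted protospacer; the reverse oligo is the reverse overhang
#' plus the reverse complement of the same insert. Annealed, the two oligos
#' form a duplex whose insert region is exactly the adjusted protospacer
#' with the vector's sticky ends.
#'
#' @param protospacer Guide sequence(s), 5'->3'.
#' @param profile Cloning profile name or list (see
#'   [register_cloning_profile()]).
#' @return Tibble with columns `protospacer`, `insert`, `fwd_oligo`,
#'   `rev_oligo`.
#' @export
#' @examples
#' cloning_oligos("ATCGATCGATCGATCGATCG", "bbsI_U6")
cloning_oligos <- function(protospacer, profile = "bbsI_U6") {
  if (is.character(profile)) profile <- cloning_profile(profile)
  insert <- adjust_insert(protospacer, profile$prepend_g_rule)
  tibble(
    protospacer = protospacer,
    insert = insert,
    fwd_oligo = paste0(profile$fwd_overhang, insert),
    rev_oligo = paste0(profile$rev_overhang, revcomp(insert))
  )
}
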