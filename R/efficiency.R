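#' Efficiency model registry
#'
#' On-target efficiency scoring is pluggable: a model is a function
#' `f(protospacer, context, cut_in_context)` returning a score that is
#' clamped to \[0, 100\], plus the number of context bases it needs on each
#' side of the protospacer (guides lacking that context get `NA`, reported
#' as unavailable rather than 0).
#'
#' The built-in default, `"pam_proximal_gc"`, is fully specified and needs
#' no trained coefficients:
#' `100 * (0.2 + 0.6 * GC10/10 + 0.2 * [terminal PAM-proximal base is G])`
#' where `GC10` is the GC count of the ten PAM-proximal protospacer bases.
#' It encodes two robust observations — PAM-proximal GC content and a
#' terminal G correlate with activity — and spans \[20, 100\].
#' Experimentally trained linear models (e.g. one-hot coefficient sets) can
#' be registered from a TSV via [register_linear_model()].
#'
#' @param name Model name (unique in the registry).
#' @param fn Scoring function `f(protospacer, context, cut_in_context)`.
#' @param required_context Context bases needed on each side (0 = none).
#' @return `register_efficiency_model()` returns `name` invisibly.
#' @export
register_efficiency_model <- function(name, fn, required_context = 0L) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  the$eff_models[[name]] <- list(name = name, fn = fn,
                                 required_context = as.integer(required_context))
  invisible(name)
}

#' @rdname register_efficiency_model
#' @export
list_efficiency_models <- function() names(the$eff_models)

eff_model_get <- function(name) {
  m <- the$eff_models[[name]]
  if (is.null(m)) {
    abort(sprintf("unknown efficiency model '%s' (registered: %s)", name,
                  paste(list_efficiency_models(), collapse = ", ")),
          class = "guidecraft_usage_error")
  }
  m
}

pam_proximal_gc_fn <- function(pam_side) {
  force(pam_side)
  function(protospacer, context, cut_in_context) {
    g <- nchar(protospacer)
    prox10 <- if (pam_side == "3p") substr(protospacer, g - 9L, g)
              else substr(protospacer, 1L, 10L)
    term <- if (pam_side == "3p") substr(protospacer, g, g)
            else substr(protospacer, 1L, 1L)
    gc10 <- stringr::str_count(prox10, "[GC]")
    100 * (0.2 + 0.6 * gc10 / 10 + 0.2 * (term == "G"))
  }
}

#' Register a linear one-hot efficiency model from a coefficient TSV
#'
#' The file is tab-separated with columns `position` (1-based within the
#' protospacer), `base` and `weight`; a row with `position == 0` and
#' `base == "*"` is the intercept. The raw score is the intercept plus the
#' sum of the weights of the observed (position, base) pairs, clamped to
#' \[0, 100\].
#'
#' @param name Registry name for the model.
#' @param path Path to the coefficient TSV.
#' @return `name`, invisibly.
#' @export
register_linear_model <- function(name, path) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("position", "base", "weight") %in% names(tb))) {
    abort("coefficient table needs columns position, base, weight",
          class = "guidecraft_config_error")
  }
  intercept <- sum(tb$weight[tb$position == 0 & tb$base == "*"])
  coef_key <- stats::setNames(tb$weight, paste(tb$position, tb$base, sep = "|"))
  fn <- function(protospacer, context, cut_in_context) {
    keys <- paste(seq_len(nchar(protospacer)), seq_chars(protospacer), sep = "|")
    vals <- coef_key[keys]
    vals[is.na(vals)] <- 0
    intercept + sum(vals)
  }
  register_efficiency_model(name, fn, required_context = 0L)
}

#' Score guides with a registered efficiency model
#'
#' @param guides Guide tibble from [scan_guides()].
#' @param model Registered model name (default `"pam_proximal_gc"`).
#' @return `guides` with an `eff_score` column in \[0, 100\] (NA when the
#'   model's required context is unavailable).
#' @export
efficiency_score <- function(guides, model = "pam_proximal_gc") {
  m <- eff_model_get(model)
  guides$eff_score <- pmap_dbl(
    list(guides$protospacer, guides$context),
    function(proto, ctx) {
      if (m$required_context > 0 && is.na(ctx)) return(NA_real_)
      s <- m$fn(proto, ctx, if (is.na(ctx)) NA_integer_ else nchar(ctx) %/% 2L)
      min(max(s, 0), 100)
    }
  )
  guides
}

# default models are registered at load time (per nuclease PAM side the
# "PAM-proximal" ten bases differ, so the model reads the profile side from
# the protospacer orientation set at registration)
register_default_models <- function() {
  the$eff_models <- list()
  register_efficiency_model("pam_proximal_gc", pam_proximal_gc_fn("3p"))
  register_efficiency_model("pam_proximal_gc_5p", pam_proximal_gc_fn("5p"))
}
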