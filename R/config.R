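# cli_config: one validated configuration document covering every module
# parameter, with documented defaults. Values follow defaults < YAML file <
# direct overrides; unknown keys are rejected.

.tdmd_defaults <- list(
  # pairing / search
  window = 30L, three_prime_start = 9L, match_point = 1, end_bonus = 0.5,
  terminal_wobble_bonus = 0.5, interruption_point = 1, offset_free = 3L,
  offset_point = 0.5, min_tpm = 1,
  # energy
  energy_backend = "builtin",
  # small-RNA quantification
  prefix_len = 19L, alpha = 0.05, min_log2fc = 0,
  # target repression
  repression_min_tpm = 10, top_fraction = 0.10, iterations = 21L,
  # randomness
  seed = 1L)

#' Assemble a validated run configuration
#'
#' Defaults carry the pipeline's documented parameter values (30-nt search
#' window, 19-nt read prefix, 10-TPM repression filter, 10% top-target
#' fraction, 21 resampling iterations, ...). A YAML file and then direct
#' `...` overrides are layered on top. Unknown keys raise an error naming
#' the key; types must match the default's type.
#'
#' @param path Optional YAML file of overrides.
#' @param ... Direct overrides, e.g. `window = 25`.
#' @return A `tdmd_config` list.
#' @export
tdmd_config <- function(path = NULL, ...) {
  cfg <- .tdmd_defaults
  apply_overrides <- function(cfg, over, origin) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      .stopf("unknown configuration key(s) in %s: %s", origin,
             paste(unknown, collapse = ", "))
    }
    for (k in names(over)) {
      v <- over[[k]]
      if (is.numeric(cfg[[k]]) && !is.numeric(v)) {
        .stopf("configuration key '%s' must be numeric", k)
      }
      if (is.character(cfg[[k]]) && !is.character(v)) {
        .stopf("configuration key '%s' must be character", k)
      }
      cfg[[k]] <- if (is.integer(cfg[[k]])) as.integer(v) else v
    }
    cfg
  }
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    if (length(over)) cfg <- apply_overrides(cfg, over, path)
  }
  dots <- list(...)
  if (length(dots)) cfg <- apply_overrides(cfg, dots, "arguments")
  structure(cfg, class = "tdmd_config")
}

#' Score parameters carried by a configuration
#'
#' @param config A [tdmd_config()].
#' @return The corresponding [score_params()].
#' @export
config_score_params <- function(config = tdmd_config()) {
  score_params(match_point = config$match_point, end_bonus = config$end_bonus,
               terminal_wobble_bonus = config$terminal_wobble_bonus,
               interruption_point = config$interruption_point,
               offset_free = config$offset_free,
               offset_point = config$offset_point, window = config$window,
               three_prime_start = config$three_prime_start)
}

#' Write the effective configuration next to an output file
#'
#' @param config A [tdmd_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.tdmd_config <- function(x, ...) {
  cat("tdmdscout configuration:\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
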