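# duplex_energy: minimum free energy of intermolecular hybridization between
# the miRNA 3' region and the site window, used as an orthogonal ranking
# metric next to the point score. The embedded model is a reduced
# nearest-neighbor set (WCF + G:U stacks, affine bulge/internal-loop
# penalties, duplex initiation, terminal AU/GU penalty) shipped as packaged
# TSV tables; it targets ranking behavior, not thermodynamic fidelity.
# An external RNAduplex executable can be selected as an alternate backend.

#' Load the reduced nearest-neighbor duplex energy model
#'
#' @param stack_path,loop_path Paths to the parameter tables; defaults to the
#'   tables shipped with the package.
#' @return An `energy_model` list: `stacks` (6x6 matrix over pair types AU,
#'   CG, GC, UA, GU, UG, kcal/mol) and the loop/initiation parameters.
#' @export
energy_model <- function(stack_path = system.file("extdata", "stack_energies.tsv",
                                                  package = "tdmdscout"),
                         loop_path = system.file("extdata", "loop_params.tsv",
                                                 package = "tdmdscout")) {
  st <- utils::read.delim(stack_path)
  types <- c("AU", "CG", "GC", "UA", "GU", "UG")
  stacks <- matrix(NA_real_, 6, 6, dimnames = list(types, types))
  stacks[cbind(match(st$pair5, types), match(st$pair3, types))] <- st$kcal_mol
  if (anyNA(stacks)) .stopf("incomplete stack-energy table")
  wc <- c("AU", "CG", "GC", "UA")
  if (any(stacks[wc, wc] > 0)) .stopf("WCF/WCF stack energies must be <= 0")
  lp <- utils::read.delim(loop_path)
  pars <- stats::setNames(lp$value, lp$param)
  structure(list(stacks = stacks,
                 duplex_initiation = pars[["duplex_initiation"]],
                 terminal_au_penalty = pars[["terminal_au_penalty"]],
                 bulge_base = pars[["bulge_base"]],
                 bulge_ext = pars[["bulge_ext"]],
                 internal_base = pars[["internal_base"]],
                 internal_ext = pars[["internal_ext"]],
                 internal_asym = pars[["internal_asym"]],
                 max_loop = as.integer(pars[["max_loop"]])),
            class = "energy_model")
}

#' Minimum free energy of an RNA-RNA duplex
#'
#' Considers intermolecular pairs only (no intramolecular structure).
#' Returns the no-duplex sentinel (`energy = NA`, `no_duplex = TRUE`) when
#' no pairing arrangement has energy below initiation alone.
#'
#' @param seq_a,seq_b RNA sequences, both 5'->3'.
#' @param model An [energy_model()].
#' @param backend `"builtin"` (embedded model) or `"external"` (an
#'   `RNAduplex` executable on the PATH, reported verbatim).
#' @return List with `energy` (kcal/mol), `pairs` (two-column matrix of
#'   1-based paired positions in `seq_a`/`seq_b`), and `no_duplex`.
#' @export
duplex_mfe <- function(seq_a, seq_b, model = energy_model(),
                       backend = c("builtin", "external")) {
  backend <- match.arg(backend)
  .rna_validate(seq_a, "seq_a")
  .rna_validate(seq_b, "seq_b")
  if (!nzchar(seq_a) || !nzchar(seq_b)) .stopf("sequences must be non-empty")
  if (backend == "external") return(.duplex_external(seq_a, seq_b))
  # DP pairs a[i] with b[j] antiparallel: i ascends while j descends
  res <- dp_duplex(.rna_codes(seq_a), .rna_codes(seq_b), model$stacks,
                   model$duplex_initiation, model$terminal_au_penalty,
                   model$bulge_base, model$bulge_ext, model$internal_base,
                   model$internal_ext, model$internal_asym, model$max_loop)
  if (isTRUE(res$no_duplex)) {
    return(list(energy = NA_real_, pairs = cbind(i = integer(), j = integer()),
                no_duplex = TRUE))
  }
  list(energy = round(res$energy, 2),
       pairs = cbind(i = res$i, j = res$j), no_duplex = FALSE)
}

.duplex_external <- function(seq_a, seq_b) {
  exe <- Sys.which("RNAduplex")
  if (!nzchar(exe)) .stopf("RNAduplex executable not found on PATH")
  out <- system2(exe, args = "--noLP",
                 input = paste0(seq_a, "\n", seq_b, "\n"), stdout = TRUE)
  line <- out[length(out)]
  en <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\).*", "\\1", line))
  if (is.na(en)) .stopf("could not parse RNAduplex output: %s", line)
  list(energy = en, pairs = cbind(i = integer(), j = integer()),
       no_duplex = FALSE)
}

#' Duplex energy of a candidate site
#'
#' Hybridizes the miRNA 3' region (positions `three_prime_start`..L) against
#' the same upstream window used by the pairing scorer and reports the
#' minimum free energy, or `NA` for the no-duplex sentinel / an empty window.
#'
#' @inheritParams score_configuration
#' @param model An [energy_model()].
#' @param backend See [duplex_mfe()].
#' @return Energy in kcal/mol (scalar), or `NA`.
#' @export
energy_for_candidate <- function(mirna_seq, region_seq, seed_start,
                                 params = score_params(),
                                 model = energy_model(),
                                 backend = "builtin") {
  win <- .site_window(seed_start, params)
  if (win["end"] <= win["start"]) return(NA_real_)
  three_prime <- substr(mirna_seq, params$three_prime_start, nchar(mirna_seq))
  wseq <- substr(region_seq, win["start"] + 1L, win["end"])
  duplex_mfe(three_prime, wseq, model = model, backend = backend)$energy
}
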