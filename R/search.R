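# trigger_search: the two search branches, the expression filter, and
# per-miRNA ranking of candidates.
#
# The de novo branch scans every expressed 3' UTR / lncRNA for canonical
# seed matches and scores each; the conserved branch scores externally
# provided (e.g. TargetScan-conserved) sites without rescanning. Ranking is
# by total 3'-pairing score, descending, within each miRNA; duplex energy is
# reported as an orthogonal column and used only to break score ties, with
# transcript id and seed position as final deterministic tie-breaks.

#' Filter transcript regions by mean expression
#'
#' Gene-level TPM is averaged across the samples of `expression`; genes
#' absent from the table count as unexpressed (0 TPM). With
#' `expression = NULL` the `tpm` column of `regions` is used directly.
#'
#' @param regions Region data frame (see [transcript_regions()]).
#' @param expression Long expression table (`gene_id`, `sample_id`, `tpm`)
#'   or `NULL`.
#' @param min_tpm Minimum mean TPM to retain a region.
#' @return The retained regions, with their `tpm` column set to the mean.
#' @export
filter_expression <- function(regions, expression = NULL, min_tpm = 1) {
  if (!is.null(expression)) {
    mean_tpm <- tapply(expression$tpm, expression$gene_id, mean)
    tp <- mean_tpm[regions$gene_id]
    regions$tpm <- unname(ifelse(is.na(tp), 0, tp))
  }
  out <- regions[regions$tpm >= min_tpm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.score_one_site <- function(mirna, region, seed_start, seed_end, site_type,
                            branch, params, model, backend) {
  cfg <- best_configuration(mirna$sequence, region$sequence, seed_start,
                            params = params)
  en <- energy_for_candidate(mirna$sequence, region$sequence, seed_start,
                             params = params, model = model,
                             backend = backend)
  data.frame(mirna_id = mirna$mirna_id, transcript_id = region$transcript_id,
             gene_id = region$gene_id, site_type = site_type,
             seed_start = seed_start, seed_end = seed_end,
             score = cfg$total_score,
             base_points = cfg$breakdown[["base_points"]],
             end_bonus = cfg$breakdown[["end_bonus"]],
             terminal_wobble_bonus = cfg$breakdown[["terminal_wobble_bonus"]],
             interruption_penalty = cfg$breakdown[["interruption_penalty"]],
             offset_penalty = cfg$breakdown[["offset_penalty"]],
             offset = if (is.na(cfg$offset)) NA_integer_ else cfg$offset,
             duplex_energy_kcal_mol = en, tpm = region$tpm, branch = branch,
             pairing_string = .encode_pairs(cfg))
}

.rank_candidates <- function(df) {
  if (nrow(df) == 0L) {
    df$rank <- integer()
    return(df)
  }
  pieces <- split(df, list(df$mirna_id, df$branch), drop = TRUE)
  ranked <- lapply(pieces, function(p) {
    en <- ifelse(is.na(p$duplex_energy_kcal_mol), Inf,
                 p$duplex_energy_kcal_mol)
    o <- order(-p$score, en, p$transcript_id, p$seed_start)
    p <- p[o, , drop = FALSE]
    p$rank <- seq_len(nrow(p))
    p
  })
  out <- do.call(rbind, ranked)
  out <- out[order(out$mirna_id, out$branch, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' De novo search branch: scan expressed regions for scored seed matches
#'
#' @param mirnas miRNA data frame (see [mirna_set()]).
#' @param regions Region data frame.
#' @param expression Optional expression table for [filter_expression()].
#' @param min_tpm Expression threshold (mean TPM).
#' @param site_types Canonical site types to scan for.
#' @param params [score_params()].
#' @param model [energy_model()].
#' @param backend Energy backend, see [duplex_mfe()].
#' @return Ranked candidate data frame (one row per seed match on an
#'   expressed transcript; `rank` is 1..n per miRNA).
#' @export
run_denovo_branch <- function(mirnas, regions, expression = NULL, min_tpm = 1,
                              site_types = c("6mer", "7mer-A1", "7mer-m8", "8mer"),
                              params = score_params(), model = energy_model(),
                              backend = "builtin") {
  regions <- filter_expression(regions, expression, min_tpm)
  rows <- list()
  for (mi in seq_len(nrow(mirnas))) {
    mirna <- mirnas[mi, , drop = FALSE]
    for (ri in seq_len(nrow(regions))) {
      region <- regions[ri, , drop = FALSE]
      matches <- find_seed_matches(mirna, region, site_types = site_types)
      for (si in seq_len(nrow(matches))) {
        m <- matches[si, ]
        rows[[length(rows) + 1L]] <-
          .score_one_site(mirna, region, m$seed_start, m$seed_end,
                          m$site_type, "denovo", params, model, backend)
      }
    }
  }
  if (length(rows) == 0L) return(.empty_candidates())
  .rank_candidates(do.call(rbind, rows))
}

#' Conserved-sites branch: score externally annotated sites
#'
#' Each provided site is scored in place (no rescanning); sites on
#' transcripts below the expression threshold are dropped; sites with
#' coordinates outside their transcript are skipped with a warning.
#'
#' @param sites Data frame with `mirna_id`, `transcript_id`, `seed_start`,
#'   `seed_end`, `site_type`.
#' @inheritParams run_denovo_branch
#' @return Ranked candidate data frame.
#' @export
run_conserved_branch <- function(sites, regions, mirnas, expression = NULL,
                                 min_tpm = 1, params = score_params(),
                                 model = energy_model(), backend = "builtin") {
  regions <- filter_expression(regions, expression, min_tpm)
  rows <- list()
  for (si in seq_len(nrow(sites))) {
    s <- sites[si, ]
    mirna <- mirnas[mirnas$mirna_id == s$mirna_id, , drop = FALSE]
    region <- regions[regions$transcript_id == s$transcript_id, , drop = FALSE]
    if (nrow(mirna) == 0L) {
      .warnf("site row %d: unknown mirna_id '%s', skipped", si, s$mirna_id)
      next
    }
    if (nrow(region) == 0L) next   # unexpressed or unknown transcript
    if (s$seed_start < 0L || s$seed_end > nchar(region$sequence) ||
        s$seed_end - s$seed_start != 6L) {
      .warnf("site row %d: coordinates outside transcript '%s', skipped",
             si, s$transcript_id)
      next
    }
    rows[[length(rows) + 1L]] <-
      .score_one_site(mirna[1, , drop = FALSE], region[1, , drop = FALSE],
                      s$seed_start, s$seed_end, s$site_type, "conserved",
                      params, model, backend)
  }
  if (length(rows) == 0L) return(.empty_candidates())
  .rank_candidates(do.call(rbind, rows))
}

.empty_candidates <- function() {
  data.frame(mirna_id = character(), transcript_id = character(),
             gene_id = character(), site_type = character(),
             seed_start = integer(), seed_end = integer(), score = numeric(),
             base_points = numeric(), end_bonus = numeric(),
             terminal_wobble_bonus = numeric(),
             interruption_penalty = numeric(), offset_penalty = numeric(),
             offset = integer(), duplex_energy_kcal_mol = numeric(),
             tpm = numeric(), branch = character(),
             pairing_string = character(), rank = integer())
}
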