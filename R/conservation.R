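# conservation: re-score a trigger site across species from a multiple
# alignment and flag covariation events.
#
# Per-species mature miRNAs are obtained by alignment projection of the
# reference mature interval; per-species sites by projection of the site
# interval. Every species is then scored with the identical pipeline used
# for the reference, and positions where both the miRNA base and its target
# partner changed are reported with their pairing status.

# map reference source coordinates [start, end) to alignment column range
.ref_columns <- function(block, ref_interval) {
  ref <- block$text[[block$ref]]
  chars <- .rna_chars(ref)
  notgap <- chars != "-"
  refpos <- cumsum(notgap) - 1L + block$start[[block$ref]]  # 0-based source pos
  refpos[!notgap] <- NA_integer_
  lo <- ref_interval[1]
  hi <- ref_interval[2]
  span <- block$start[[block$ref]] + c(0L, block$size[[block$ref]])
  if (lo < span[1] || hi > span[2] || lo >= hi) {
    .stopf("interval [%d, %d) outside alignment block span [%d, %d)",
           lo, hi, span[1], span[2])
  }
  cols <- which(!is.na(refpos) & refpos >= lo & refpos < hi)
  seq.int(min(cols), max(cols))
}

#' Extract per-species site sequences from an alignment block
#'
#' Alignment columns covering the reference interval are sliced and gaps
#' stripped per species. Species whose slice is entirely gapped are reported
#' with `missing = TRUE` (empty sequence), never silently dropped. An
#' insertion in a non-reference species makes that species' site longer than
#' the reference's.
#'
#' @param block A `maf_block` (see [read_maf()]).
#' @param ref_interval 0-based half-open interval in reference source
#'   coordinates.
#' @return Data frame with `species`, `sequence`, `missing`.
#' @export
extract_species_site <- function(block, ref_interval) {
  cols <- .ref_columns(block, ref_interval)
  seqs <- vapply(block$text, function(s) {
    gsub("-", "", paste(.rna_chars(s)[cols], collapse = ""), fixed = TRUE)
  }, character(1))
  data.frame(species = names(seqs), sequence = unname(seqs),
             missing = !nzchar(seqs))
}

#' Project the reference mature miRNA onto each aligned species
#'
#' The aligned columns of the reference mature interval are sliced per
#' species, gap-stripped and T-to-U normalized. Species whose projected
#' mature differs in length from the reference by more than 2 nt are
#' flagged low-confidence.
#'
#' @param block A `maf_block` over the miRNA locus.
#' @param ref_interval 0-based half-open reference interval of the mature
#'   miRNA (sense strand).
#' @return Data frame with `species`, `sequence`, `low_confidence`,
#'   `missing`.
#' @export
predict_species_mirna <- function(block, ref_interval) {
  out <- extract_species_site(block, ref_interval)
  out$sequence <- chartr("T", "U", out$sequence)
  ref_len <- nchar(out$sequence[out$species == block$ref])
  out$low_confidence <- abs(nchar(out$sequence) - ref_len) > 2L
  out
}

#' Re-score a trigger site across species
#'
#' For each species, the projected site sequence is rescanned for a seed
#' match of the cognate (projected) miRNA and the best 3'-pairing
#' configuration is scored with the same parameters as the reference.
#' `seed_intact` requires a site of the same-or-stronger canonical type as
#' the reference (set `seed_policy = "any"` to accept any canonical type).
#'
#' @param site_block `maf_block` over the site locus.
#' @param site_interval Reference interval covering the site: the upstream
#'   pairing window plus the seed match (and t1 position, if present).
#' @param mirna_block `maf_block` over the miRNA locus.
#' @param mirna_interval Reference interval of the mature miRNA.
#' @param ref_site_type Site type of the reference site (e.g. `"8mer"`).
#' @param params [score_params()].
#' @param seed_policy `"same_or_stronger"` or `"any"`.
#' @return A `conservation_profile`: data frame with one row per species
#'   (`species`, `site_sequence`, `mirna_sequence`, `total_score`,
#'   `seed_intact`, `missing`, `low_confidence`), with the reference species
#'   in attribute `"ref"`.
#' @export
score_across_species <- function(site_block, site_interval, mirna_block,
                                 mirna_interval, ref_site_type = "6mer",
                                 params = score_params(),
                                 seed_policy = c("same_or_stronger", "any")) {
  seed_policy <- match.arg(seed_policy)
  sites <- extract_species_site(site_block, site_interval)
  mirnas <- predict_species_mirna(mirna_block, mirna_interval)
  species <- union(sites$species, mirnas$species)
  min_rank <- if (seed_policy == "any") 1L else .site_type_rank[[ref_site_type]]
  rows <- lapply(species, function(sp) {
    st <- sites[sites$species == sp, ]
    mr <- mirnas[mirnas$species == sp, ]
    if (nrow(st) == 0L) st <- data.frame(sequence = "", missing = TRUE)
    if (nrow(mr) == 0L) {
      mr <- data.frame(sequence = "", missing = TRUE, low_confidence = TRUE)
    }
    row <- data.frame(species = sp, site_sequence = st$sequence,
                      mirna_sequence = mr$sequence, total_score = NA_real_,
                      seed_intact = FALSE, missing = st$missing | mr$missing,
                      low_confidence = mr$low_confidence)
    if (row$missing || nchar(mr$sequence) < 8L) return(row)
    m <- find_seed_matches(mr$sequence, st$sequence)
    if (nrow(m)) {
      row$seed_intact <- any(.site_type_rank[m$site_type] >= min_rank)
      scores <- vapply(m$seed_start, function(ss) {
        best_configuration(mr$sequence, st$sequence, ss,
                           params = params)$total_score
      }, numeric(1))
      row$total_score <- max(scores)
    } else {
      row$total_score <- 0
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, ref = site_block$ref, class = c("conservation_profile",
                                                 class(out)))
}

#' Detect covariation between miRNA and site substitutions
#'
#' For each paired position of the reference configuration, finds species
#' where both the miRNA base and its target partner differ from the
#' reference, and reports whether the substituted pair still base-pairs
#' (WCF or G:U). A substitution on only one side is not an event.
#'
#' @param site_block,site_interval,mirna_block,mirna_interval As in
#'   [score_across_species()].
#' @param ref_pairs Reference configuration pairs: data frame with
#'   `mirna_pos` (1-based in the reference mature) and `site_pos` (0-based in
#'   the reference site interval).
#' @return Data frame with one row per (miRNA position, alternative pair):
#'   `mirna_pos`, `species` (comma-separated), `ref_mirna_base`,
#'   `ref_site_base`, `alt_mirna_base`, `alt_site_base`,
#'   `pairing_preserved`.
#' @export
detect_covariation <- function(site_block, site_interval, mirna_block,
                               mirna_interval, ref_pairs) {
  scols <- .ref_columns(site_block, site_interval)
  mcols <- .ref_columns(mirna_block, mirna_interval)
  sref <- .rna_chars(site_block$text[[site_block$ref]])
  mref <- .rna_chars(mirna_block$text[[mirna_block$ref]])
  # columns of ungapped reference positions within each interval
  s_ref_cols <- scols[sref[scols] != "-"]
  m_ref_cols <- mcols[mref[mcols] != "-"]
  species <- intersect(names(site_block$text), names(mirna_block$text))
  species <- setdiff(species, site_block$ref)
  events <- list()
  for (k in seq_len(nrow(ref_pairs))) {
    mp <- ref_pairs$mirna_pos[k]
    sp_pos <- ref_pairs$site_pos[k]
    mcol <- m_ref_cols[mp]
    scol <- s_ref_cols[sp_pos + 1L]
    rm <- mref[mcol]
    rs <- sref[scol]
    for (sp in species) {
      am <- .rna_chars(mirna_block$text[[sp]])[mcol]
      as_ <- .rna_chars(site_block$text[[sp]])[scol]
      if (am %in% c("-", "N") || as_ %in% c("-", "N")) next
      if (am != rm && as_ != rs) {
        key <- paste(mp, am, as_, sep = "|")
        if (is.null(events[[key]])) {
          events[[key]] <- data.frame(
            mirna_pos = mp, species = sp, ref_mirna_base = rm,
            ref_site_base = rs, alt_mirna_base = am, alt_site_base = as_,
            pairing_preserved = !is.na(.pair_class(am, as_)))
        } else {
          events[[key]]$species <- paste(events[[key]]$species, sp, sep = ",")
        }
      }
    }
  }
  if (length(events) == 0L) {
    return(data.frame(mirna_pos = integer(), species = character(),
                      ref_mirna_base = character(), ref_site_base = character(),
                      alt_mirna_base = character(), alt_site_base = character(),
                      pairing_preserved = logical()))
  }
  out <- do.call(rbind, unname(events))
  out[order(out$mirna_pos), , drop = FALSE]
}
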