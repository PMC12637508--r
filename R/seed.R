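# seed_scan: canonical seed-match enumeration.
#
# A canonical site pairs miRNA nucleotides 2-7 (the seed); pairing to
# nucleotide 8 (m8) and/or an A across from nucleotide 1 (A1) upgrade the
# site: 8mer (m8 + A1) > 7mer-m8 > 7mer-A1 > 6mer. Each 6mer-core occurrence
# is reported once, labeled with the maximal supported type.

.site_type_rank <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)

#' Target strings recognized by each canonical site type
#'
#' @param mirna_seq Mature miRNA sequence (>= 8 nt, RNA).
#' @return Named character vector with elements `6mer`, `7mer-m8`, `7mer-A1`,
#'   `8mer`: the exact target subsequences (sense strand, 5'->3') that each
#'   site type requires.
#' @export
seed_site_strings <- function(mirna_seq) {
  .rna_validate(mirna_seq, "miRNA sequence")
  if (nchar(mirna_seq) < 8L) .stopf("miRNA must be at least 8 nt for seed-site strings")
  six <- rc_rna(substr(mirna_seq, 2L, 7L))
  sevenm8 <- rc_rna(substr(mirna_seq, 2L, 8L))
  c("6mer" = six, "7mer-m8" = sevenm8,
    "7mer-A1" = paste0(six, "A"), "8mer" = paste0(sevenm8, "A"))
}

#' Find all canonical seed matches of a miRNA in a transcript region
#'
#' Every occurrence of the 6mer seed core (reverse complement of miRNA
#' nucleotides 2-7) is reported exactly once with the maximal site type it
#' supports. Coordinates are 0-based half-open over the 6 core-pairing target
#' nucleotides. Overlapping occurrences at distinct coordinates are all kept.
#'
#' @param mirna One-row miRNA data frame (see [mirna_set()]) or a bare RNA
#'   string.
#' @param region One-row region data frame (see [transcript_regions()]) or a
#'   bare RNA string.
#' @param site_types Site types to report (default: all four canonical types).
#' @return Data frame with columns `mirna_id`, `transcript_id`, `site_type`,
#'   `seed_start`, `seed_end`, `t1_is_A`, `m8_paired`.
#' @export
find_seed_matches <- function(mirna, region,
                              site_types = c("6mer", "7mer-A1", "7mer-m8", "8mer")) {
  if (is.character(mirna)) mirna <- mirna_set("mirna", mirna)
  if (is.character(region)) {
    region <- transcript_regions("region", sequence = region)
  }
  seq <- region$sequence[1]
  core <- seed_site_strings(mirna$sequence[1])[["6mer"]]
  hits <- Biostrings::start(Biostrings::matchPattern(core, Biostrings::BString(seq)))
  out <- data.frame(mirna_id = character(), transcript_id = character(),
                    site_type = character(), seed_start = integer(),
                    seed_end = integer(), t1_is_A = logical(),
                    m8_paired = logical())
  if (length(hits) == 0L) return(out)
  seed_start <- as.integer(hits) - 1L          # to 0-based
  seed_end <- seed_start + 6L
  n <- nchar(seq)
  m8c <- .wc_complement(substr(mirna$sequence[1], 8L, 8L))
  t1_is_A <- seed_end < n & substring(seq, seed_end + 1L, seed_end + 1L) == "A"
  m8_paired <- seed_start >= 1L & substring(seq, seed_start, seed_start) == m8c
  site_type <- ifelse(m8_paired & t1_is_A, "8mer",
                      ifelse(m8_paired, "7mer-m8",
                             ifelse(t1_is_A, "7mer-A1", "6mer")))
  out <- data.frame(mirna_id = mirna$mirna_id[1],
                    transcript_id = region$transcript_id[1],
                    site_type = site_type, seed_start = seed_start,
                    seed_end = seed_end, t1_is_A = t1_is_A,
                    m8_paired = m8_paired)
  out <- out[out$site_type %in% site_types, , drop = FALSE]
  rownames(out) <- NULL
  out
}
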