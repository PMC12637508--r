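# io_formats: readers and writers for FASTA, MAF and the pipeline's tables.
# All machine coordinates are 0-based, half-open, on the transcript sense
# strand; miRNA positions in pairing output are 1-based from the 5' end.

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Sequences are upper-cased; under `alphabet_policy = "dna_to_rna"` any T is
#' converted to U. Identifiers are the first whitespace-delimited token of the
#' header line. An alphabet violation is reported with the offending file line.
#'
#' @param path Path to a FASTA file.
#' @param alphabet_policy `"rna"` (strict A/C/G/U) or `"dna_to_rna"`
#'   (T accepted and normalized to U).
#' @return A data frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path, alphabet_policy = c("rna", "dna_to_rna")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(data.frame(id = character(), sequence = character()))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    .stopf("malformed FASTA in %s: line %d does not start a record", path, nonblank[1])
  }
  allowed <- if (alphabet_policy == "dna_to_rna") "[^ACGUT]" else "[^ACGU]"
  for (k in nonblank) {
    ln <- trimws(lines[k])
    if (startsWith(ln, ">")) next
    if (grepl(allowed, toupper(ln))) {
      .stopf("disallowed character in %s at line %d", path, k)
    }
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  if (alphabet_policy == "dna_to_rna") seqs <- chartr("T", "U", seqs)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  data.frame(id = unname(ids), sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x Data frame with `id` and `sequence` columns, or a named character
#'   vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- data.frame(id = names(x), sequence = unname(x))
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read mature miRNA sequences from FASTA
#'
#' Enforces the mature-miRNA invariants: unique identifiers, lengths in
#' \[16, 30\] and a strict RNA alphabet after T-to-U normalization.
#'
#' @param path FASTA of mature miRNAs (RNA or DNA alphabet).
#' @param species Species label attached to every entry.
#' @return A data frame with columns `mirna_id`, `species`, `sequence`,
#'   `cluster_id`, `partners` (comma-separated co-transcribed normalization
#'   partners, empty by default).
#' @export
read_mirna_fasta <- function(path, species = NA_character_) {
  fa <- read_fasta(path, alphabet_policy = "dna_to_rna")
  mirna_set(fa$id, fa$sequence, species = species)
}

#' Construct a mature miRNA set
#'
#' @param mirna_id Character vector of unique identifiers.
#' @param sequence RNA sequences, 5'->3'.
#' @param species Optional species label(s).
#' @param cluster_id Optional cluster labels (co-transcribed groups).
#' @param partners Optional comma-separated normalization partner ids.
#' @return A validated miRNA data frame (see [read_mirna_fasta()]).
#' @export
mirna_set <- function(mirna_id, sequence, species = NA_character_,
                      cluster_id = NA_character_, partners = "") {
  if (anyDuplicated(mirna_id)) {
    .stopf("duplicated mirna_id: %s",
           paste(unique(mirna_id[duplicated(mirna_id)]), collapse = ", "))
  }
  sequence <- chartr("T", "U", toupper(sequence))
  .rna_validate(sequence, "miRNA sequence")
  n <- nchar(sequence)
  if (any(n < 16L | n > 30L)) {
    .stopf("miRNA length outside [16, 30]: %s",
           paste(mirna_id[n < 16L | n > 30L], collapse = ", "))
  }
  data.frame(mirna_id = mirna_id, species = species, sequence = sequence,
             cluster_id = cluster_id, partners = partners)
}

#' Construct transcript regions (3' UTRs or lncRNAs)
#'
#' @param transcript_id,gene_id Identifiers.
#' @param region_kind `"UTR3"` or `"lncRNA"`.
#' @param sequence Sense-strand RNA sequence, 5'->3'.
#' @param tpm Non-negative expression level (transcripts per million).
#' @return A validated region data frame.
#' @export
transcript_regions <- function(transcript_id, gene_id = transcript_id,
                               region_kind = "UTR3", sequence, tpm = 0) {
  if (!all(region_kind %in% c("UTR3", "lncRNA"))) {
    .stopf("region_kind must be 'UTR3' or 'lncRNA'")
  }
  sequence <- chartr("T", "U", toupper(sequence))
  .rna_validate(sequence, "region sequence")
  if (any(!nzchar(sequence))) .stopf("empty region sequence")
  if (any(tpm < 0)) .stopf("negative TPM")
  data.frame(transcript_id = transcript_id, gene_id = gene_id,
             region_kind = region_kind, sequence = sequence, tpm = tpm)
}

#' Read transcript regions from FASTA
#'
#' @inheritParams read_fasta
#' @param region_kind Region kind applied to all records.
#' @param tpm Optional named vector of TPM values (by id); missing ids get 0.
#' @return A region data frame (see [transcript_regions()]).
#' @export
read_region_fasta <- function(path, region_kind = "UTR3", tpm = NULL) {
  fa <- read_fasta(path, alphabet_policy = "dna_to_rna")
  tp <- if (is.null(tpm)) 0 else unname(ifelse(is.na(tpm[fa$id]), 0, tpm[fa$id]))
  transcript_regions(fa$id, fa$id, region_kind, fa$sequence, tp)
}

#' Read a headered TSV against a column schema
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema Named character vector mapping required column names to types
#'   (`"character"`, `"numeric"`, `"integer"`). Extra columns are preserved
#'   as character.
#' @return A data frame with the schema columns coerced.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    .stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      character = df[[col]],
      numeric = as.numeric(df[[col]]),
      integer = as.integer(df[[col]]),
      .stopf("unknown schema type '%s' for column '%s'", schema[[col]], col))
  }
  df
}

#' Read a gene-level expression table
#'
#' Expects columns `gene_id`, `sample_id`, `tpm`; rejects negative TPM and
#' duplicated (gene, sample) pairs.
#'
#' @param path TSV path.
#' @return A typed data frame.
#' @export
read_expression <- function(path) {
  df <- read_table(path, c(gene_id = "character", sample_id = "character",
                           tpm = "numeric"))
  if (any(is.na(df$tpm)) || any(df$tpm < 0)) .stopf("negative or missing TPM")
  if (anyDuplicated(df[c("gene_id", "sample_id")])) {
    .stopf("duplicated (gene_id, sample_id) rows")
  }
  df
}

# ---------------------------------------------------------------------------
# MAF multiple alignments

#' Read a MAF multiple-alignment file
#'
#' Parses "a"/"s" paragraphs into alignment blocks. The first "s" row of each
#' block is the reference. Sequences are upper-cased and T-normalized to U.
#' If the reference row is on the minus strand, the whole block is
#' reverse-complemented so downstream code always sees reference sense-strand
#' coordinates.
#'
#' @param path Path to a MAF file.
#' @return A list of alignment blocks; each is a list with `ref` (reference
#'   species), `text` (named gapped sequences), `start`, `size`, `strand`,
#'   `src_size` (named vectors), of class `maf_block`.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- NULL
  bi <- 0L
  flush <- function(cur, bi) {
    if (is.null(cur) || length(cur$text) == 0L) return(NULL)
    if (length(unique(nchar(cur$text))) != 1L) {
      .stopf("MAF block %d has rows of unequal length", bi)
    }
    if (cur$strand[[1]] == "-") {
      cur$text <- vapply(cur$text, function(s) {
        paste(rev(.rna_chars(chartr("ACGUN-", "UGCAN-", s))), collapse = "")
      }, character(1))
      cur$strand <- stats::setNames(ifelse(cur$strand == "-", "+", "-"),
                                    names(cur$strand))
    }
    structure(cur, class = "maf_block")
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "a")) {
      b <- flush(cur, bi)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      bi <- bi + 1L
      cur <- list(ref = NA_character_, text = character(), start = integer(),
                  size = integer(), strand = character(), src_size = integer())
    } else if (startsWith(ln, "s ") && !is.null(cur)) {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 7L) .stopf("malformed 's' line in MAF block %d", bi)
      species <- sub("\\..*$", "", f[2])
      txt <- chartr("T", "U", toupper(f[7]))
      if (grepl("[^ACGUN-]", txt)) {
        .stopf("disallowed character in MAF block %d, species %s", bi, species)
      }
      cur$text[species] <- txt
      cur$start[species] <- as.integer(f[3])
      cur$size[species] <- as.integer(f[4])
      cur$strand[species] <- f[5]
      cur$src_size[species] <- as.integer(f[6])
      if (is.na(cur$ref)) cur$ref <- species
    }
  }
  b <- flush(cur, bi)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  for (k in seq_along(blocks)) {
    bl <- blocks[[k]]
    ref <- bl$text[[bl$ref]]
    if (nchar(gsub("-", "", ref, fixed = TRUE)) != bl$size[[bl$ref]]) {
      .stopf("MAF block %d: reference row length disagrees with declared size", k)
    }
  }
  blocks
}

#' Write alignment blocks to MAF
#'
#' @param blocks List of `maf_block` objects (see [read_maf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (bl in blocks) {
    writeLines("a score=0", con)
    for (sp in names(bl$text)) {
      writeLines(sprintf("s %s %d %d %s %d %s", sp, bl$start[[sp]],
                         bl$size[[sp]], bl$strand[[sp]], bl$src_size[[sp]],
                         bl$text[[sp]]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# candidate tables

.candidate_cols <- c("mirna_id", "transcript_id", "gene_id", "site_type",
                     "seed_start", "seed_end", "score", "base_points",
                     "end_bonus", "terminal_wobble_bonus",
                     "interruption_penalty", "offset_penalty", "offset",
                     "duplex_energy_kcal_mol", "tpm", "rank", "pairing_string")

#' Write ranked trigger candidates to TSV
#'
#' Column order is fixed; rows are emitted by rank, then transcript id, so the
#' output is byte-deterministic. The duplex-energy sentinel (no duplex) is an
#' empty cell; energies are written to 0.01 kcal/mol.
#'
#' @param candidates Candidate data frame from [run_denovo_branch()] or
#'   [run_conserved_branch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  df <- candidates[order(candidates$mirna_id, candidates$rank,
                         candidates$transcript_id), , drop = FALSE]
  out <- df[intersect(.candidate_cols, names(df))]
  for (col in setdiff(.candidate_cols, names(out))) out[[col]] <- NA
  out <- out[.candidate_cols]
  out$duplex_energy_kcal_mol <-
    ifelse(is.na(out$duplex_energy_kcal_mol), "",
           sprintf("%.2f", out$duplex_energy_kcal_mol))
  for (col in c("score", "base_points", "end_bonus", "terminal_wobble_bonus",
                "interruption_penalty", "offset_penalty")) {
    out[[col]] <- sprintf("%g", out[[col]])
  }
  out$offset <- ifelse(is.na(out$offset), "", as.character(out$offset))
  out$pairing_string <- ifelse(is.na(out$pairing_string), "", out$pairing_string)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate table written by [write_candidates()]
#'
#' @param path TSV path.
#' @return A typed candidate data frame; empty energy cells become `NA`.
#' @export
read_candidates <- function(path) {
  df <- read_table(path, c(mirna_id = "character", transcript_id = "character",
                           gene_id = "character", site_type = "character",
                           seed_start = "integer", seed_end = "integer",
                           score = "numeric", base_points = "numeric",
                           end_bonus = "numeric",
                           terminal_wobble_bonus = "numeric",
                           interruption_penalty = "numeric",
                           offset_penalty = "numeric",
                           tpm = "numeric", rank = "integer",
                           pairing_string = "character"))
  df$offset <- suppressWarnings(as.integer(df$offset))
  df$duplex_energy_kcal_mol <-
    suppressWarnings(as.numeric(df$duplex_energy_kcal_mol))
  df[.candidate_cols]
}
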