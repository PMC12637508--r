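# smallrna_quant: read-to-miRNA assignment by exact prefix matching,
# counts-per-million normalization, within-cluster normalization, and
# ZSWIM8-sensitivity calls from differential-expression tables.
#
# A read is assigned when its first `prefix_len` (default 19) nucleotides
# exactly match the prefix of a dictionary miRNA; no mismatches are
# tolerated. miRNAs sharing a prefix are quantified as one merged
# (ambiguous) group. Spike-in and marker reads are tallied separately and
# excluded from the counts-per-million denominator.

#' Build an exact-prefix assignment index
#'
#' @param mirnas miRNA data frame (see [mirna_set()]).
#' @param spikeins Optional data frame of spike-in/marker sequences (same
#'   shape as `mirnas`).
#' @param prefix_len Prefix length used for assignment.
#' @return A `prefix_index`: list with `prefix_len`, `prefixes`, `group_ids`
#'   (sorted "+"-joined member ids for shared prefixes), `ambiguous`,
#'   `is_spikein`.
#' @export
build_prefix_index <- function(mirnas, spikeins = NULL, prefix_len = 19) {
  prefix_len <- as.integer(prefix_len)
  all_ids <- c(mirnas$mirna_id, if (!is.null(spikeins)) spikeins$mirna_id)
  all_seq <- c(mirnas$sequence, if (!is.null(spikeins)) spikeins$sequence)
  spike <- c(rep(FALSE, nrow(mirnas)),
             if (!is.null(spikeins)) rep(TRUE, nrow(spikeins)))
  short <- nchar(all_seq) < prefix_len
  if (any(short)) {
    .stopf("sequence(s) shorter than prefix length %d: %s", prefix_len,
           paste(all_ids[short], collapse = ", "))
  }
  pref <- substr(all_seq, 1L, prefix_len)
  groups <- split(seq_along(pref), pref)
  prefixes <- names(groups)
  group_ids <- vapply(groups, function(ix) {
    paste(sort(all_ids[ix]), collapse = "+")
  }, character(1))
  ambiguous <- vapply(groups, function(ix) length(ix) > 1L, logical(1))
  is_spike <- vapply(groups, function(ix) any(spike[ix]), logical(1))
  if (any(is_spike & ambiguous)) {
    .stopf("spike-in shares a %d-nt prefix with a miRNA: %s", prefix_len,
           paste(group_ids[is_spike & ambiguous], collapse = ", "))
  }
  structure(list(prefix_len = prefix_len, prefixes = unname(prefixes),
                 group_ids = unname(group_ids),
                 ambiguous = unname(ambiguous),
                 is_spikein = unname(is_spike)),
            class = "prefix_index")
}

#' Assign reads to miRNA groups by exact prefix match
#'
#' @param reads Character vector of adapter-trimmed read sequences (one
#'   sample), or a FASTA/FASTQ-derived data frame with a `sequence` column.
#' @param index A [build_prefix_index()] index.
#' @return List with `counts` (data frame `group_id`, `count` for miRNA
#'   groups with nonzero totals included; zero-count groups retained),
#'   `spikein_counts`, `unassigned`, `total`.
#' @export
assign_reads <- function(reads, index) {
  if (is.data.frame(reads)) reads <- reads$sequence
  reads <- chartr("T", "U", toupper(reads))
  total <- length(reads)
  long_enough <- nchar(reads) >= index$prefix_len
  rp <- substr(reads[long_enough], 1L, index$prefix_len)
  hit <- match(rp, index$prefixes)
  assigned <- !is.na(hit)
  tab <- tabulate(hit[assigned], nbins = length(index$prefixes))
  mir <- !index$is_spikein
  counts <- data.frame(group_id = index$group_ids[mir], count = tab[mir])
  counts <- counts[order(counts$group_id), , drop = FALSE]
  rownames(counts) <- NULL
  spike <- data.frame(group_id = index$group_ids[!mir], count = tab[!mir])
  rownames(spike) <- NULL
  list(counts = counts, spikein_counts = spike,
       unassigned = total - sum(tab), total = total)
}

#' Quantify several samples into a cpm table
#'
#' Counts per million are computed over miRNA-assigned reads only
#' (spike-ins/markers excluded from the denominator), so cpm sums to 1e6
#' per sample whenever any read is assigned.
#'
#' @param read_sets Named list of per-sample read vectors.
#' @param index A [build_prefix_index()] index.
#' @return Long data frame: `sample_id`, `group_id`, `count`, `cpm`, with
#'   per-sample assignment summaries in attribute `"summary"`.
#' @export
quantify_samples <- function(read_sets, index) {
  stopifnot(length(names(read_sets)) == length(read_sets))
  rows <- list()
  summ <- list()
  for (s in names(read_sets)) {
    a <- assign_reads(read_sets[[s]], index)
    tot <- sum(a$counts$count)
    cpm <- if (tot > 0) a$counts$count / tot * 1e6 else
      rep(NA_real_, nrow(a$counts))
    rows[[s]] <- data.frame(sample_id = s, group_id = a$counts$group_id,
                            count = a$counts$count, cpm = cpm)
    summ[[s]] <- data.frame(sample_id = s, assigned = tot,
                            spikein = sum(a$spikein_counts$count),
                            unassigned = a$unassigned, total = a$total)
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  attr(out, "summary") <- do.call(rbind, unname(summ))
  out
}

#' Normalize a miRNA to its co-transcribed partners
#'
#' Per sample, the miRNA's cpm is divided by the geometric mean of its
#' partners' cpm (a single partner reduces to a simple ratio, e.g. a
#' passenger-strand normalization); fold change is that ratio divided by the
#' mean ratio over the control samples, so controls average to 1 by
#' construction. Samples where any partner cpm is 0 get an undefined (`NA`)
#' ratio, are excluded from the control mean, and are flagged with a
#' warning.
#'
#' @param cpm_table Long cpm table from [quantify_samples()] (or any data
#'   frame with `sample_id`, `group_id`, `cpm`).
#' @param mirna_id Group id of the miRNA to normalize.
#' @param partners Character vector of partner group ids (non-empty).
#' @param control_samples Sample ids forming the control (e.g. wild-type)
#'   group.
#' @return Data frame: `sample_id`, `mirna_id`, `ratio`, `fold_change`,
#'   `is_control`.
#' @export
cluster_normalize <- function(cpm_table, mirna_id, partners, control_samples) {
  if (length(partners) == 0L) .stopf("partners must be non-empty")
  samples <- unique(cpm_table$sample_id)
  missing <- setdiff(c(mirna_id, partners), unique(cpm_table$group_id))
  if (length(missing)) {
    .stopf("group(s) absent from cpm table: %s", paste(missing, collapse = ", "))
  }
  if (!all(control_samples %in% samples)) .stopf("unknown control sample id")
  get <- function(g, s) cpm_table$cpm[cpm_table$group_id == g &
                                        cpm_table$sample_id == s]
  ratio <- vapply(samples, function(s) {
    x <- get(mirna_id, s)
    ps <- vapply(partners, get, numeric(1), s = s)
    if (any(ps == 0)) return(NA_real_)
    x / exp(mean(log(ps)))
  }, numeric(1))
  if (anyNA(ratio)) {
    .warnf("undefined ratio (zero partner cpm) in sample(s): %s",
           paste(samples[is.na(ratio)], collapse = ", "))
  }
  ctrl <- ratio[samples %in% control_samples]
  ctrl_mean <- mean(ctrl, na.rm = TRUE)
  data.frame(sample_id = samples, mirna_id = mirna_id, ratio = unname(ratio),
             fold_change = unname(ratio) / ctrl_mean,
             is_control = samples %in% control_samples)
}

#' Call ZSWIM8-/trigger-sensitive miRNAs from a differential table
#'
#' Returns the miRNAs significantly upregulated in the perturbation:
#' adjusted p at or below `alpha` and log2 fold change at or above
#' `min_log2fc`. Rows with missing adjusted p are skipped with a warning.
#'
#' @param de_table Data frame with `mirna_id`, `log2fc`, `padj`.
#' @param alpha Adjusted-p threshold.
#' @param min_log2fc Minimum log2 fold change (upregulation only).
#' @return Sorted character vector of called miRNA ids.
#' @export
call_sensitive <- function(de_table, alpha = 0.05, min_log2fc = 0) {
  bad <- is.na(de_table$padj)
  if (any(bad)) {
    .warnf("%d row(s) with missing padj skipped", sum(bad))
    de_table <- de_table[!bad, , drop = FALSE]
  }
  sort(de_table$mirna_id[de_table$padj <= alpha & de_table$log2fc > 0 &
                           de_table$log2fc >= min_log2fc])
}
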