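# synthetic_data: generators for every input the pipeline consumes, with
# planted ground truth. Every generator is a pure function of its seed and
# parameters (byte-identical reruns under the same seed).

#' Generate a synthetic mature miRNA set
#'
#' Random miRNA sequences with unique 19-nt prefixes (unless a deliberate
#' collision pair is requested). Cluster structure emulates co-transcribed
#' miRNAs: members of a cluster list each other as normalization partners.
#'
#' @param n Number of miRNAs.
#' @param length_range Min/max mature length.
#' @param cluster_sizes Optional integer vector; the first
#'   `sum(cluster_sizes)` miRNAs are grouped into clusters of these sizes.
#' @param collision_pair If `TRUE`, the last two miRNAs share their first
#'   19 nt and differ at position 20 (an ambiguous-prefix pair).
#' @param seed Integer seed.
#' @return A miRNA data frame (see [mirna_set()]).
#' @export
sim_mirnas <- function(n, length_range = c(21, 23), cluster_sizes = NULL,
                       collision_pair = FALSE, seed = 1) {
  stopifnot(n >= 1)
  if (collision_pair && n < 2) .stopf("collision_pair needs n >= 2")
  set.seed(seed)
  seqs <- character(0)
  tries <- 0L
  while (length(seqs) < n) {
    tries <- tries + 1L
    if (tries > 50L * n) .stopf("could not generate %d unique 19-nt prefixes", n)
    len <- sample(seq(length_range[1], length_range[2]), 1L)
    s <- .random_rna(len)
    if (!substr(s, 1, 19) %in% substr(seqs, 1, 19)) seqs <- c(seqs, s)
  }
  if (collision_pair) {
    base <- seqs[n - 1L]
    alt_base <- setdiff(RNA_BASES, substr(base, 20, 20))[1]
    seqs[n] <- paste0(substr(base, 1, 19), alt_base,
                      substr(base, 21, nchar(base)))
  }
  ids <- sprintf("syn-miR-%02d", seq_len(n))
  cluster_id <- rep(NA_character_, n)
  partners <- rep("", n)
  if (!is.null(cluster_sizes)) {
    stopifnot(sum(cluster_sizes) <= n)
    idx <- 1L
    for (ci in seq_along(cluster_sizes)) {
      members <- seq.int(idx, idx + cluster_sizes[ci] - 1L)
      cluster_id[members] <- sprintf("cluster%d", ci)
      for (m in members) {
        partners[m] <- paste(ids[setdiff(members, m)], collapse = ",")
      }
      idx <- idx + cluster_sizes[ci]
    }
  }
  mirna_set(ids, seqs, species = "synthetic", cluster_id = cluster_id,
            partners = partners)
}

#' Describe an intended 3'-pairing architecture
#'
#' @param wcf miRNA positions (1-based) intended to pair Watson-Crick-Franklin.
#' @param gu miRNA positions intended to form G:U wobbles (the miRNA base
#'   there must be G or U).
#' @param offset Intended offset (target-side loop minus miRNA-side loop).
#' @return A `trigger_pattern` list.
#' @export
trigger_pattern <- function(wcf = 13:22, gu = integer(0), offset = 0) {
  if (length(intersect(wcf, gu))) .stopf("wcf and gu positions overlap")
  pos <- sort(c(wcf, gu))
  if (length(pos) && any(pos < 9L)) .stopf("3' pattern positions must be >= 9")
  structure(list(wcf = sort(as.integer(wcf)), gu = sort(as.integer(gu)),
                 offset = as.integer(offset)), class = "trigger_pattern")
}

#' Plant a trigger site of specified architecture in a synthetic transcript
#'
#' Emits a transcript whose upstream window realizes exactly the requested
#' pairing configuration against the given miRNA (non-planted window
#' positions opposite the miRNA 3' region are forced non-pairing), together
#' with a seed match of the requested type. The expected score is recorded
#' from [score_configuration()] on the intended pattern.
#'
#' @param mirna One-row miRNA data frame or RNA string.
#' @param pattern A [trigger_pattern()].
#' @param site_type Planted canonical site type.
#' @param length Transcript length (nt).
#' @param gc Background GC fraction.
#' @param transcript_id Identifier for the emitted transcript.
#' @param tpm Expression level attached to the transcript.
#' @param params [score_params()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return List with `region` (one-row region data frame) and `truth`
#'   (one-row data frame: `mirna_id`, `transcript_id`, `seed_start`,
#'   `site_type`, `expected_score`).
#' @export
plant_trigger_site <- function(mirna, pattern = trigger_pattern(),
                               site_type = "8mer", length = 1000, gc = 0.5,
                               transcript_id = "synthetic_T1", tpm = 50,
                               params = score_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(mirna)) mirna <- mirna_set("planted-mir", mirna)
  mseq <- mirna$sequence[1]
  L <- nchar(mseq)
  pos <- sort(c(pattern$wcf, pattern$gu))
  if (length(pos) && max(pos) > L) .stopf("pattern positions exceed miRNA length")
  W <- params$window
  jw <- function(i) W - pattern$offset - (i - 9L)   # 1-based window index
  if (length(pos) && (min(jw(max(pos))) < 1L || max(jw(min(pos))) > W)) {
    .stopf("pattern does not fit in a %d-nt window at offset %d", W,
           pattern$offset)
  }
  site_len <- W + 2L + 6L                          # window + m8 + core + t1
  if (length < site_len + 20L) .stopf("transcript too short for the site")
  seed_start <- sample(seq.int(W + 1L, length - 8L), 1L)

  chars <- .rna_chars(.random_rna(length, gc))
  mch <- .rna_chars(mseq)
  wob <- c(G = "U", U = "G")
  nonpairing <- function(b) {
    sample(setdiff(RNA_BASES, c(.wc_complement(b), unname(wob[b]))), 1L)
  }
  # window content: planted pairs, everything else opposite the 3' region
  # forced non-pairing so the realized configuration is exactly the pattern
  win_start <- seed_start - 1L - W                  # 0-based
  for (i in seq.int(9L, L)) {
    j <- jw(i)
    if (j < 1L || j > W) next
    at <- win_start + j                             # 1-based string index
    if (i %in% pattern$wcf) {
      chars[at] <- .wc_complement(mch[i])
    } else if (i %in% pattern$gu) {
      if (!mch[i] %in% names(wob)) {
        .stopf("G:U wobble requested at position %d but miRNA base is %s",
               i, mch[i])
      }
      chars[at] <- unname(wob[mch[i]])
    } else {
      chars[at] <- nonpairing(mch[i])
    }
  }
  # seed match: t8 column, 6mer core, t1
  core <- rc_rna(substr(mseq, 2L, 7L))
  m8c <- .wc_complement(substr(mseq, 8L, 8L))
  chars[seed_start] <- if (site_type %in% c("8mer", "7mer-m8")) m8c else
    nonpairing(substr(mseq, 8L, 8L))
  chars[seed_start + seq_len(6L)] <- .rna_chars(core)
  if (seed_start + 7L <= length) {
    chars[seed_start + 7L] <- if (site_type %in% c("8mer", "7mer-A1")) "A"
                              else "C"
  }
  region <- transcript_regions(transcript_id, transcript_id, "UTR3",
                               paste(chars, collapse = ""), tpm)
  # expected score from the intended configuration
  tpos <- vapply(pos, function(i) win_start + jw(i) - 1L, integer(1))
  cfg_pairs <- if (length(pos)) {
    data.frame(mirna_pos = pos, target_pos = tpos)[order(pos), ]
  } else NULL
  cfg <- score_configuration(mseq, region$sequence, seed_start, cfg_pairs,
                             params = params)
  truth <- data.frame(mirna_id = mirna$mirna_id[1],
                      transcript_id = transcript_id, seed_start = seed_start,
                      site_type = site_type, expected_score = cfg$total_score)
  list(region = region, truth = truth)
}

#' Generate a synthetic transcriptome with one planted trigger per miRNA
#'
#' @param mirnas miRNA data frame.
#' @param n_transcripts Total transcript count (the first `nrow(mirnas)`
#'   carry one planted trigger each; the rest are background).
#' @param length Transcript length.
#' @param gc Background GC fraction.
#' @param pattern A [trigger_pattern()] used for every planted site, or
#'   `NULL` for a full-length perfect 3' duplex (WCF over nucleotides 13 to
#'   the miRNA 3' end).
#' @param site_type Planted site type.
#' @param params [score_params()].
#' @param seed Integer seed.
#' @return List with `regions` (region data frame) and `truth` (one row per
#'   planted site).
#' @export
sim_transcriptome <- function(mirnas, n_transcripts = 200, length = 1000,
                              gc = 0.5, pattern = NULL,
                              site_type = "8mer", params = score_params(),
                              seed = 1) {
  nm <- nrow(mirnas)
  stopifnot(n_transcripts >= nm)
  set.seed(seed)
  tpm <- pmax(1, round(stats::rlnorm(n_transcripts, log(20), 1), 2))
  regions <- vector("list", n_transcripts)
  truths <- vector("list", nm)
  for (k in seq_len(nm)) {
    pat <- if (is.null(pattern)) {
      trigger_pattern(13:nchar(mirnas$sequence[k]))
    } else pattern
    planted <- plant_trigger_site(mirnas[k, , drop = FALSE], pat,
                                  site_type = site_type, length = length,
                                  gc = gc,
                                  transcript_id = sprintf("synthetic_T%03d", k),
                                  tpm = tpm[k], params = params, seed = NULL)
    regions[[k]] <- planted$region
    truths[[k]] <- planted$truth
  }
  for (k in seq_len(n_transcripts - nm) + nm) {
    regions[[k]] <- transcript_regions(sprintf("synthetic_T%03d", k),
                                       sprintf("synthetic_T%03d", k), "UTR3",
                                       .random_rna(length, gc), tpm[k])
  }
  list(regions = do.call(rbind, regions), truth = do.call(rbind, truths))
}

#' Generate a synthetic multiple alignment around a reference sequence
#'
#' The reference row reproduces the input sequence; each additional species
#' applies its planted substitutions, deletions, and insertions.
#'
#' @param ref_seq Reference (ungapped) RNA sequence.
#' @param species_spec Named list; each element describes one species as a
#'   list with optional `subs` (data frame `pos` 0-based, `base`), `del`
#'   (0-based positions deleted), `ins` (list with `after` 0-based
#'   reference position and `seq`).
#' @param ref_name Reference species name.
#' @param ref_start Reference start coordinate recorded in the block.
#' @return A `maf_block`.
#' @export
sim_alignment <- function(ref_seq, species_spec = list(), ref_name = "mouse",
                          ref_start = 0L) {
  .rna_validate(ref_seq)
  ref_chars <- .rna_chars(ref_seq)
  n <- length(ref_chars)
  rows <- list()
  rows[[ref_name]] <- ref_chars
  for (sp in names(species_spec)) {
    spec <- species_spec[[sp]]
    ch <- ref_chars
    if (!is.null(spec$subs)) {
      for (r in seq_len(nrow(spec$subs))) {
        ch[spec$subs$pos[r] + 1L] <- spec$subs$base[r]
      }
    }
    if (!is.null(spec$del)) ch[spec$del + 1L] <- "-"
    rows[[sp]] <- ch
  }
  # insertions: extra columns gapped in every other row
  for (sp in names(species_spec)) {
    ins <- species_spec[[sp]]$ins
    if (is.null(ins)) next
    at <- ins$after + 1L
    extra <- .rna_chars(ins$seq)
    for (nm in names(rows)) {
      cur <- rows[[nm]]
      fill <- if (nm == sp) extra else rep("-", length(extra))
      rows[[nm]] <- append(cur, fill, after = at)
    }
  }
  text <- vapply(rows, paste, character(1), collapse = "")
  sizes <- vapply(text, function(s) nchar(gsub("-", "", s, fixed = TRUE)),
                  integer(1))
  structure(list(ref = ref_name, text = text,
                 start = stats::setNames(rep(as.integer(ref_start),
                                             length(text)), names(text)),
                 size = stats::setNames(as.integer(sizes), names(text)),
                 strand = stats::setNames(rep("+", length(text)), names(text)),
                 src_size = stats::setNames(rep(1000000L, length(text)),
                                            names(text))),
            class = "maf_block")
}

#' Simulate small-RNA reads for one sample
#'
#' Reads are exact full-length miRNA sequences drawn multinomially from the
#' abundance vector, followed by the requested number of spike-in reads.
#'
#' @param mirnas miRNA data frame.
#' @param abundances Named non-negative vector (by `mirna_id`); relative
#'   abundances.
#' @param n_reads Number of miRNA reads to draw.
#' @param spikeins Optional spike-in data frame (same shape as `mirnas`).
#' @param spikein_counts Reads per spike-in (recycled).
#' @param seed Integer seed, or `NULL`.
#' @return Character vector of read sequences.
#' @export
sim_reads <- function(mirnas, abundances, n_reads, spikeins = NULL,
                      spikein_counts = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ab <- abundances[mirnas$mirna_id]
  if (anyNA(ab) || sum(ab) <= 0) .stopf("abundances must cover all miRNAs and sum > 0")
  reads <- sample(mirnas$sequence, n_reads, replace = TRUE, prob = ab)
  if (!is.null(spikeins)) {
    cnt <- rep_len(spikein_counts, nrow(spikeins))
    reads <- c(reads, rep(spikeins$sequence, times = cnt))
  }
  reads
}

#' Simulate a differential-expression gene table with planted repression
#'
#' Nontarget log2 fold changes are Normal(0, sigma); predicted targets of
#' `family` are Normal(delta + per-gene boost, sigma). 3' UTR lengths are
#' log-normal, optionally confounded with target status to stress the
#' length matcher. Context++ scores track the per-gene effect rank (more
#' negative = more repressed).
#'
#' @param n_genes Number of genes.
#' @param family miRNA family id planted as `target_of`.
#' @param delta Planted mean log2 fold-change shift of targets.
#' @param sigma Noise standard deviation.
#' @param target_fraction Fraction of genes that are predicted targets.
#' @param top_boost Extra (signed) shift applied in proportion to the
#'   context++ rank, making "top" targets more repressed; 0 disables.
#' @param utr_meanlog,utr_sdlog Log-normal UTR length parameters.
#' @param confound If `TRUE`, target UTRs are drawn systematically longer
#'   (meanlog + 0.5) than nontarget UTRs.
#' @param mean_tpm_meanlog Log-normal mean TPM location parameter.
#' @param seed Integer seed.
#' @return Gene data frame suitable for [run_repression()].
#' @export
sim_de_table <- function(n_genes = 1000, family = "syn-family",
                         delta = -0.3, sigma = 0.2, target_fraction = 0.2,
                         top_boost = 0, utr_meanlog = log(1000),
                         utr_sdlog = 0.6, confound = FALSE,
                         mean_tpm_meanlog = log(50), seed = 1) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  set.seed(seed)
  n_t <- round(n_genes * target_fraction)
  is_target <- c(rep(TRUE, n_t), rep(FALSE, n_genes - n_t))
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  meanlog <- ifelse(confound & is_target, utr_meanlog + 0.5, utr_meanlog)
  utr3_length <- pmax(50, round(stats::rlnorm(n_genes, meanlog, utr_sdlog)))
  mean_tpm <- round(stats::rlnorm(n_genes, mean_tpm_meanlog, 0.8), 2)
  strength <- stats::runif(n_genes)              # 1 = strongest predicted
  shift <- ifelse(is_target, delta + top_boost * strength, 0)
  log2fc <- stats::rnorm(n_genes, shift, sigma)
  contextpp <- ifelse(is_target, round(-0.05 - 0.75 * strength, 4), NA_real_)
  data.frame(gene_id = gene_id, log2fc = log2fc, mean_tpm = mean_tpm,
             utr3_length = utr3_length,
             target_of = ifelse(is_target, family, ""),
             contextpp_score = contextpp)
}
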