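# target_repression: repression of predicted miRNA targets versus 3'-UTR
# length-matched nontargets in differential-expression data, with iterated
# nontarget resampling.
#
# Repression is the median log2 fold change of the matched nontarget cohort
# minus that of the target cohort (positive = targets more repressed);
# significance per iteration is a Mann-Whitney U test; the mean repression
# and median p across iterations summarize the analysis.

#' Filter genes by mean expression
#'
#' @param genes Gene data frame with a `mean_tpm` column.
#' @param min_tpm Minimum mean TPM (genes at the threshold are kept).
#' @return The retained subset.
#' @export
filter_expressed <- function(genes, min_tpm = 10) {
  out <- genes[genes$mean_tpm >= min_tpm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top predicted targets by context++ score
#'
#' The `ceiling(fraction * n)` targets with the lowest (most repressive)
#' cumulative weighted context++ scores; boundary ties are broken by gene id
#' for determinism.
#'
#' @param targets Target gene data frame with a `contextpp_score` column.
#' @param fraction Fraction of targets to keep.
#' @return The selected subset.
#' @export
top_targets <- function(targets, fraction = 0.10) {
  if (any(is.na(targets$contextpp_score))) {
    .stopf("missing contextpp_score for: %s",
           paste(targets$gene_id[is.na(targets$contextpp_score)],
                 collapse = ", "))
  }
  n <- nrow(targets)
  if (n == 0L) return(targets)
  k <- ceiling(fraction * n)
  o <- order(targets$contextpp_score, targets$gene_id)
  out <- targets[o[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample nontargets matched on 3' UTR length
#'
#' Greedy nearest-neighbor matching without replacement on log10 UTR
#' length: targets are visited in random order and each takes the remaining
#' pool gene closest in log-length (one nontarget per target).
#'
#' @param targets Target gene data frame (`gene_id`, `utr3_length`).
#' @param pool Nontarget pool, disjoint from the targets, with at least as
#'   many rows.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return The matched nontarget subset of `pool` (one row per target).
#' @export
sample_matched_nontargets <- function(targets, pool, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nt <- nrow(targets)
  if (nrow(pool) < nt) {
    .stopf("nontarget pool (%d) smaller than target set (%d)", nrow(pool), nt)
  }
  tl <- log10(targets$utr3_length)
  pl <- log10(pool$utr3_length)
  taken <- rep(FALSE, nrow(pool))
  pick <- integer(nt)
  for (t in sample.int(nt)) {
    d <- abs(pl - tl[t])
    d[taken] <- Inf
    k <- which.min(d)
    taken[k] <- TRUE
    pick[t] <- k
  }
  out <- pool[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from rank sums with midranks for ties. The p-value is
#' exact (by enumeration) when `min(n, m) <= exact_max` and there are no
#' ties, and otherwise uses the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_max Largest smaller-sample size for which the exact null
#'   distribution is used.
#' @return List with `U` (for `x`) and `p_two_sided`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (length(x) == 0L || length(y) == 0L) .stopf("samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  ht <- stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  list(U = unname(ht$statistic), p_two_sided = ht$p.value)
}

#' Matched-nontarget repression analysis
#'
#' Runs the target-versus-nontarget comparison for two target sets ("all"
#' predicted targets of the family, and the "top" fraction by context++
#' score). Each iteration draws a fresh length-matched nontarget cohort,
#' computes repression = median(nontarget log2fc) - median(target log2fc)
#' and a Mann-Whitney p. The representative iteration (for plotting) is the
#' one generating the median p of the all-targets set.
#'
#' @param genes Gene data frame with columns `gene_id`, `log2fc`,
#'   `mean_tpm`, `utr3_length`, `target_of` (comma-separated family ids) and
#'   `contextpp_score` (required for predicted targets).
#' @param family miRNA family id whose targets are analyzed; the nontarget
#'   pool excludes predicted targets of this family only.
#' @param iterations Number of resampling iterations.
#' @param seed Integer seed; per-iteration sub-seeds are derived from it
#'   deterministically.
#' @param min_tpm Expression filter applied first (mean TPM).
#' @param top_fraction Fraction defining the top target set.
#' @param min_targets Minimum post-filter target count required.
#' @return A `repression_report`: list with `iterations` (data frame:
#'   `iteration`, `target_set`, `repression`, `p_value`, `n_targets`),
#'   `summary` (per target set: `mean_repression`, `sd_repression`,
#'   `median_p`, `n_targets`, `n_nontargets`), and
#'   `representative_iteration`.
#' @export
run_repression <- function(genes, family, iterations = 21, seed = 1,
                           min_tpm = 10, top_fraction = 0.10,
                           min_targets = 5) {
  genes <- filter_expressed(genes, min_tpm)
  genes <- genes[genes$utr3_length > 0, , drop = FALSE]
  is_target <- vapply(strsplit(genes$target_of, ",", fixed = TRUE),
                      function(fams) family %in% trimws(fams), logical(1))
  targets_all <- genes[is_target, , drop = FALSE]
  pool <- genes[!is_target, , drop = FALSE]
  if (nrow(targets_all) < min_targets) {
    .stopf("only %d predicted target(s) of family '%s' pass the filters (need >= %d)",
           nrow(targets_all), family, min_targets)
  }
  sets <- list(all = targets_all,
               top = top_targets(targets_all, top_fraction))
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, iterations)
  rows <- list()
  for (sname in names(sets)) {
    tg <- sets[[sname]]
    for (it in seq_len(iterations)) {
      nt <- sample_matched_nontargets(tg, pool, seed = iter_seeds[it])
      mw <- mann_whitney_u(tg$log2fc, nt$log2fc)
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = it, target_set = sname,
        repression = stats::median(nt$log2fc) - stats::median(tg$log2fc),
        p_value = mw$p_two_sided, n_targets = nrow(tg))
    }
  }
  iter_df <- do.call(rbind, rows)
  summary_df <- do.call(rbind, lapply(names(sets), function(sname) {
    d <- iter_df[iter_df$target_set == sname, ]
    data.frame(target_set = sname, mean_repression = mean(d$repression),
               sd_repression = if (nrow(d) > 1L) stats::sd(d$repression)
                               else NA_real_,
               median_p = stats::median(d$p_value),
               n_targets = nrow(sets[[sname]]),
               n_nontargets = nrow(sets[[sname]]))
  }))
  d_all <- iter_df[iter_df$target_set == "all", ]
  rep_it <- d_all$iteration[which.min(abs(d_all$p_value -
                                            stats::median(d_all$p_value)))]
  structure(list(iterations = iter_df, summary = summary_df,
                 representative_iteration = rep_it, family = family,
                 seed = seed),
            class = "repression_report")
}

#' @export
print.repression_report <- function(x, ...) {
  cat(sprintf("Repression of predicted '%s' targets (%d iterations)\n",
              x$family, max(x$iterations$iteration)))
  for (k in seq_len(nrow(x$summary))) {
    s <- x$summary[k, ]
    cat(sprintf("  %-4s targets (n=%d): mean repression %.3f, median p %.3g\n",
                s$target_set, s$n_targets, s$mean_repression, s$median_p))
  }
  invisible(x)
}
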