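# pairing_score: the point scheme for 3'-region complementarity and the
# optimal-configuration search over the upstream window.
#
# Point scheme (defaults): each Watson-Crick-Franklin pair beyond miRNA
# nucleotide 12 earns 1 point; WCF pairing at the penultimate or
# third-to-last nucleotide earns an extra 0.5 each; a G:U wobble earns
# nothing except 0.5 at the very last nucleotide; every gap or mismatch
# interrupting the 3' duplex costs 1 point per interrupting column
# (max of the two strand gaps); |offset| beyond 3 costs 0.5 per nucleotide.
# Pairs at positions 9-12 may form (helping contiguity) but earn 0.

#' Scoring parameters for 3'-pairing configurations
#'
#' @param match_point Points per WCF pair at miRNA position > 12.
#' @param end_bonus Extra points per WCF pair at the penultimate or
#'   third-to-last miRNA position (each counted independently).
#' @param terminal_wobble_bonus Points for a G:U wobble at the last miRNA
#'   position.
#' @param interruption_point Points deducted per gap/mismatch column
#'   (max of the miRNA-side and target-side gap per interruption event).
#' @param offset_free Largest |offset| that goes unpenalized.
#' @param offset_point Points deducted per nucleotide of |offset| beyond
#'   `offset_free`.
#' @param window Width (nt) of the upstream search window, anchored
#'   immediately 5' of the target nucleotide opposite miRNA position 8.
#' @param three_prime_start First miRNA position eligible for 3' pairing.
#' @return A validated `score_params` list.
#' @export
score_params <- function(match_point = 1, end_bonus = 0.5,
                         terminal_wobble_bonus = 0.5, interruption_point = 1,
                         offset_free = 3, offset_point = 0.5, window = 30,
                         three_prime_start = 9) {
  p <- list(match_point = match_point, end_bonus = end_bonus,
            terminal_wobble_bonus = terminal_wobble_bonus,
            interruption_point = interruption_point,
            offset_free = as.integer(offset_free),
            offset_point = offset_point, window = as.integer(window),
            three_prime_start = as.integer(three_prime_start))
  pts <- unlist(p[c("match_point", "end_bonus", "terminal_wobble_bonus",
                    "interruption_point", "offset_point")])
  if (any(pts < 0)) .stopf("point parameters must be >= 0")
  if (p$window < 1L) .stopf("window must be >= 1")
  if (p$three_prime_start < 9L) .stopf("three_prime_start must be >= 9")
  structure(p, class = "score_params")
}

# window coordinates for a seed match: [start, end) on the region,
# immediately 5' of the target nucleotide opposite miRNA position 8
.site_window <- function(seed_start, params) {
  we <- seed_start - 1L
  ws <- max(0L, we - params$window)
  c(start = ws, end = max(ws, we))
}

#' Score one explicit 3'-pairing configuration
#'
#' Validates the configuration against the sequences and returns the full
#' point breakdown. The offset is derived from the geometry of the first 3'
#' pair: target-side loop minus miRNA-side loop between the seed helix
#' (miRNA position 8 column) and that pair. Terminal unpaired overhangs are
#' free; only interruptions strictly inside the 3' duplex are penalized.
#'
#' @param mirna_seq Mature miRNA sequence.
#' @param region_seq Transcript region sequence (sense strand).
#' @param seed_start 0-based start of the 6mer seed core on the region.
#' @param pairs Data frame with columns `mirna_pos` (1-based, strictly
#'   increasing, >= `three_prime_start`) and `target_pos` (0-based region
#'   coordinate, strictly decreasing); an empty data frame is the empty
#'   configuration. An optional `pair_class` column is checked against the
#'   sequences.
#' @param params [score_params()].
#' @return A `pairing_config` object: list with `pairs` (with inferred
#'   `pair_class`), `offset`, `interruptions`, `breakdown`, `total_score`.
#' @export
score_configuration <- function(mirna_seq, region_seq, seed_start, pairs,
                                params = score_params()) {
  .rna_validate(mirna_seq, "miRNA sequence")
  .rna_validate(region_seq, "region sequence")
  L <- nchar(mirna_seq)
  empty_breakdown <- c(base_points = 0, end_bonus = 0,
                       terminal_wobble_bonus = 0, interruption_penalty = 0,
                       offset_penalty = 0)
  win <- .site_window(seed_start, params)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(structure(list(pairs = data.frame(mirna_pos = integer(),
                                             target_pos = integer(),
                                             pair_class = character()),
                          offset = NA_integer_,
                          interruptions = data.frame(mirna_gap = integer(),
                                                     target_gap = integer()),
                          breakdown = empty_breakdown, total_score = 0,
                          seed_start = seed_start, window = win),
                     class = "pairing_config"))
  }
  mp <- as.integer(pairs$mirna_pos)
  tp <- as.integer(pairs$target_pos)
  o <- order(mp)
  mp <- mp[o]; tp <- tp[o]
  if (any(diff(mp) <= 0L)) .stopf("mirna_pos must be strictly increasing")
  if (any(diff(tp) >= 0L)) .stopf("target_pos must be strictly decreasing (antiparallel)")
  if (mp[1] < params$three_prime_start || mp[length(mp)] > L) {
    .stopf("mirna_pos outside [%d, %d]", params$three_prime_start, L)
  }
  if (tp[1] >= seed_start - 1L || tp[length(tp)] < 0L ||
      tp[length(tp)] < win["start"]) {
    .stopf("target_pos outside the upstream window [%d, %d)",
           win["start"], win["end"])
  }
  mb <- substr(rep(mirna_seq, length(mp)), mp, mp)
  tb <- substr(rep(region_seq, length(tp)), tp + 1L, tp + 1L)
  cls <- .pair_class(mb, tb)
  if (anyNA(cls)) {
    .stopf("bases cannot pair at miRNA position %s",
           paste(mp[is.na(cls)], collapse = ", "))
  }
  if (!is.null(pairs$pair_class)) {
    given <- pairs$pair_class[o]
    if (!all(given == cls)) {
      .stopf("pair_class label inconsistent with sequences at miRNA position %s",
             paste(mp[given != cls], collapse = ", "))
    }
  }
  offset <- (seed_start - 2L - tp[1]) - (mp[1] - 9L)
  gm <- diff(mp) - 1L
  gt <- -diff(tp) - 1L
  keep <- gm > 0L | gt > 0L
  interruptions <- data.frame(mirna_gap = gm[keep], target_gap = gt[keep])
  wcf <- cls == "WCF"
  breakdown <- c(
    base_points = params$match_point * sum(wcf & mp > 12L),
    end_bonus = params$end_bonus * sum(wcf & (mp == L - 1L | mp == L - 2L)),
    terminal_wobble_bonus =
      params$terminal_wobble_bonus * sum(cls == "GU" & mp == L),
    interruption_penalty =
      params$interruption_point * sum(pmax(gm[keep], gt[keep])),
    offset_penalty =
      params$offset_point * max(0L, abs(offset) - params$offset_free))
  total <- breakdown[["base_points"]] + breakdown[["end_bonus"]] +
    breakdown[["terminal_wobble_bonus"]] -
    breakdown[["interruption_penalty"]] - breakdown[["offset_penalty"]]
  structure(list(pairs = data.frame(mirna_pos = mp, target_pos = tp,
                                    pair_class = cls),
                 offset = offset, interruptions = interruptions,
                 breakdown = breakdown, total_score = total,
                 seed_start = seed_start, window = win),
            class = "pairing_config")
}

#' @export
print.pairing_config <- function(x, ...) {
  cat(sprintf("3'-pairing configuration: %d pair(s), score %.2f\n",
              nrow(x$pairs), x$total_score))
  if (nrow(x$pairs)) {
    cat(sprintf("  offset %d; breakdown: base %.2f + end %.2f + wobble %.2f - interruption %.2f - offset %.2f\n",
                x$offset, x$breakdown[["base_points"]],
                x$breakdown[["end_bonus"]],
                x$breakdown[["terminal_wobble_bonus"]],
                x$breakdown[["interruption_penalty"]],
                x$breakdown[["offset_penalty"]]))
  }
  invisible(x)
}

#' Optimal 3'-pairing configuration within the upstream window
#'
#' Dynamic-programming search for the configuration of antiparallel,
#' monotone miRNA-window pairs maximizing the point scheme of
#' [score_configuration()]. Ties are resolved deterministically: smaller
#' |offset|, then fewer interruption events, then the 5'-most target start.
#' The empty configuration (score 0) is always admissible, so the returned
#' score is never negative. Windows truncated by the transcript 5' end are
#' searched as-is; a zero-length window yields the empty configuration.
#'
#' @inheritParams score_configuration
#' @return A `pairing_config` object.
#' @export
best_configuration <- function(mirna_seq, region_seq, seed_start,
                               params = score_params()) {
  .rna_validate(mirna_seq, "miRNA sequence")
  .rna_validate(region_seq, "region sequence")
  win <- .site_window(seed_start, params)
  if (win["end"] <= win["start"]) {
    return(score_configuration(mirna_seq, region_seq, seed_start,
                               pairs = NULL, params = params))
  }
  wseq <- substr(region_seq, win["start"] + 1L, win["end"])
  res <- dp_best_config(.rna_codes(mirna_seq), .rna_codes(wseq),
                        params$three_prime_start, params$match_point,
                        params$end_bonus, params$terminal_wobble_bonus,
                        params$interruption_point, params$offset_point,
                        params$offset_free)
  if (length(res$mirna_pos) == 0L) {
    return(score_configuration(mirna_seq, region_seq, seed_start,
                               pairs = NULL, params = params))
  }
  cfg <- score_configuration(
    mirna_seq, region_seq, seed_start,
    pairs = data.frame(mirna_pos = res$mirna_pos,
                       target_pos = win["start"] + res$win_idx),
    params = params)
  stopifnot(abs(cfg$total_score - res$score) < 1e-6)
  cfg
}

#' Exhaustive search oracle for small instances
#'
#' Enumerates every monotone antiparallel pairing between the eligible miRNA
#' 3' region and the window, scoring each incrementally, and returns the
#' argmax under the same tie-break order as [best_configuration()]. Refuses
#' instances beyond the combinatorial guard (3' region > 10 nt or window >
#' 14 nt, or more than `max_nodes` enumeration steps). Intended as an
#' independent test oracle; it shares no code with the dynamic program.
#'
#' @inheritParams score_configuration
#' @param max_nodes Enumeration-step guard.
#' @return A `pairing_config` object.
#' @export
exhaustive_best <- function(mirna_seq, region_seq, seed_start,
                            params = score_params(), max_nodes = 2e6) {
  .rna_validate(mirna_seq, "miRNA sequence")
  L <- nchar(mirna_seq)
  p0 <- params$three_prime_start
  win <- .site_window(seed_start, params)
  W <- as.integer(win["end"] - win["start"])
  if (L - p0 + 1L > 10L || W > 14L) {
    .stopf("instance too large for exhaustive search (3' region %d nt, window %d nt)",
           L - p0 + 1L, W)
  }
  empty <- score_configuration(mirna_seq, region_seq, seed_start, NULL, params)
  if (W <= 0L) return(empty)
  wseq <- substr(region_seq, win["start"] + 1L, win["end"])
  mch <- .rna_chars(mirna_seq)
  wch <- .rna_chars(wseq)
  clsmat <- outer(mch, wch, .pair_class)     # [mirna_pos, window_idx]

  pair_score <- function(i, cls) {
    if (cls == "WCF") {
      s <- if (i > 12L) params$match_point else 0
      if (i == L - 1L || i == L - 2L) s <- s + params$end_bonus
      s
    } else if (i == L) params$terminal_wobble_bonus else 0
  }

  best <- list(score = 0, aoff = 0L, nint = 0L, startj = W, pairs = NULL)
  nodes <- 0L
  consider <- function(score, aoff, nint, startj, pairs) {
    b <- best
    take <- score > b$score + 1e-9 ||
      (abs(score - b$score) <= 1e-9 && !is.null(pairs) &&
         (is.null(b$pairs) && FALSE ||
          (!is.null(b$pairs) &&
             (aoff < b$aoff ||
              (aoff == b$aoff && (nint < b$nint ||
                                  (nint == b$nint && startj < b$startj)))))))
    if (take) best <<- list(score = score, aoff = aoff, nint = nint,
                            startj = startj, pairs = pairs)
  }
  recurse <- function(i_prev, j_prev, score, aoff, nint, pairs) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes) .stopf("exhaustive enumeration exceeded %g nodes", max_nodes)
    if (i_prev >= L || j_prev <= 1L) return(invisible())
    for (i in seq.int(i_prev + 1L, L)) {
      if (i < p0) next
      jmax <- j_prev - 1L
      for (j in seq_len(jmax)) {
        cls <- clsmat[i, j]
        if (is.na(cls)) next
        if (is.null(pairs)) {
          off <- (W - j) - (i - 9L)          # target loop minus miRNA loop
          pen <- params$offset_point * max(0L, abs(off) - params$offset_free)
          s2 <- pair_score(i, cls) - pen
          p2 <- list(c(i, j))
          consider(s2, abs(off), 0L, j, p2)
          recurse(i, j, s2, abs(off), 0L, p2)
        } else {
          last <- pairs[[length(pairs)]]
          gm <- i - last[1] - 1L
          gt <- last[2] - j - 1L
          gap <- max(gm, gt)
          s2 <- score + pair_score(i, cls) - params$interruption_point * gap
          n2 <- nint + (gap > 0L)
          p2 <- c(pairs, list(c(i, j)))
          consider(s2, aoff, n2, j, p2)
          recurse(i, j, s2, aoff, n2, p2)
        }
      }
    }
  }
  # seed the recursion with "no pairs chosen yet" (j_prev = W + 1 sentinel)
  recurse(p0 - 1L, W + 1L, 0, 0L, 0L, NULL)
  if (is.null(best$pairs) || best$score <= 1e-9) return(empty)
  mpos <- vapply(best$pairs, `[`, integer(1), 1L)
  jpos <- vapply(best$pairs, `[`, integer(1), 2L)
  score_configuration(mirna_seq, region_seq, seed_start,
                      pairs = data.frame(mirna_pos = mpos,
                                         target_pos = win["start"] + jpos - 1L),
                      params = params)
}

#' Render a pairing configuration as a text diagram
#'
#' Three lines: the paired stretch of the target (3'->5') on top, pair
#' symbols in the middle (`|` for Watson-Crick-Franklin, `:` for G:U
#' wobble), and the miRNA 3' region (5'->3') below. Bulged nucleotides on
#' either strand appear against `-` on the opposite strand. The empty
#' configuration renders an empty middle line.
#'
#' @param config A `pairing_config`.
#' @param mirna_seq Mature miRNA sequence.
#' @param region_seq Transcript region sequence.
#' @return A single string containing the three newline-separated lines.
#' @export
pairing_string <- function(config, mirna_seq, region_seq) {
  if (nrow(config$pairs) == 0L) return("\n\n")
  mp <- config$pairs$mirna_pos
  tp <- config$pairs$target_pos
  cls <- config$pairs$pair_class
  top <- mid <- bot <- character()
  for (k in seq_along(mp)) {
    if (k > 1L) {
      gm <- mp[k] - mp[k - 1L] - 1L
      gt <- tp[k - 1L] - tp[k] - 1L
      if (gm > 0L || gt > 0L) {
        width <- max(gm, gt)
        mseq <- if (gm > 0L) .rna_chars(substr(mirna_seq, mp[k - 1L] + 1L,
                                               mp[k] - 1L)) else character()
        tseq <- if (gt > 0L) rev(.rna_chars(substr(region_seq, tp[k] + 2L,
                                                   tp[k - 1L]))) else character()
        top <- c(top, c(tseq, rep("-", width - gt)))
        mid <- c(mid, rep(" ", width))
        bot <- c(bot, c(mseq, rep("-", width - gm)))
      }
    }
    top <- c(top, substr(region_seq, tp[k] + 1L, tp[k] + 1L))
    mid <- c(mid, if (cls[k] == "WCF") "|" else ":")
    bot <- c(bot, substr(mirna_seq, mp[k], mp[k]))
  }
  paste(paste(top, collapse = ""), paste(mid, collapse = ""),
        paste(bot, collapse = ""), sep = "\n")
}

# compact single-line encoding used in candidate TSVs
.encode_pairs <- function(config) {
  if (nrow(config$pairs) == 0L) return("")
  paste(sprintf("%d-%d%s", config$pairs$mirna_pos, config$pairs$target_pos,
                ifelse(config$pairs$pair_class == "WCF", "W", "G")),
        collapse = ";")
}
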