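test_that("prefix index groups miRNAs by their first 19 nt", {
  m <- sim_mirnas(6, seed = 71)
  idx <- build_prefix_index(m)
  expect_equal(sort(idx$group_ids), sort(m$mirna_id))
  expect_false(any(idx$ambiguous))

  mc <- sim_mirnas(6, collision_pair = TRUE, seed = 72)
  idxc <- build_prefix_index(mc)
  expect_equal(sum(idxc$ambiguous), 1L)
  amb <- idxc$group_ids[idxc$ambiguous]
  expect_match(amb, "\\+")                      # merged, sorted group id

  short <- mirna_set("tiny", "ACGUACGUACGUACGUAC")   # 18 nt
  expect_error(build_prefix_index(short), "tiny")
})

test_that("reads are assigned on the 19-nt prefix only, with no mismatches", {
  m <- sim_mirnas(4, seed = 73)
  idx <- build_prefix_index(m)
  full <- m$sequence[1]
  # a read matching through nt 19 but differing at nt 20 is still assigned
  alt20 <- paste0(substr(full, 1, 19),
                  setdiff(c("A", "C", "G", "U"), substr(full, 20, 20))[1],
                  substr(full, 21, nchar(full)))
  # a read with a single mismatch at nt 10 is unassigned
  mm10 <- paste0(substr(full, 1, 9),
                 setdiff(c("A", "C", "G", "U"), substr(full, 10, 10))[1],
                 substr(full, 11, nchar(full)))
  res <- assign_reads(c(full, alt20, mm10, "ACGU"), idx)
  expect_equal(res$counts$count[res$counts$group_id == m$mirna_id[1]], 2L)
  expect_equal(res$unassigned, 2L)              # mismatch + short read
})

test_that("assigned + unassigned + spike-in counts conserve the read total", {
  m <- sim_mirnas(5, seed = 74)
  sp <- mirna_set(c("spike1", "spike2"),
                  c(rand_rna(22), rand_rna(22)))
  idx <- build_prefix_index(m, spikeins = sp)
  set.seed(74)
  reads <- c(sim_reads(m, stats::setNames(c(5, 4, 3, 2, 1), m$mirna_id),
                       2000, spikeins = sp, spikein_counts = 50),
             replicate(100, rand_rna(22)))
  res <- assign_reads(reads, idx)
  expect_equal(sum(res$counts$count) + sum(res$spikein_counts$count) +
                 res$unassigned, length(reads))
  expect_equal(sum(res$spikein_counts$count), 100L)
})

test_that("cpm sums to one million per sample, spike-ins excluded", {
  m <- sim_mirnas(5, seed = 75)
  sp <- mirna_set("spike1", rand_rna(22))
  idx <- build_prefix_index(m, spikeins = sp)
  ab <- stats::setNames(c(10, 8, 4, 2, 1), m$mirna_id)
  reads <- list(
    wt1 = sim_reads(m, ab, 5000, spikeins = sp, spikein_counts = 40, seed = 751),
    ko1 = sim_reads(m, ab, 5000, spikeins = sp, spikein_counts = 40, seed = 752))
  tab <- quantify_samples(reads, idx)
  sums <- tapply(tab$cpm, tab$sample_id, sum)
  expect_equal(as.numeric(sums), rep(1e6, 2), tolerance = 1e-9)
  expect_false(any(grepl("spike", tab$group_id)))
})

test_that("cluster normalization matches hand-computed ratios", {
  tab <- data.frame(
    sample_id = rep(c("wt1", "wt2", "mut1"), each = 3),
    group_id = rep(c("mirX", "p1", "p2"), 3),
    cpm = c(100, 50, 200,   120, 60, 240,   240, 50, 200))
  out <- cluster_normalize(tab, "mirX", c("p1", "p2"), c("wt1", "wt2"))
  # geometric mean of (50, 200) is 100 -> wt ratios 1.0 and 1.2
  expect_equal(out$ratio[out$sample_id == "wt1"], 1.0)
  expect_equal(out$ratio[out$sample_id == "mut1"], 2.4)
  expect_equal(mean(out$fold_change[out$is_control]), 1.0, tolerance = 1e-12)

  # single partner reduces to a simple ratio
  tab1 <- tab[tab$group_id != "p2", ]
  tab1$cpm[tab1$group_id == "mirX" & tab1$sample_id == "wt1"] <- 40
  tab1$cpm[tab1$group_id == "p1" & tab1$sample_id == "wt1"] <- 20
  out1 <- cluster_normalize(tab1, "mirX", "p1", c("wt1", "wt2"))
  expect_equal(out1$ratio[out1$sample_id == "wt1"], 2.0)

  # zero partner cpm flags that sample undefined and drops it from the mean
  tab0 <- tab
  tab0$cpm[tab0$group_id == "p1" & tab0$sample_id == "wt2"] <- 0
  expect_warning(out0 <- cluster_normalize(tab0, "mirX", c("p1", "p2"),
                                           c("wt1", "wt2")), "wt2")
  expect_true(is.na(out0$ratio[out0$sample_id == "wt2"]))
  expect_equal(out0$fold_change[out0$sample_id == "wt1"], 1.0)
})

test_that("planted expression ratios are recovered from simulated reads", {
  m <- sim_mirnas(8, cluster_sizes = c(2), seed = 76)
  idx <- build_prefix_index(m)
  ab_wt <- stats::setNames(rep(100, 8), m$mirna_id)
  ab_ko <- ab_wt
  ab_ko[m$mirna_id[1]] <- 240                  # planted 2.4x on the guide
  reads <- list(
    wt1 = sim_reads(m, ab_wt, 1e5, seed = 761),
    wt2 = sim_reads(m, ab_wt, 1e5, seed = 762),
    ko1 = sim_reads(m, ab_ko, 1e5, seed = 763))
  tab <- quantify_samples(reads, idx)
  out <- cluster_normalize(tab, m$mirna_id[1], m$mirna_id[2],
                           c("wt1", "wt2"))
  fc <- out$fold_change[out$sample_id == "ko1"]
  # normalizing to the partner cancels sequencing depth, so the planted
  # cpm ratio of 2.4 should be recovered within sampling error
  expect_gt(fc, 2.4 * 0.9)
  expect_lt(fc, 2.4 * 1.1)
})

test_that("sensitivity calls require significance and upregulation", {
  de <- data.frame(mirna_id = c("up", "down", "weak", "nop"),
                   log2fc = c(1.2, -1.2, 1.2, 0.8),
                   padj = c(0.001, 0.001, 0.2, NA))
  expect_warning(hits <- call_sensitive(de), "skipped")
  expect_equal(hits, "up")
  expect_equal(suppressWarnings(call_sensitive(de, min_log2fc = 2)),
               character(0))
})
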