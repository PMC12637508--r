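test_that("generators are pure functions of their seed", {
  expect_identical(sim_mirnas(10, seed = 91), sim_mirnas(10, seed = 91))
  expect_false(identical(sim_mirnas(10, seed = 91), sim_mirnas(10, seed = 92)))
  m <- sim_mirnas(4, seed = 91)
  s1 <- sim_transcriptome(m, n_transcripts = 8, length = 300, seed = 5)
  s2 <- sim_transcriptome(m, n_transcripts = 8, length = 300, seed = 5)
  expect_identical(s1, s2)
  expect_identical(sim_de_table(100, seed = 3), sim_de_table(100, seed = 3))
  expect_identical(sim_reads(m, stats::setNames(rep(1, 4), m$mirna_id), 100,
                             seed = 7),
                   sim_reads(m, stats::setNames(rep(1, 4), m$mirna_id), 100,
                             seed = 7))
})

test_that("simulated miRNAs have unique prefixes unless a collision is asked", {
  m <- sim_mirnas(10, seed = 93)
  expect_equal(anyDuplicated(substr(m$sequence, 1, 19)), 0L)
  mc <- sim_mirnas(10, collision_pair = TRUE, seed = 93)
  pref <- substr(mc$sequence, 1, 19)
  expect_equal(sum(duplicated(pref)), 1L)
  expect_equal(pref[9], pref[10])
  expect_false(mc$sequence[9] == mc$sequence[10])
})

test_that("cluster specification wires up normalization partners", {
  m <- sim_mirnas(6, cluster_sizes = c(2, 3), seed = 94)
  expect_equal(m$cluster_id[1:2], rep("cluster1", 2))
  expect_equal(m$partners[1], m$mirna_id[2])
  expect_equal(sort(strsplit(m$partners[3], ",")[[1]]),
               sort(m$mirna_id[4:5]))
  expect_equal(m$partners[6], "")
})

test_that("planted sites realize exactly their recorded expected score", {
  pats <- list(trigger_pattern(13:22),
               trigger_pattern(c(13:16, 18:22)),
               trigger_pattern(13:21, gu = 22),
               trigger_pattern(13:22, offset = 5),
               trigger_pattern(integer(0)))
  expected <- c(11, 9, 10.5, 10, 0)
  for (k in seq_along(pats)) {
    pl <- plant_trigger_site(LET7, pats[[k]], seed = 950 + k)
    expect_equal(pl$truth$expected_score, expected[k])
    got <- best_configuration(LET7, pl$region$sequence, pl$truth$seed_start)
    if (expected[k] > 0) {
      # strong planted patterns are the window optimum
      expect_equal(got$total_score, expected[k], info = sprintf("pattern %d", k))
    } else {
      # a seed-only site scores 0 by intent; the search may still pick up
      # weak chance complementarity in the random window
      expect_gte(got$total_score, 0)
    }
  }
})

test_that("planted site types are realized in the emitted transcript", {
  for (st in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    pl <- plant_trigger_site(LET7, trigger_pattern(13:22), site_type = st,
                             seed = 96)
    m <- find_seed_matches(LET7, pl$region$sequence)
    hit <- m[m$seed_start == pl$truth$seed_start, ]
    expect_equal(hit$site_type, st)
  }
})

test_that("inconsistent patterns are rejected", {
  expect_error(trigger_pattern(13:22, gu = 20), "overlap")
  expect_error(trigger_pattern(wcf = c(5, 13)), ">= 9")
  # wobble requested where the miRNA base admits none
  expect_error(plant_trigger_site(LET7, trigger_pattern(13:16, gu = 17),
                                  seed = 97), "wobble")
})

test_that("simulated reads follow the abundance vector", {
  m <- sim_mirnas(2, seed = 98)
  ab <- stats::setNames(c(3, 1), m$mirna_id)
  reads <- sim_reads(m, ab, 40000, seed = 98)
  frac <- mean(reads == m$sequence[1])
  expect_equal(frac, 0.75, tolerance = 0.02)
  one <- sim_reads(m[1, ], stats::setNames(1, m$mirna_id[1]), 1000, seed = 98)
  expect_true(all(one == m$sequence[1]))
  sp <- mirna_set("spike1", rand_rna(22))
  with_sp <- sim_reads(m, ab, 100, spikeins = sp, spikein_counts = 50,
                       seed = 98)
  expect_equal(sum(with_sp == sp$sequence), 50L)
})

test_that("synthetic alignments round-trip through MAF files", {
  pl <- plant_trigger_site(LET7, trigger_pattern(13:22), length = 100,
                           seed = 99)
  b <- sim_alignment(pl$region$sequence,
                     list(rat = list(subs = data.frame(pos = 3, base = "A")),
                          human = list(del = 10:12)))
  f <- withr::local_tempfile(fileext = ".maf")
  write_maf(list(b), f)
  back <- read_maf(f)
  expect_length(back, 1L)
  expect_identical(back[[1]]$text, b$text)
  expect_identical(back[[1]]$ref, b$ref)
})

test_that("de tables plant the requested target shift", {
  g <- sim_de_table(4000, delta = -0.4, sigma = 0.1, target_fraction = 0.3,
                    seed = 100)
  tmean <- mean(g$log2fc[g$target_of != ""])
  ntmean <- mean(g$log2fc[g$target_of == ""])
  expect_equal(tmean - ntmean, -0.4, tolerance = 0.02)
  expect_true(all(is.na(g$contextpp_score[g$target_of == ""])))
  expect_true(all(!is.na(g$contextpp_score[g$target_of != ""])))
})
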