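# helpers: realize a pattern in a synthetic transcript and score either the
# intended configuration (fixed) or the search optimum
plant <- function(pattern, seed = 1, mirna = LET7, ...) {
  plant_trigger_site(mirna, pattern, seed = seed, ...)
}

planted_config <- function(pattern, seed = 1, mirna = LET7,
                           params = score_params()) {
  pl <- plant(pattern, seed, mirna, params = params)
  list(planted = pl,
       best = best_configuration(mirna, pl$region$sequence,
                                 pl$truth$seed_start, params))
}

test_that("the point scheme scores hand-checked configurations", {
  # contiguous WCF over nt 13-22: 10 match points + 0.5 each at nt 20 and 21
  a <- plant(trigger_pattern(13:22), seed = 21)
  cfg <- best_configuration(LET7, a$region$sequence, a$truth$seed_start)
  expect_equal(cfg$total_score, 11)
  expect_equal(unname(cfg$breakdown),
               c(10, 1, 0, 0, 0))

  # 1x1 mismatch at nt 17: one lost match point and a 1-point interruption
  b <- plant(trigger_pattern(c(13:16, 18:22)), seed = 22)
  cfgb <- best_configuration(LET7, b$region$sequence, b$truth$seed_start)
  expect_equal(cfgb$total_score, 9)
  expect_equal(cfgb$breakdown[["base_points"]], 9)
  expect_equal(cfgb$breakdown[["interruption_penalty"]], 1)

  # G:U wobble at the final nt: no match point, 0.5 terminal wobble bonus
  c_ <- plant(trigger_pattern(13:21, gu = 22), seed = 23)
  cfgc <- best_configuration(LET7, c_$region$sequence, c_$truth$seed_start)
  expect_equal(cfgc$total_score, 10.5)
  expect_equal(cfgc$breakdown[["terminal_wobble_bonus"]], 0.5)
  expect_equal(cfgc$breakdown[["base_points"]], 9)

  # offset 5: 0.5 x (5 - 3) penalty
  d <- plant(trigger_pattern(13:22, offset = 5), seed = 24)
  cfgd <- best_configuration(LET7, d$region$sequence, d$truth$seed_start)
  expect_equal(cfgd$total_score, 10)
  expect_equal(cfgd$breakdown[["offset_penalty"]], 1)
  expect_equal(cfgd$offset, 5)

  # the empty configuration is the additive identity
  e <- score_configuration(LET7, rand_rna(100), 60, NULL)
  expect_equal(e$total_score, 0)
  expect_equal(sum(abs(e$breakdown)), 0)
})

test_that("inconsistent pair labels are rejected with the position named", {
  pl <- plant(trigger_pattern(13:22), seed = 31)
  cfg <- best_configuration(LET7, pl$region$sequence, pl$truth$seed_start)
  pairs <- cfg$pairs
  pairs$pair_class[3] <- "GU"
  expect_error(score_configuration(LET7, pl$region$sequence,
                                   pl$truth$seed_start, pairs),
               as.character(pairs$mirna_pos[3]))
})

test_that("breakdown components sum to the total on searched configurations", {
  set.seed(77)
  for (k in 1:40) {
    mir <- rand_rna(sample(20:24, 1))
    reg <- rand_rna(300)
    cfg <- best_configuration(mir, reg, sample(40:250, 1))
    b <- cfg$breakdown
    expect_equal(cfg$total_score,
                 b[["base_points"]] + b[["end_bonus"]] +
                   b[["terminal_wobble_bonus"]] -
                   b[["interruption_penalty"]] - b[["offset_penalty"]])
    expect_gte(cfg$total_score, 0)
  }
})

test_that("the search recovers a planted perfect 3' duplex exactly", {
  res <- planted_config(trigger_pattern(13:22), seed = 41)
  expect_equal(res$best$total_score, res$planted$truth$expected_score)
  expect_equal(res$best$pairs$mirna_pos, 13:22)
  expect_equal(res$best$offset, 0)
})

test_that("degenerate windows yield the empty configuration", {
  # seed right at the transcript start: no upstream window at all
  cfg <- best_configuration(LET7, "CUACCUCAGGG", 1)
  expect_equal(cfg$total_score, 0)
  expect_equal(nrow(cfg$pairs), 0)
  # window of all A against a 3' region with no pairing partner for A
  mir <- paste0("UGAGGUAG", paste(rep("C", 12), collapse = ""))  # 3' all C
  reg <- paste0(paste(rep("A", 40), collapse = ""), "CUACCUCA")
  cfg2 <- best_configuration(mir, reg, 41)
  expect_equal(cfg2$total_score, 0)
})

test_that("extending a terminal helix contiguously never lowers the score", {
  set.seed(55)
  for (k in 1:10) {
    pl <- plant(trigger_pattern(13:22), seed = 500 + k)
    full <- best_configuration(LET7, pl$region$sequence, pl$truth$seed_start)
    scores <- vapply(16:22, function(last) {
      sub <- full$pairs[full$pairs$mirna_pos <= last, ]
      score_configuration(LET7, pl$region$sequence, pl$truth$seed_start,
                          sub)$total_score
    }, numeric(1))
    expect_true(all(diff(scores) >= 0))
  }
})

test_that("the dynamic program matches the exhaustive oracle", {
  set.seed(66)
  for (k in 1:150) {
    L <- sample(16:18, 1)            # 3' region of 8-10 nt
    mir <- rand_rna(L)
    W <- sample(6:14, 1)
    reg <- rand_rna(W + 12)
    p <- score_params(window = W)
    b <- best_configuration(mir, reg, W + 1, p)
    e <- exhaustive_best(mir, reg, W + 1, p)
    expect_equal(b$total_score, e$total_score)
  }
})

test_that("the exhaustive oracle refuses oversized instances", {
  expect_error(exhaustive_best(rand_rna(22), rand_rna(60), 40), "too large")
})

test_that("pairing strings follow the diagram convention", {
  a <- planted_config(trigger_pattern(13:22), seed = 81)
  d1 <- pairing_string(a$best, LET7, a$planted$region$sequence)
  lines <- strsplit(d1, "\n")[[1]]
  expect_equal(nchar(gsub("[^|]", "", lines[2])), 10L)
  # miRNA line reads 5'->3' over positions 13-22
  expect_equal(lines[3], substr(LET7, 13, 22))

  b <- planted_config(trigger_pattern(13:21, gu = 22), seed = 82)
  d2 <- pairing_string(b$best, LET7, b$planted$region$sequence)
  expect_equal(nchar(gsub("[^:]", "", strsplit(d2, "\n")[[1]][2])), 1L)

  reg <- rand_rna(80)
  e <- score_configuration(LET7, reg, 50, NULL)
  expect_equal(strsplit(pairing_string(e, LET7, reg), "\n")[[1]][2], "")
})
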