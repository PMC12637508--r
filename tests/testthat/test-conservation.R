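# alignments are built with the synthetic generator; the reference sequence
# carries a planted let-7 trigger site so re-scoring has a real optimum
planted_block <- function(species_spec = list(), seed = 61,
                          pattern = trigger_pattern(13:22)) {
  pl <- plant_trigger_site(LET7, pattern, length = 120, seed = seed)
  list(pl = pl,
       block = sim_alignment(pl$region$sequence, species_spec, ref_name = "mouse"))
}

mirna_block <- function(species_spec = list()) {
  sim_alignment(LET7, species_spec, ref_name = "mouse")
}

test_that("species site extraction slices columns and strips gaps", {
  b <- sim_alignment("ACGUACGUAC",
                     list(rat = list(subs = data.frame(pos = 2, base = "U")),
                          human = list(del = 3:5)),
                     ref_name = "mouse")
  out <- extract_species_site(b, c(2, 8))
  expect_equal(out$sequence[out$species == "mouse"], "GUACGU")
  expect_equal(out$sequence[out$species == "rat"], "UUACGU")
  expect_equal(out$sequence[out$species == "human"], "GGU")
  expect_false(any(out$missing))
  # fully gapped species gets an explicit missing flag
  b2 <- sim_alignment("ACGUACGUAC", list(frog = list(del = 0:9)))
  out2 <- extract_species_site(b2, c(3, 7))
  expect_true(out2$missing[out2$species == "frog"])
  expect_error(extract_species_site(b, c(5, 20)), "outside")
})

test_that("insertions in other species lengthen their site, not the reference", {
  b <- sim_alignment("ACGUACGUAC",
                     list(rat = list(ins = list(after = 4, seq = "GGG"))))
  out <- extract_species_site(b, c(0, 10))
  expect_equal(nchar(out$sequence[out$species == "mouse"]), 10L)
  expect_equal(nchar(out$sequence[out$species == "rat"]), 13L)
})

test_that("species miRNAs are projected with low-confidence flags", {
  mb <- mirna_block(list(
    monkey = list(subs = data.frame(pos = 16, base = "C")),
    frog = list(del = 5:9)))
  out <- predict_species_mirna(mb, c(0, nchar(LET7)))
  expect_equal(out$sequence[out$species == "mouse"], LET7)
  monkey <- out$sequence[out$species == "monkey"]
  expect_equal(substr(monkey, 17, 17), "C")
  expect_equal(substr(monkey, 1, 16), substr(LET7, 1, 16))
  expect_true(out$low_confidence[out$species == "frog"])   # 5-nt deletion
  expect_false(out$low_confidence[out$species == "monkey"])
})

test_that("re-scoring across species reproduces the reference score exactly", {
  pb <- planted_block(list(rat = list(), human = list()))
  ref_cfg <- best_configuration(LET7, pb$pl$region$sequence,
                                pb$pl$truth$seed_start)
  prof <- score_across_species(pb$block, c(0, 120),
                               mirna_block(list(rat = list(), human = list())),
                               c(0, nchar(LET7)), ref_site_type = "8mer")
  expect_equal(sort(prof$species), c("human", "mouse", "rat"))
  expect_equal(prof$total_score[prof$species == "mouse"], ref_cfg$total_score)
  # identical species score identically
  expect_equal(unique(prof$total_score), ref_cfg$total_score)
  expect_true(all(prof$seed_intact))
})

test_that("a seed-disrupting substitution flags only that species", {
  pb <- planted_block()
  seed_pos <- pb$pl$truth$seed_start + 2       # inside the 6mer core
  pb2 <- planted_block(list(
    rat = list(),
    mole = list(subs = data.frame(pos = seed_pos,
                                  base = "A"))),
    seed = 61)
  # ensure the substitution actually changed the core base
  core_base <- substr(pb2$pl$region$sequence, seed_pos + 1, seed_pos + 1)
  if (core_base == "A") {
    pb2 <- planted_block(list(rat = list(),
                              mole = list(subs = data.frame(pos = seed_pos,
                                                            base = "G"))),
                         seed = 61)
  }
  prof <- score_across_species(pb2$block, c(0, 120),
                               mirna_block(list(rat = list(), mole = list())),
                               c(0, nchar(LET7)), ref_site_type = "8mer")
  expect_true(prof$seed_intact[prof$species == "rat"])
  expect_false(prof$seed_intact[prof$species == "mole"])
})

test_that("reference-gapped insertion columns do not change the reference score", {
  pb <- planted_block(list(rat = list(ins = list(after = 10, seq = "ACACA"))))
  ref_cfg <- best_configuration(LET7, pb$pl$region$sequence,
                                pb$pl$truth$seed_start)
  prof <- score_across_species(pb$block, c(0, 120),
                               mirna_block(list(rat = list())),
                               c(0, nchar(LET7)), ref_site_type = "8mer")
  expect_equal(prof$total_score[prof$species == "mouse"], ref_cfg$total_score)
})

test_that("covariation requires substitutions on both sides of a pair", {
  pb <- planted_block(seed = 63)
  cfg <- best_configuration(LET7, pb$pl$region$sequence,
                            pb$pl$truth$seed_start)
  ref_pairs <- data.frame(mirna_pos = cfg$pairs$mirna_pos,
                          site_pos = cfg$pairs$target_pos)
  # partner site position of miRNA nt 17 (0-based in the site interval)
  p17 <- ref_pairs$site_pos[ref_pairs$mirna_pos == 17]
  # compensatory double substitution at nt 17: miRNA U->G with site A->C
  mb <- mirna_block(list(monkey = list(subs = data.frame(pos = 16, base = "G"))))
  sb <- sim_alignment(pb$pl$region$sequence,
                      list(monkey = list(subs = data.frame(pos = p17,
                                                           base = "C"))),
                      ref_name = "mouse")
  ev <- detect_covariation(sb, c(0, 120), mb, c(0, nchar(LET7)), ref_pairs)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$mirna_pos, 17)
  expect_true(ev$pairing_preserved)            # G:C still pairs
  expect_equal(ev$species, "monkey")

  # miRNA-only substitution is not an event
  ev2 <- detect_covariation(pb$block, c(0, 120), mb, c(0, nchar(LET7)),
                            ref_pairs)
  expect_equal(nrow(ev2), 0L)

  # no substitutions anywhere -> no events
  ev3 <- detect_covariation(pb$block, c(0, 120), mirna_block(),
                            c(0, nchar(LET7)), ref_pairs)
  expect_equal(nrow(ev3), 0L)
})
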