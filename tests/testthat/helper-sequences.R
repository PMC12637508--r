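# shared fixtures, built in code

# a let-7a-like 22-nt miRNA used throughout the scoring tests
LET7 <- "UGAGGUAGUAGGUUGUAUAGUU"

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

# brute-force seed-match oracle: substring scan over the four site strings
naive_seed_scan <- function(mirna_seq, region_seq) {
  strings <- seed_site_strings(mirna_seq)
  core <- strings[["6mer"]]
  n <- nchar(region_seq)
  starts <- integer(0)
  if (n >= 6) {
    for (i in seq_len(n - 5L)) {
      if (substr(region_seq, i, i + 5L) == core) starts <- c(starts, i - 1L)
    }
  }
  types <- vapply(starts, function(s) {
    has_m8 <- s >= 1L &&
      substr(region_seq, s, s + 6L) == strings[["7mer-m8"]]
    has_a1 <- s + 7L <= n &&
      substr(region_seq, s + 1L, s + 7L) == strings[["7mer-A1"]]
    if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
    else if (has_a1) "7mer-A1" else "6mer"
  }, character(1))
  data.frame(seed_start = starts, site_type = types)
}
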