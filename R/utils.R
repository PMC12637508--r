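# Internal sequence helpers shared across modules.

RNA_BASES <- c("A", "C", "G", "U")

.rna_validate <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGU]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains non-RNA characters (allowed: A, C, G, U)", what),
         call. = FALSE)
  }
  invisible(seq)
}

.rna_codes <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], RNA_BASES) - 1L
}

.rna_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA string (5'->3', alphabet A/C/G/U).
#' @return The reverse complement, 5'->3'.
#' @export
rc_rna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .rna_validate(seq)
  comp <- chartr("ACGU", "UGCA", seq)
  paste(rev(.rna_chars(comp)), collapse = "")
}

.wc_complement <- function(base) chartr("ACGU", "UGCA", base)

# Pair class of one miRNA base against one target base:
# "WCF", "GU", or NA when the bases cannot pair.
.pair_class <- function(mirna_base, target_base) {
  p <- paste0(mirna_base, target_base)
  ifelse(p %in% c("AU", "UA", "CG", "GC"), "WCF",
         ifelse(p %in% c("GU", "UG"), "GU", NA_character_))
}

# uniform random RNA of given length with a target GC fraction
.random_rna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(RNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
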