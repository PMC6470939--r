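# Internal sequence helpers.  All sequences are held in the DNA alphabet
# (U -> T on input); reverse complement and base sampling are used constantly
# by the generators, so these stay as cheap vectorized base-R/stringi calls.

.dna_bases <- c("A", "C", "G", "T")

dna_norm <- function(x) {
  x <- toupper(x)
  chartr("U", "T", x)
}

revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

check_dna <- function(x, what = "sequence") {
  bad <- stringi::stri_detect_regex(x, "[^ACGT]")
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T}: ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

random_dna <- function(n_chars, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.dna_bases, n_chars, replace = TRUE, prob = p), collapse = "")
}

gc_percent <- function(x) {
  100 * stringi::stri_count_regex(x, "[GC]") / nchar(x)
}

# deterministic child seeds (kept well below 2^31)
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
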