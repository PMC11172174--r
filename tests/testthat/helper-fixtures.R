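# Shared fixture builders (all generated in code, seeded).

fixture_panel <- function(n = 5L, len = 600L, seed = 1L) {
  synthetic_te_panel(n, len, seed)
}

panel_refs <- function(panel) {
  stats::setNames(panel$consensus, panel$family)
}

random_reads <- function(n, len, seed, prefix = "r") {
  withr::with_seed(seed, {
    stats::setNames(
      vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
        character(1)),
      paste0(prefix, seq_len(n)))
  })
}

rand_dna_fixture <- function(len, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len, TRUE),
                               collapse = ""))
}

# Reads planted as substrings (or revcomp substrings) of a reference.
planted_reads <- function(reference, n, len, seed, revcomp_frac = 0.5) {
  withr::with_seed(seed, {
    m <- nchar(reference)
    s <- sample.int(m - len + 1L, n, replace = TRUE)
    seqs <- substring(reference, s, s + len - 1L)
    flip <- runif(n) < revcomp_frac
    seqs[flip] <- revcomp(seqs[flip])
    stats::setNames(seqs, sprintf("p%04d", seq_len(n)))
  })
}
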