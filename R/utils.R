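# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over the alphabet A, C, G, T, N.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# Draw random DNA sequences. Uses the current RNG stream; callers are
# responsible for seeding.
rand_dna <- function(n, length) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

# Substitute each site independently with probability `p`, always to a
# different base (no indels, so coordinates stay 1:1).
mutate_dna <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Round half-up to `digits` decimals (base round() is half-even; printed
# tables in this field use half-up).
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Validate a single integer-ish scalar.
check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be in [0, 1]", name), call. = FALSE)
  }
  x
}

# Run `expr` with a temporarily-seeded RNG, restoring the caller's RNG
# state afterwards so simulations are reproducible but non-invasive.
with_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed")
  withr::with_seed(seed, expr)
}
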