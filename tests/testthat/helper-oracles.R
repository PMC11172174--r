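# Independent brute-force oracles. These deliberately share no code with
# the package implementation: naive character-by-character scans and
# hand-written step-up formulas, feasible at fixture scale.

# Exhaustive O(n*m) Hamming scan over every window of every reference,
# both strands. N mismatches everything.
oracle_map <- function(reads, references, max_mismatch) {
  rc <- function(s) {
    paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])),
          collapse = "")
  }
  rows <- list()
  k <- 0L
  for (id in names(reads)) {
    for (st in c("+", "-")) {
      q <- if (st == "+") reads[[id]] else rc(reads[[id]])
      qc <- strsplit(q, "")[[1]]
      L <- length(qc)
      for (rn in names(references)) {
        refc <- strsplit(references[[rn]], "")[[1]]
        if (length(refc) < L) next
        for (p in 1:(length(refc) - L + 1)) {
          w <- refc[p:(p + L - 1)]
          mm <- sum(w != qc | w == "N" | qc == "N")
          if (mm <= max_mismatch) {
            k <- k + 1L
            rows[[k]] <- data.frame(read_id = id, ref_id = rn,
                                    start = p - 1L, strand = st,
                                    mismatches = mm, width = L,
                                    stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (k == 0L) {
    return(data.frame(read_id = character(0), ref_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), width = integer(0)))
  }
  do.call(rbind, rows)
}

# Canonical sort for order-insensitive alignment comparison.
sort_aln <- function(a) {
  a <- a[order(a$read_id, a$ref_id, a$start, a$strand, a$mismatches), ,
         drop = FALSE]
  rownames(a) <- NULL
  a[, c("read_id", "ref_id", "start", "strand", "mismatches", "width")]
}

# Naive longest-suffix adapter trim.
oracle_trim <- function(seq, adapter, min_overlap) {
  L <- nchar(seq)
  best <- NA_integer_
  for (o in min_overlap:min(L, nchar(adapter))) {
    if (substr(seq, L - o + 1, L) == substr(adapter, 1, o)) best <- o
  }
  if (is.na(best)) seq else substr(seq, 1, L - best)
}

# Hand-written BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Direct z10 recomputation from a counts vector over 1..30.
oracle_z10 <- function(counts) {
  bg <- counts[-10]
  (counts[10] - mean(bg)) / sd(bg)
}
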