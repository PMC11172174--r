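# Ortholog resolution from tabular homology hits, allele-specific hybrid
# expression, dosage-category classification, and the AT-chX / vasa
# cross-set ping-pong report.

#' Resolve orthologous gene pairs from homology hits
#'
#' Per query transcript, the maximum-bitscore hit is kept (ties broken
#' toward the lexicographically lower subject id and flagged). Transcripts
#' are grouped by query gene; a pair is accepted only when every
#' transcript of the gene agrees on a single subject gene. Subject genes
#' claimed by more than one accepted query gene are conflicted and all
#' claimants rejected, so a gene appears in at most one accepted pair.
#'
#' @param hits data.frame of homology hits as from [read_blast_tab()].
#' @param tx2gene_query,tx2gene_subject Named character vectors mapping
#'   transcript ids to gene ids for the query and subject species.
#' @return data.frame with columns `gene_query`, `gene_subject`,
#'   `support` (number of agreeing transcripts), `conflict`, `tie`,
#'   `accepted`.
#' @export
resolve_orthologs <- function(hits, tx2gene_query, tx2gene_subject) {
  missing_q <- setdiff(unique(hits$query_id), names(tx2gene_query))
  if (length(missing_q)) {
    stop("query transcripts missing from gene map: ",
         paste(missing_q, collapse = ", "), call. = FALSE)
  }
  missing_s <- setdiff(unique(hits$subject_id), names(tx2gene_subject))
  if (length(missing_s)) {
    stop("subject transcripts missing from gene map: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  if (nrow(hits) == 0L) {
    return(data.frame(gene_query = character(0), gene_subject = character(0),
                      support = integer(0), conflict = logical(0),
                      tie = logical(0), accepted = logical(0),
                      stringsAsFactors = FALSE))
  }
  # Best hit per query transcript: max bitscore, tie -> lower subject id.
  ord <- order(hits$query_id, -hits$bitscore, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  best <- h[!duplicated(h$query_id), , drop = FALSE]
  # A transcript is tie-flagged when another subject reaches its bitscore.
  key <- paste(h$query_id, h$bitscore)
  tie_tab <- tapply(h$subject_id, key, function(x) length(unique(x)) > 1L)
  best$tie <- as.logical(tie_tab[paste(best$query_id, best$bitscore)])

  best$gene_query <- unname(tx2gene_query[best$query_id])
  best$gene_subject <- unname(tx2gene_subject[best$subject_id])

  by_gene <- split(best, best$gene_query)
  pairs <- do.call(rbind, lapply(by_gene, function(b) {
    subj <- unique(b$gene_subject)
    data.frame(gene_query = b$gene_query[1L],
               gene_subject = sort(subj)[1L],
               support = nrow(b),
               conflict = length(subj) > 1L,
               tie = any(b$tie),
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  # One accepted claimant per subject gene; multiple claimants conflict.
  cand <- !pairs$conflict
  claimed <- table(pairs$gene_subject[cand])
  multi <- names(claimed)[claimed > 1L]
  pairs$conflict <- pairs$conflict |
    (cand & pairs$gene_subject %in% multi)
  pairs$accepted <- !pairs$conflict
  pairs
}

#' Allele-specific expression of orthologs in a hybrid
#'
#' Replicates within each sample class are depth-normalized by
#' median-of-ratios size factors (falling back to column totals when no
#' feature is all-nonzero) and averaged; hybrid-allele /
#' same-species-parent ratios are then computed with a pseudocount.
#' Expression values must already be comparable across libraries
#' (tpm-like abundances, or counts generated at a common depth):
#' cross-library rescaling is deliberately not applied, because a global
#' factor estimated from the hybrid would absorb genuine allele-dosage
#' shifts. In an F1 hybrid each allele is present in a single copy, so
#' the expected ratio against the two-copy parental level is 0.5.
#'
#' @param parent_query,parent_subject,hybrid_query,hybrid_subject Numeric
#'   matrices (genes x replicates) of expression values; rownames are
#'   gene ids of the respective species.
#' @param pairs Accepted ortholog pairs from [resolve_orthologs()] (only
#'   rows with `accepted = TRUE` are used; others are skipped).
#' @param pseudocount Added to normalized means before ratios (default
#'   0.5).
#' @return data.frame with per-pair expression means and `ratio_query`,
#'   `ratio_subject` columns.
#' @export
allele_expression <- function(parent_query, parent_subject,
                              hybrid_query, hybrid_subject,
                              pairs, pseudocount = 0.5) {
  norm_mean <- function(m) {
    m <- as.matrix(m)
    sf <- tryCatch(size_factors(m), error = function(e) {
      cs <- colSums(m)
      if (all(cs > 0)) cs / mean(cs) else rep(1, ncol(m))
    })
    rowMeans(sweep(m, 2L, sf, "/"))
  }
  pq <- norm_mean(parent_query); ps <- norm_mean(parent_subject)
  hq <- norm_mean(hybrid_query); hs <- norm_mean(hybrid_subject)
  use <- pairs[pairs$accepted %||% rep(TRUE, nrow(pairs)), , drop = FALSE]
  gq <- use$gene_query; gs <- use$gene_subject
  stopifnot(all(gq %in% names(pq)), all(gs %in% names(ps)))
  data.frame(
    gene_query = gq, gene_subject = gs,
    parent_query = unname(pq[gq]), parent_subject = unname(ps[gs]),
    hybrid_query = unname(hq[gq]), hybrid_subject = unname(hs[gs]),
    ratio_query = unname((hq[gq] + pseudocount) / (pq[gq] + pseudocount)),
    ratio_subject = unname((hs[gs] + pseudocount) / (ps[gs] + pseudocount)),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify allele-dosage categories in the hybrid
#'
#' Per allele, the hybrid/parent ratio is called `over` when
#' `log2(ratio) > log2(0.5) + band_log2`, `under` when below
#' `log2(0.5) - band_log2`, and `expected` otherwise (the half-dose level
#' with a twofold band by default). The two per-allele calls determine the
#' category: both expected -> `expected`; exactly one over, other
#' expected -> `one_allele_over`; both over -> `both_over`; both under ->
#' `both_under`; anything else -> `mixed_other`.
#'
#' @param records data.frame from [allele_expression()].
#' @param band_log2 Half-width of the expected band in log2 units
#'   (default 1.0, i.e. a twofold band around the half-dose level).
#' @return `records` with `call_query`, `call_subject` and `category`
#'   columns added.
#' @export
classify_dosage <- function(records, band_log2 = 1.0) {
  call_one <- function(ratio) {
    lr <- log2(ratio)
    ifelse(lr > log2(0.5) + band_log2, "over",
           ifelse(lr < log2(0.5) - band_log2, "under", "expected"))
  }
  cq <- call_one(records$ratio_query)
  cs <- call_one(records$ratio_subject)
  category <- ifelse(cq == "expected" & cs == "expected", "expected",
              ifelse(cq == "over" & cs == "over", "both_over",
              ifelse(cq == "under" & cs == "under", "both_under",
              ifelse((cq == "over" & cs == "expected") |
                       (cs == "over" & cq == "expected"),
                     "one_allele_over", "mixed_other"))))
  records$call_query <- cq
  records$call_subject <- cs
  records$category <- category
  records
}

#' Dosage-category proportions
#'
#' @param records Output of [classify_dosage()].
#' @return Named numeric vector of category proportions over the five
#'   categories.
#' @export
dosage_proportions <- function(records) {
  lv <- c("expected", "one_allele_over", "both_over", "both_under",
          "mixed_other")
  tab <- table(factor(records$category, levels = lv))
  stats::setNames(as.numeric(tab) / sum(tab), lv)
}

#' Pearson correlation of log-scale expression
#'
#' Standard Pearson correlation of `log2(x + pseudocount)` against
#' `log2(y + pseudocount)`. Zero variance in either vector yields `NA`
#' with a warning.
#'
#' @param x,y Non-negative numeric vectors of equal length >= 3.
#' @param pseudocount Added before the log (default 0.5).
#' @return Correlation coefficient (or `NA` if undefined).
#' @export
expression_correlation <- function(x, y, pseudocount = 0.5) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  lx <- log2(x + pseudocount); ly <- log2(y + pseudocount)
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(lx, ly)
}

#' AT-chX / vasa allele piRNA report
#'
#' Maps a piRNA population to an X-linked repeat consensus and to each
#' vasa-like allele transcript (up to `max_mismatch` mismatches), then
#' scores cross-set ping-pong between consensus-matching piRNAs and the
#' full allele-mapped piRNA population on each allele's coordinates, with
#' per-position sense/antisense coverage tracks. Divergent alleles whose
#' repeat-homologous region exceeds the mismatch gate lose the
#' consensus-matching piRNA set and score low or undefined.
#'
#' @param reads Named character vector (or `read_library`) of processed
#'   piRNA reads.
#' @param consensus Single named character: the repeat consensus.
#' @param alleles Named character vector of allele transcript sequences.
#' @param max_mismatch Mismatch tolerance (default 3).
#' @return A list per allele with elements `score` (`pingpong_score`),
#'   `histogram`, `coverage` (data.frame pos/sense/antisense), plus
#'   `consensus_coverage` and `n_consensus_reads`.
#' @export
vasa_atchx_report <- function(reads, consensus, alleles, max_mismatch = 3L) {
  if (length(consensus) != 1L || is.null(names(consensus))) {
    stop("`consensus` must be a single named sequence", call. = FALSE)
  }
  aln_cons <- map_reads(reads, consensus, max_mismatch = max_mismatch,
                        policy = "all_hits")
  cons_reads <- unique(aln_cons$read_id)
  per_allele <- lapply(names(alleles), function(al) {
    aln <- map_reads(reads, alleles[al], max_mismatch = max_mismatch,
                     policy = "all_hits")
    # Set A: allele placements of consensus-matching piRNAs. Set B: all
    # allele-mapped piRNAs (membership may overlap; pairs need one member
    # from each set).
    set_a <- aln[aln$read_id %in% cons_reads, , drop = FALSE]
    cp <- cross_pingpong(set_a, aln)
    list(score = cp$score, histogram = cp$histogram,
         coverage = coverage_track(aln, nchar(alleles[[al]])),
         n_consensus_matched = nrow(set_a))
  })
  names(per_allele) <- names(alleles)
  list(alleles = per_allele,
       consensus_coverage = coverage_track(aln_cons, nchar(consensus[[1L]])),
       n_consensus_reads = length(cons_reads))
}

#' Per-position strand coverage of alignments on one reference
#'
#' @param alignments Alignment data.frame on a single reference.
#' @param ref_length Reference length in nt.
#' @return data.frame with columns `pos` (0-based), `sense`, `antisense`.
#' @export
coverage_track <- function(alignments, ref_length) {
  sense <- numeric(ref_length); anti <- numeric(ref_length)
  count <- if ("count" %in% names(alignments)) alignments$count else
    rep(1, nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    span <- (alignments$start[i] + 1L):(alignments$start[i] +
                                          alignments$width[i])
    if (alignments$strand[i] == "+") {
      sense[span] <- sense[span] + count[i]
    } else {
      anti[span] <- anti[span] + count[i]
    }
  }
  data.frame(pos = seq_len(ref_length) - 1L, sense = sense,
             antisense = anti)
}
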