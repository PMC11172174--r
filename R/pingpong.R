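# 5'-to-5' overlap histograms and the ping-pong z10 statistic.
#
# For a sense read with 5' end at coordinate p (= start) and an antisense
# read with 5' end at q (= start + width - 1, its highest coordinate), the
# pair contributes to overlap o = q - p + 1 when 1 <= o <= 30. A perfect
# ping-pong pair gives o = 10. Pair counting is exhaustive with abundance
# weighting: a read seen c times contributes c to each pairing.

PP_MAX_OVERLAP <- 30L
PP_FOCAL <- 10L

# Convolve sense and antisense 5' profiles into overlap counts 1..30.
overlap_counts <- function(aln_sense, w_sense, aln_anti, w_anti,
                           max_overlap = PP_MAX_OVERLAP) {
  counts <- stats::setNames(numeric(max_overlap),
                            as.character(seq_len(max_overlap)))
  if (nrow(aln_sense) == 0L || nrow(aln_anti) == 0L) return(counts)
  ps <- aln_sense$start
  qs <- aln_anti$start + aln_anti$width - 1L
  maxpos <- max(ps, qs)
  vs <- numeric(maxpos + 1L); va <- numeric(maxpos + 1L)
  for (i in seq_along(ps)) vs[ps[i] + 1L] <- vs[ps[i] + 1L] + w_sense[i]
  for (i in seq_along(qs)) va[qs[i] + 1L] <- va[qs[i] + 1L] + w_anti[i]
  for (o in seq_len(max_overlap)) {
    # q = p + o - 1
    pmax_ <- maxpos + 1L - (o - 1L)
    if (pmax_ < 1L) break
    counts[o] <- sum(vs[seq_len(pmax_)] * va[seq_len(pmax_) + (o - 1L)])
  }
  counts
}

#' Build a 5'-to-5' overlap histogram on one reference
#'
#' @param alignments data.frame of alignments restricted to a single
#'   reference (columns `read_id`, `ref_id`, `start`, `strand`, `width`);
#'   an optional `count` column carries per-read abundances (default 1).
#' @param max_overlap Largest overlap distance tabulated (default 30).
#' @return An object of class `overlap_histogram`: `counts` (named vector
#'   over 1..max_overlap), `n_pairs_total`, `normalized` (counts divided by
#'   the number of piRNAs on the reference) and `n_pirnas`.
#' @export
overlap_histogram <- function(alignments, max_overlap = PP_MAX_OVERLAP) {
  if (nrow(alignments) > 0L && length(unique(alignments$ref_id)) > 1L) {
    stop("alignments span more than one reference", call. = FALSE)
  }
  count <- if ("count" %in% names(alignments)) alignments$count else
    rep(1, nrow(alignments))
  sense <- alignments$strand == "+"
  counts <- overlap_counts(alignments[sense, , drop = FALSE], count[sense],
                           alignments[!sense, , drop = FALSE],
                           count[!sense], max_overlap)
  n_pirnas <- sum(count)
  structure(list(
    counts = counts,
    n_pairs_total = sum(counts),
    n_pirnas = n_pirnas,
    normalized = if (n_pirnas > 0) counts / n_pirnas else counts
  ), class = "overlap_histogram")
}

#' @export
print.overlap_histogram <- function(x, ...) {
  cat("overlap_histogram:", x$n_pairs_total, "pairs over",
      x$n_pirnas, "piRNAs\n")
  print(x$counts)
  invisible(x)
}

#' Ping-pong z10 score of an overlap histogram
#'
#' The 10-nt bin is compared against the background of the other overlap
#' bins (1..30 without 10 by default): `z10 = (counts[10] - mean(bg)) /
#' sd(bg)` with the sample standard deviation. A flat histogram scores 0;
#' an all-zero histogram, or a zero-SD background with a deviating focal
#' bin, yields an undefined (flagged) score.
#'
#' @param hist An `overlap_histogram`.
#' @param focal Focal overlap distance (default 10).
#' @param exclude_focal Exclude the focal bin from the background (default
#'   TRUE, the standard construction; including it only shrinks the score).
#' @return A list of class `pingpong_score`: `z10`, `background_mean`,
#'   `background_sd`, `defined`, `reason`.
#' @export
pp_zscore <- function(hist, focal = PP_FOCAL, exclude_focal = TRUE) {
  stopifnot(inherits(hist, "overlap_histogram"))
  counts <- hist$counts
  bg <- if (exclude_focal) counts[-focal] else counts
  m <- mean(bg)
  s <- stats::sd(bg)
  score <- function(z, defined = TRUE, reason = NA_character_) {
    structure(list(z10 = z, background_mean = m, background_sd = s,
                   defined = defined, reason = reason),
              class = "pingpong_score")
  }
  if (all(counts == 0)) {
    return(score(NA_real_, FALSE, "empty histogram"))
  }
  if (s == 0) {
    if (counts[focal] == m) return(score(0))
    return(score(NA_real_, FALSE, "zero-variance background"))
  }
  score((counts[[focal]] - m) / s)
}

#' @export
print.pingpong_score <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("z10 = %.3f (background %.3f +/- %.3f)\n",
                x$z10, x$background_mean, x$background_sd))
  } else {
    cat("z10 undefined:", x$reason, "\n")
  }
  invisible(x)
}

#' Cross-set ping-pong score between two piRNA populations
#'
#' Builds the overlap histogram only from pairs with one member from each
#' set, in either strand arrangement (sense from A with antisense from B,
#' plus sense from B with antisense from A), on a shared reference
#' coordinate system. Used for AT-chX piRNAs versus vasa-mapped piRNAs.
#' The construction is symmetric in its two arguments.
#'
#' @param aln_a,aln_b Alignment data.frames on the same single reference.
#' @param max_overlap Largest overlap distance tabulated (default 30).
#' @return A list with elements `histogram` (`overlap_histogram`) and
#'   `score` (`pingpong_score`).
#' @export
cross_pingpong <- function(aln_a, aln_b, max_overlap = PP_MAX_OVERLAP) {
  refs_a <- unique(aln_a$ref_id)
  refs_b <- unique(aln_b$ref_id)
  if (length(refs_a) > 1L || length(refs_b) > 1L) {
    stop("each set must be restricted to a single reference", call. = FALSE)
  }
  if (length(refs_a) == 1L && length(refs_b) == 1L && refs_a != refs_b) {
    stop("sets are mapped to disjoint references", call. = FALSE)
  }
  cnt <- function(a) if ("count" %in% names(a)) a$count else rep(1, nrow(a))
  wa <- cnt(aln_a); wb <- cnt(aln_b)
  sa <- aln_a$strand == "+"; sb <- aln_b$strand == "+"
  counts <- overlap_counts(aln_a[sa, , drop = FALSE], wa[sa],
                           aln_b[!sb, , drop = FALSE], wb[!sb],
                           max_overlap) +
    overlap_counts(aln_b[sb, , drop = FALSE], wb[sb],
                   aln_a[!sa, , drop = FALSE], wa[!sa], max_overlap)
  n_pirnas <- sum(wa) + sum(wb)
  hist <- structure(list(
    counts = counts,
    n_pairs_total = sum(counts),
    n_pirnas = n_pirnas,
    normalized = if (n_pirnas > 0) counts / n_pirnas else counts
  ), class = "overlap_histogram")
  list(histogram = hist, score = pp_zscore(hist))
}

#' Per-family ping-pong scores from TE-mapped alignments
#'
#' Splits alignments by reference (TE family) and scores each family's
#' overlap histogram.
#'
#' @param alignments Alignment data.frame over one or more TE consensus
#'   references.
#' @return data.frame with columns `family`, `z10`, `defined`,
#'   `n_pairs_total`, `n_pirnas`.
#' @export
te_pingpong_scores <- function(alignments) {
  fams <- unique(alignments$ref_id)
  rows <- lapply(fams, function(f) {
    h <- overlap_histogram(
      alignments[alignments$ref_id == f, , drop = FALSE])
    z <- pp_zscore(h)
    data.frame(family = f, z10 = z$z10, defined = z$defined,
               n_pairs_total = h$n_pairs_total, n_pirnas = h$n_pirnas,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(family = character(0), z10 = numeric(0),
                      defined = logical(0), n_pairs_total = numeric(0),
                      n_pirnas = numeric(0), stringsAsFactors = FALSE)
  }
  out
}
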