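# Desk-scale exact ungapped k-mismatch read mapper. At piRNA read lengths
# (23-29 nt) with at most 3 mismatches, an exhaustive seeded search is
# feasible and fully specified, so no heuristic seed semantics are needed.
# A pigeonhole seed index accelerates the scan but the result is exactly
# the set of placements with Hamming distance <= max_mismatch.
#
# N bases mismatch everything (including N), a conservative policy.

# Cache-free seed index: positions (1-based) of every s-mer of `ref`.
seed_index <- function(ref, s) {
  m <- nchar(ref)
  if (m < s) return(list())
  starts <- seq_len(m - s + 1L)
  kmers <- substring(ref, starts, starts + s - 1L)
  split(starts, kmers)
}

# Hamming distance between read and the ref window starting at `pos`
# (1-based), with N mismatching everything.
window_mismatches <- function(ref_int, read_int, pos) {
  w <- ref_int[pos:(pos + length(read_int) - 1L)]
  sum(w != read_int | w == 78L | read_int == 78L)
}

# Exact-match path (max_mismatch 0): hash every reference window of each
# needed read length and look unique sequences up directly. N never
# matches, so windows or reads containing N are excluded.
exact_hits <- function(useq, rev_useq, references, strands) {
  ulen <- nchar(useq)
  pieces <- list(); np <- 0L
  for (L in sort(unique(ulen))) {
    win <- character(0); win_ref <- character(0); win_pos <- integer(0)
    for (rn in names(references)) {
      m <- nchar(references[[rn]])
      if (m < L) next
      starts <- seq_len(m - L + 1L)
      w <- substring(references[[rn]], starts, starts + L - 1L)
      win <- c(win, w)
      win_ref <- c(win_ref, rep(rn, length(w)))
      win_pos <- c(win_pos, starts)
    }
    if (!length(win)) next
    has_n <- grepl("N", win, fixed = TRUE)
    tab <- split(which(!has_n), win[!has_n])
    sel <- which(ulen == L)
    for (st in strands) {
      q <- if (st == "+") useq[sel] else rev_useq[sel]
      ok <- !grepl("N", q, fixed = TRUE)
      matches <- tab[q[ok]]
      n_hit <- lengths(matches)
      idx <- unlist(matches, use.names = FALSE)
      if (!length(idx)) next
      np <- np + 1L
      pieces[[np]] <- data.frame(
        ui = rep(sel[ok], times = n_hit),
        ref_id = win_ref[idx], start = win_pos[idx] - 1L,
        strand = st, mismatches = 0L, width = L,
        stringsAsFactors = FALSE)
    }
  }
  collect_hits(pieces, np)
}

# Pigeonhole seed-and-verify path for max_mismatch >= 1.
seeded_hits <- function(useq, rev_useq, references, strands, max_mismatch) {
  ref_int <- lapply(references, utf8ToInt)
  ref_len <- nchar(references)
  # k+1 disjoint seeds of length s fit in every read, so any placement
  # with <= k mismatches is found through at least one exact seed.
  lmin <- min(nchar(useq))
  s <- max(1L, lmin %/% (max_mismatch + 1L))
  idx <- lapply(references, seed_index, s = s)
  pieces <- list(); np <- 0L
  for (ui in seq_along(useq)) {
    u <- useq[ui]
    L <- nchar(u)
    offsets <- (0:max_mismatch) * s            # 0-based seed offsets
    offsets <- offsets[offsets + s <= L]
    for (st in strands) {
      q <- if (st == "+") u else rev_useq[ui]
      q_int <- utf8ToInt(q)
      seeds <- substring(q, offsets + 1L, offsets + s)
      for (rn in names(references)) {
        if (ref_len[[rn]] < L) next
        cand <- integer(0)
        for (j in seq_along(seeds)) {
          pos <- idx[[rn]][[seeds[j]]]
          if (!is.null(pos)) cand <- c(cand, pos - offsets[j])
        }
        cand <- unique(cand)
        cand <- cand[cand >= 1L & cand + L - 1L <= ref_len[[rn]]]
        if (!length(cand)) next
        ri <- ref_int[[rn]]
        cand <- sort(cand)
        mm <- vapply(cand, function(p) window_mismatches(ri, q_int, p),
                     numeric(1))
        keep <- mm <= max_mismatch
        if (!any(keep)) next
        np <- np + 1L
        pieces[[np]] <- data.frame(
          ui = ui, ref_id = rn, start = cand[keep] - 1L, strand = st,
          mismatches = as.integer(mm[keep]), width = L,
          stringsAsFactors = FALSE)
      }
    }
  }
  collect_hits(pieces, np)
}

collect_hits <- function(pieces, np) {
  if (np == 0L) {
    return(data.frame(ui = integer(0), ref_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), width = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, pieces[seq_len(np)])
}

#' Map reads to references by exact ungapped k-mismatch search
#'
#' Finds, for every read, all placements on the references (and their
#' reverse strand when `both_strands`) whose Hamming distance is at most
#' `max_mismatch`, then applies one of three reporting policies:
#'
#' * `all_hits`: every qualifying placement is returned.
#' * `one_best`: a single minimum-mismatch placement per read, with the
#'   deterministic tie-break (ref id lexicographic, then start, then `+`
#'   before `-`). Mirrors a "report one alignment" mapper run.
#' * `best_unique`: reads whose minimum-mismatch placement is not unique
#'   are discarded entirely. With `max_mismatch = 0` on a merged
#'   two-genome reference this is the species-specificity device: any read
#'   occurring in both genomes is dropped.
#'
#' A `-` strand record means the reverse complement of the read matches
#' the reference window; its 5' end is at `start + width - 1`.
#'
#' @param reads Named character vector of read sequences, a data.frame
#'   with columns `id` and `seq`, or a `read_library`.
#' @param references Named character vector of reference sequences.
#' @param max_mismatch Maximum Hamming distance (default 0).
#' @param policy One of `"all_hits"`, `"one_best"`, `"best_unique"`.
#' @param both_strands Search the reverse strand too (default TRUE).
#' @return data.frame with columns `read_id`, `ref_id`, `start` (0-based),
#'   `strand`, `mismatches`, `width`.
#' @export
map_reads <- function(reads, references,
                      max_mismatch = 0L,
                      policy = c("all_hits", "one_best", "best_unique"),
                      both_strands = TRUE) {
  policy <- match.arg(policy)
  max_mismatch <- check_count(max_mismatch, "max_mismatch")
  if (inherits(reads, "read_library")) reads <- reads$reads
  if (is.data.frame(reads)) {
    ids <- reads$id; seqs <- toupper(reads$seq)
  } else {
    if (is.null(names(reads))) {
      names(reads) <- paste0("read_", seq_along(reads))
    }
    ids <- names(reads); seqs <- toupper(unname(reads))
  }
  if (length(references) == 0L) {
    stop("empty reference set", call. = FALSE)
  }
  if (is.null(names(references))) stop("references must be named",
                                       call. = FALSE)
  references <- toupper(references)

  empty <- data.frame(read_id = character(0), ref_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), width = integer(0),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(empty)

  # Map unique sequences once; expand to read ids afterwards.
  useq <- unique(seqs)
  strands <- if (both_strands) c("+", "-") else "+"
  rev_useq <- if (both_strands) revcomp(useq) else NULL

  hits_u <- if (max_mismatch == 0L) {
    exact_hits(useq, rev_useq, references, strands)
  } else {
    seeded_hits(useq, rev_useq, references, strands, max_mismatch)
  }
  if (nrow(hits_u) == 0L) return(empty)

  # Expand unique-sequence hits to every read carrying that sequence:
  # hit row for useq u is replicated once per read with that sequence.
  grp <- split(seq_along(ids), factor(seqs, levels = useq))
  n_ids <- lengths(grp)
  reps <- n_ids[hits_u$ui]
  out <- hits_u[rep(seq_len(nrow(hits_u)), times = reps), , drop = FALSE]
  out$read_id <- ids[unlist(grp[hits_u$ui], use.names = FALSE)]
  out <- out[, c("read_id", "ref_id", "start", "strand", "mismatches",
                 "width")]
  rownames(out) <- NULL

  if (policy == "all_hits") return(out)

  # Deterministic order: read, mismatches, ref id, start, '+' first.
  ord <- order(out$read_id, out$mismatches, out$ref_id, out$start,
               match(out$strand, c("+", "-")))
  out <- out[ord, , drop = FALSE]
  if (policy == "one_best") {
    out <- out[!duplicated(out$read_id), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  # best_unique: drop reads whose minimum-mismatch placement is tied.
  first <- out[!duplicated(out$read_id), , drop = FALSE]
  min_mm <- stats::setNames(first$mismatches, first$read_id)
  at_min <- out$mismatches == min_mm[out$read_id]
  n_min <- table(out$read_id[at_min])
  keep <- first$read_id %in% names(n_min)[n_min == 1L]
  out <- first[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Orient a TE-mapped read as sense or antisense
#'
#' Transposon consensus sequences are stored in sense orientation, so a
#' `+` alignment is a sense read and a `-` alignment an antisense read.
#'
#' @param strand Character vector of `"+"`/`"-"` alignment strands.
#' @return Character vector of `"sense"`/`"antisense"`.
#' @export
strand_of_te_read <- function(strand) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'",
                                          call. = FALSE)
  ifelse(strand == "+", "sense", "antisense")
}
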