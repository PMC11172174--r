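# Small-RNA read-processing cascade with explicit per-stage depth
# bookkeeping. rpm normalization uses the library depth recorded *before*
# miRNA filtration (i.e. after rRNA/snRNA/snoRNA/tRNA removal), which is
# what published rpm tables in this analysis are normalized to.

STAGE_ORDER <- c("raw", "adapter_trimmed", "quality_kept",
                 "contaminant_filtered", "mirna_filtered",
                 "length_selected")

#' Construct a small-RNA read library
#'
#' @param ids Character vector of read ids (unique).
#' @param seqs Character vector of read sequences (same length as `ids`).
#' @param qualities Optional numeric vector of mean base qualities per read
#'   (used by [filter_quality()] for FASTQ input).
#' @return An object of class `read_library`: reads plus an ordered map of
#'   per-stage depths and the normalization depth.
#' @export
read_library <- function(ids, seqs, qualities = NULL) {
  stopifnot(length(ids) == length(seqs))
  if (anyDuplicated(ids)) stop("duplicate read ids", call. = FALSE)
  if (!is.null(qualities)) stopifnot(length(qualities) == length(ids))
  structure(list(
    reads = data.frame(id = as.character(ids), seq = toupper(as.character(seqs)),
                       stringsAsFactors = FALSE),
    qualities = qualities,
    stage_depths = c(raw = length(ids)),
    normalization_depth = NA_integer_
  ), class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat("read_library with", nrow(x$reads), "reads\n")
  cat("stage depths:\n")
  for (s in names(x$stage_depths)) {
    cat(sprintf("  %-22s %d\n", s, x$stage_depths[[s]]))
  }
  cat("normalization depth:", x$normalization_depth, "\n")
  invisible(x)
}

# Record a stage depth, enforcing stage order and monotone non-increase.
record_stage <- function(lib, stage, n) {
  stopifnot(stage %in% STAGE_ORDER)
  prev <- names(lib$stage_depths)
  if (length(prev)) {
    last <- match(prev[length(prev)], STAGE_ORDER)
    if (match(stage, STAGE_ORDER) <= last) {
      stop("stage '", stage, "' recorded out of order", call. = FALSE)
    }
    if (n > lib$stage_depths[[length(lib$stage_depths)]]) {
      stop("stage depths must be non-increasing", call. = FALSE)
    }
  }
  lib$stage_depths[stage] <- n
  lib
}

keep_reads <- function(lib, keep) {
  lib$reads <- lib$reads[keep, , drop = FALSE]
  rownames(lib$reads) <- NULL
  if (!is.null(lib$qualities)) lib$qualities <- lib$qualities[keep]
  lib
}

#' Trim a 3' adapter from reads
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter, requiring at least `min_overlap` matching bases. Reads trimmed
#' to length zero are dropped. Matching is exact (synthetic libraries are
#' generated error-free); no error tolerance is applied.
#'
#' @param lib A `read_library`.
#' @param adapter Adapter sequence (non-empty DNA string).
#' @param min_overlap Minimum suffix/prefix overlap to trim (default 3).
#' @return The library with trimmed reads and stage `adapter_trimmed`
#'   recorded.
#' @export
trim_adapter <- function(lib, adapter, min_overlap = 3L) {
  stopifnot(inherits(lib, "read_library"))
  if (!is.character(adapter) || length(adapter) != 1L || !nzchar(adapter)) {
    stop("`adapter` must be a non-empty string", call. = FALSE)
  }
  adapter <- toupper(adapter)
  seqs <- lib$reads$seq
  len <- nchar(seqs)
  trim_at <- rep(NA_integer_, length(seqs))  # first trimmed position
  max_o <- min(max(len), nchar(adapter))
  for (o in seq(max_o, min_overlap)) {       # longest overlap wins
    cand <- which(is.na(trim_at) & len >= o)
    if (!length(cand)) next
    hit <- substr(seqs[cand], len[cand] - o + 1L, len[cand]) ==
      substr(adapter, 1L, o)
    trim_at[cand[hit]] <- len[cand[hit]] - o
  }
  new_len <- ifelse(is.na(trim_at), len, trim_at)
  lib$reads$seq <- substr(seqs, 1L, new_len)
  lib <- keep_reads(lib, new_len > 0L)
  record_stage(lib, "adapter_trimmed", nrow(lib$reads))
}

#' Drop low-quality reads (FASTQ input)
#'
#' Reads with mean base quality <= `min_mean_quality` are removed. For
#' FASTA input (no qualities), all reads are kept and the stage depth is
#' still recorded.
#'
#' @param lib A `read_library`.
#' @param min_mean_quality Phred threshold; reads at or below it are
#'   dropped (default 30).
#' @return The library with stage `quality_kept` recorded.
#' @export
filter_quality <- function(lib, min_mean_quality = 30) {
  stopifnot(inherits(lib, "read_library"))
  if (!is.null(lib$qualities)) {
    lib <- keep_reads(lib, lib$qualities > min_mean_quality)
  }
  record_stage(lib, "quality_kept", nrow(lib$reads))
}

# Shared engine for the two reference-based filters: drop reads that align
# anywhere in `refs` (either strand, ungapped, <= max_mismatch).
filter_against <- function(lib, refs, max_mismatch, stage) {
  if (length(refs) == 0L) {
    warning("empty reference set for stage '", stage,
            "': passing all reads through")
    lib <- record_stage(lib, stage, nrow(lib$reads))
    if (stage == "contaminant_filtered") {
      lib$normalization_depth <- nrow(lib$reads)
    }
    return(lib)
  }
  hits <- map_reads(lib$reads, refs, max_mismatch = max_mismatch,
                    policy = "one_best")
  lib <- keep_reads(lib, !(lib$reads$id %in% hits$read_id))
  lib <- record_stage(lib, stage, nrow(lib$reads))
  if (stage == "contaminant_filtered") {
    lib$normalization_depth <- nrow(lib$reads)
  }
  lib
}

#' Remove reads matching structural-RNA contaminants
#'
#' Reads aligning anywhere in the contaminant references (rRNA, snRNA,
#' snoRNA, tRNA), on either strand, ungapped with at most `max_mismatch`
#' mismatches, are removed. The surviving depth is recorded at stage
#' `contaminant_filtered` and becomes the library's normalization depth
#' (the depth "before miRNA filtration").
#'
#' @param lib A `read_library`.
#' @param contaminant_refs Named character vector of contaminant sequences.
#' @param max_mismatch Mismatch tolerance (default 3).
#' @return The filtered library.
#' @export
filter_contaminants <- function(lib, contaminant_refs, max_mismatch = 3L) {
  stopifnot(inherits(lib, "read_library"))
  filter_against(lib, contaminant_refs, max_mismatch, "contaminant_filtered")
}

#' Remove microRNA-matching reads
#'
#' Same matching rule as [filter_contaminants()], recorded at stage
#' `mirna_filtered`. The normalization depth is deliberately NOT updated by
#' this step: rpm values are normalized to the depth before miRNA
#' filtration.
#'
#' @inheritParams filter_contaminants
#' @param mirna_refs Named character vector of mature miRNA sequences.
#' @return The filtered library.
#' @export
filter_mirna <- function(lib, mirna_refs, max_mismatch = 3L) {
  stopifnot(inherits(lib, "read_library"))
  if (is.na(lib$normalization_depth)) {
    # miRNA filtration without a preceding contaminant stage: pin the
    # denominator to the current depth so rpm stays defined.
    lib$normalization_depth <- nrow(lib$reads)
  }
  nd <- lib$normalization_depth
  lib <- filter_against(lib, mirna_refs, max_mismatch, "mirna_filtered")
  lib$normalization_depth <- nd
  lib
}

#' Select reads by length
#'
#' Retains reads with `min_nt <= length <= max_nt` (both bounds inclusive;
#' the piRNA fraction is conventionally 23-29 nt).
#'
#' @param lib A `read_library`.
#' @param min_nt,max_nt Inclusive length bounds (defaults 23 and 29).
#' @return The filtered library with stage `length_selected` recorded.
#' @export
select_length <- function(lib, min_nt = 23L, max_nt = 29L) {
  stopifnot(inherits(lib, "read_library"))
  if (min_nt > max_nt) stop("min_nt > max_nt", call. = FALSE)
  len <- nchar(lib$reads$seq)
  lib <- keep_reads(lib, len >= min_nt & len <= max_nt)
  record_stage(lib, "length_selected", nrow(lib$reads))
}

#' Reads-per-million normalization
#'
#' Converts a raw count into reads per million of the library's
#' normalization depth (the depth before miRNA filtration).
#'
#' @param count Non-negative count (vectorised).
#' @param lib A `read_library` with a defined normalization depth, or a
#'   single positive number giving the depth directly.
#' @return `count / depth * 1e6`.
#' @export
rpm <- function(count, lib) {
  if (any(count < 0)) stop("negative count", call. = FALSE)
  depth <- if (inherits(lib, "read_library")) lib$normalization_depth else lib
  if (is.null(depth) || length(depth) != 1L || is.na(depth) || depth <= 0) {
    stop("normalization depth is undefined or zero", call. = FALSE)
  }
  count / depth * 1e6
}

#' Write a JSON stage-depth report
#'
#' Serialises the library's per-stage depths and normalization depth,
#' the provenance record needed to interpret rpm values.
#'
#' @param lib A `read_library`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_stage_report <- function(lib, path) {
  stopifnot(inherits(lib, "read_library"))
  jsonlite::write_json(
    list(stage_depths = as.list(lib$stage_depths),
         normalization_depth = lib$normalization_depth,
         n_reads = nrow(lib$reads)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Run the full small-RNA processing cascade
#'
#' Adapter trimming (optional), quality filtering, contaminant filtering,
#' miRNA filtering and length selection, in that order, with stage depths
#' recorded throughout.
#'
#' @param lib A `read_library`.
#' @param adapter Optional 3' adapter to trim.
#' @param contaminant_refs,mirna_refs Named character vectors of filter
#'   references.
#' @param min_nt,max_nt Length-selection bounds (defaults 23, 29).
#' @param max_mismatch Mismatch tolerance for the filters (default 3).
#' @return The processed `read_library`.
#' @export
process_small_rna <- function(lib, adapter = NULL,
                              contaminant_refs = character(0),
                              mirna_refs = character(0),
                              min_nt = 23L, max_nt = 29L,
                              max_mismatch = 3L) {
  if (!is.null(adapter)) lib <- trim_adapter(lib, adapter)
  lib <- filter_quality(lib)
  lib <- suppressWarnings(
    filter_contaminants(lib, contaminant_refs, max_mismatch))
  lib <- suppressWarnings(filter_mirna(lib, mirna_refs, max_mismatch))
  select_length(lib, min_nt, max_nt)
}
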