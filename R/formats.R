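# Readers and writers for the plain-text formats the pipeline touches.
# Internal coordinates are 0-based half-open everywhere; SAM (1-based) and
# blast tabular (1-based inclusive) are converted at this boundary.

#' Read a DNA FASTA file with strict validation
#'
#' Sequences are uppercased and must use the alphabet A, C, G, T, N.
#' Duplicate record ids are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids, the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-DNA characters in records: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) stop("duplicate ids", call. = FALSE)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read piRNA-cluster intervals from a BED3+ file
#'
#' Coordinates are kept 0-based half-open as in BED. A fourth column, when
#' present, supplies the interval name; otherwise names `interval_<k>` are
#' assigned. A fifth column (when present) is interpreted as the cluster
#' type (`uni`, `dual` or `unknown`).
#'
#' @param path Path to a tab-separated BED file (>= 3 columns).
#' @param genome_label Species/assembly tag attached to every interval.
#' @return data.frame with columns `genome_label`, `chrom`, `start`, `end`,
#'   `name`, `cluster_type`.
#' @export
read_bed <- function(path, genome_label) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(genome_label = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      name = character(0), cluster_type = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop("BED line ", which(n < 3L)[1L], " has fewer than 3 columns",
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- as.integer(vapply(fields, `[[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[[`, character(1), 3L))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("non-numeric BED coordinates", call. = FALSE)
  }
  if (any(start < 0L) || any(start >= end)) {
    stop("BED line ", which(start < 0L | start >= end)[1L],
         ": require 0 <= start < end", call. = FALSE)
  }
  name <- ifelse(n >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else "", character(1)),
    paste0("interval_", seq_along(fields)))
  if (anyDuplicated(name)) {
    stop("duplicate interval names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "),
         call. = FALSE)
  }
  ctype <- vapply(fields, function(f)
    if (length(f) >= 5L) f[[5L]] else "unknown", character(1))
  if (!all(ctype %in% c("uni", "dual", "unknown"))) {
    stop("cluster_type must be one of uni, dual, unknown", call. = FALSE)
  }
  data.frame(genome_label = genome_label, chrom = chrom, start = start,
             end = end, name = name, cluster_type = ctype,
             stringsAsFactors = FALSE)
}

#' Read 12-column tabular homology-search hits
#'
#' The standard blast tabular dialect (`-outfmt 6`): qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore. Coordinates are 1-based inclusive as in the format and are
#' preserved as such (these fields are not used for interval arithmetic).
#'
#' @param path Path to a tab-separated hits file.
#' @return data.frame with the 12 canonical columns, numeric where
#'   appropriate; row order preserved.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad)) {
    stop("line ", bad[1L], ": expected 12 tab-separated columns, found ",
         lengths(fields)[bad[1L]], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                    stringsAsFactors = FALSE)
  num <- c(3:11, 12)
  for (i in num) out[[cols[i]]] <- as.numeric(m[, i])
  if (anyNA(out$bitscore) || any(out$bitscore < 0)) {
    stop("invalid bitscore field", call. = FALSE)
  }
  out
}

#' Read a minimal SAM dialect into alignment records
#'
#' Only the fields the pipeline consumes are modelled: QNAME, FLAG strand
#' bit (16), RNAME, POS (converted to 0-based start), SEQ length, and the
#' `NM:i:` mismatch tag. Records with a CIGAR other than a single match run
#' are rejected (the internal mapper is ungapped). A missing NM tag yields
#' `NA` mismatches with `nm_known = FALSE`.
#'
#' @param path Path to a SAM file (header optional).
#' @return data.frame with columns `read_id`, `ref_id`, `start` (0-based),
#'   `strand`, `mismatches`, `width`, `nm_known`.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  empty <- data.frame(read_id = character(0), ref_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), width = integer(0),
                      nm_known = logical(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L)) {
    stop("SAM line ", which(lengths(fields) < 11L)[1L],
         " has fewer than 11 fields", call. = FALSE)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(get(2L))
  cigar <- get(6L)
  seq <- get(10L)
  width <- nchar(seq)
  ok_cigar <- cigar == "*" | cigar == paste0(width, "M")
  if (!all(ok_cigar)) {
    stop("unsupported CIGAR at line ", which(!ok_cigar)[1L],
         " (only a single match run is modelled)", call. = FALSE)
  }
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1L])) else NA_integer_
  }, integer(1))
  data.frame(read_id = get(1L), ref_id = get(3L),
             start = as.integer(get(4L)) - 1L,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mismatches = nm, width = width,
             nm_known = !is.na(nm), stringsAsFactors = FALSE)
}

#' Write alignment records as a minimal SAM file
#'
#' @param alignments data.frame as produced by [map_reads()] or
#'   [read_alignments()]; a `seq` column, when present, is written as SEQ.
#' @param path Output path.
#' @param references Optional named character vector of reference sequences
#'   used to emit `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path, references = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unknown"
  if (!is.null(references)) {
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(references),
                          nchar(references)))
  }
  seq <- if ("seq" %in% names(alignments)) alignments$seq else
    strrep("N", alignments$width)
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                  alignments$read_id,
                  ifelse(alignments$strand == "-", 16L, 0L),
                  alignments$ref_id, alignments$start + 1L,
                  alignments$width, seq, alignments$mismatches)
  writeLines(c(hdr, body), path)
  invisible(path)
}
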