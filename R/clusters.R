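# piRNA-cluster activity via unique zero-mismatch mapping to a merged
# two-genome reference. Repetitive piRNA clusters cannot be attributed to
# a species by multi-mapping reads, so only reads with a single exact
# placement across BOTH genomes count toward cluster activity.

#' Quantify piRNA-cluster activity on a merged two-genome reference
#'
#' Reads are mapped with the best-unique policy at zero mismatches to the
#' merged reference set (both genomes; reference names must be unique
#' across genomes, e.g. prefixed with a species tag). A surviving read is
#' assigned to an interval when its 5' end lies in `[start, end)`; strand
#' is relative to the `+` strand of the interval's chromosome.
#'
#' @param reads Named character vector or `read_library` of processed
#'   piRNA reads.
#' @param references Named character vector: the merged genome segments.
#' @param intervals data.frame of cluster intervals from [read_bed()].
#' @param lib A `read_library` (or single number) supplying the
#'   normalization depth for [rpm()].
#' @param assignment `"five_prime"` (default) counts a read whose 5' end
#'   falls in the interval; `"full"` requires the whole read inside it.
#' @return data.frame, one row per interval: counts and rpm split by
#'   strand plus totals.
#' @export
cluster_activity <- function(reads, references, intervals, lib,
                             assignment = c("five_prime", "full")) {
  assignment <- match.arg(assignment)
  missing_chr <- setdiff(unique(intervals$chrom), names(references))
  if (length(missing_chr)) {
    stop("interval chromosomes missing from the merged reference: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  aln <- map_reads(reads, references, max_mismatch = 0L,
                   policy = "best_unique")
  five <- ifelse(aln$strand == "+", aln$start, aln$start + aln$width - 1L)
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    on_chr <- aln$ref_id == iv$chrom
    inside <- if (assignment == "five_prime") {
      five >= iv$start & five < iv$end
    } else {
      aln$start >= iv$start & (aln$start + aln$width) <= iv$end
    }
    sel <- on_chr & inside
    sense <- sum(sel & aln$strand == "+")
    anti <- sum(sel & aln$strand == "-")
    data.frame(name = iv$name, genome_label = iv$genome_label,
               chrom = iv$chrom, cluster_type = iv$cluster_type,
               n_reads = sense + anti, sense_count = sense,
               antisense_count = anti,
               unique_pirna_rpm = rpm(sense + anti, lib),
               sense_rpm = rpm(sense, lib), antisense_rpm = rpm(anti, lib),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hybrid-to-parent relative cluster activity
#'
#' Per interval, the ratio of hybrid to parental unique piRNA rpm. For a
#' cluster inherited as a single copy in the hybrid, the expected relative
#' level is 0.5 (the half-dose reference line).
#'
#' @param hybrid_activity,parent_activity Activity tables from
#'   [cluster_activity()] for the two genotypes (matched by `name`).
#' @return data.frame with columns `name`, `cluster_type`, `hybrid_rpm`,
#'   `parent_rpm`, `ratio` (`NA`, flagged by warning, where the parent rpm
#'   is zero), and the constant `expected_level` column (0.5).
#' @export
relative_activity <- function(hybrid_activity, parent_activity) {
  m <- match(hybrid_activity$name, parent_activity$name)
  if (anyNA(m)) stop("interval sets differ between genotypes",
                     call. = FALSE)
  parent_rpm <- parent_activity$unique_pirna_rpm[m]
  ratio <- ifelse(parent_rpm > 0,
                  hybrid_activity$unique_pirna_rpm / parent_rpm, NA_real_)
  if (anyNA(ratio)) warning("ratio undefined where parent rpm is 0")
  data.frame(name = hybrid_activity$name,
             cluster_type = hybrid_activity$cluster_type,
             hybrid_rpm = hybrid_activity$unique_pirna_rpm,
             parent_rpm = parent_rpm, ratio = ratio,
             expected_level = 0.5, stringsAsFactors = FALSE)
}
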