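test_that("adapter trimming removes the longest suffix-prefix match", {
  lib <- read_library(c("r1", "r2"),
                      c("ACGTACGTAGATCGGAAG", "ACGTACGTACGTACGTAC"))
  out <- trim_adapter(lib, "AGATCGGAAG", min_overlap = 3)
  expect_equal(out$reads$seq, c("ACGTACGT", "ACGTACGTACGTACGTAC"))
  expect_equal(out$stage_depths[["adapter_trimmed"]], 2L)

  # read that is pure adapter is dropped
  lib2 <- read_library("r1", "AGATCGGAAG")
  out2 <- trim_adapter(lib2, "AGATCGGAAG")
  expect_equal(nrow(out2$reads), 0L)

  # 500 random reads with planted adapters match the brute-force scan
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  reads <- withr::with_seed(42, {
    body <- random_reads(500, 30, seed = 5)
    n_ad <- sample(0:15, 500, replace = TRUE)
    stats::setNames(paste0(body, substring(adapter, 1, n_ad)), names(body))
  })
  lib3 <- read_library(names(reads), reads)
  got <- trim_adapter(lib3, adapter, min_overlap = 3)
  want <- vapply(reads, oracle_trim, character(1), adapter = adapter,
                 min_overlap = 3)
  want <- want[nchar(want) > 0]
  expect_equal(stats::setNames(got$reads$seq, got$reads$id), want)
})

test_that("contaminant and miRNA filters match brute force and pin the
           normalization depth before miRNA filtration", {
  contams <- synthetic_contaminants(seed = 7, n = 2, length = 400)
  mirnas <- synthetic_mirnas(seed = 8, n = 5)
  reads <- c(
    random_reads(50, 25, seed = 8),                       # clean
    planted_reads(contams[[1]], 10, 25, seed = 9),        # rRNA-like
    stats::setNames(unname(mirnas[1:5]), paste0("m", 1:5))  # miRNA
  )
  lib <- read_library(names(reads), reads)
  lib <- filter_contaminants(lib, contams, max_mismatch = 3)
  expect_equal(lib$stage_depths[["contaminant_filtered"]], 55L)
  expect_equal(lib$normalization_depth, 55L)

  lib <- filter_mirna(lib, mirnas, max_mismatch = 3)
  expect_equal(lib$stage_depths[["mirna_filtered"]], 50L)
  expect_equal(lib$normalization_depth, 55L)   # unchanged by miRNA step

  # survivor set equals the brute-force window scan
  surv <- lib$reads$id
  all_refs <- c(contams, mirnas)
  oracle_surv <- names(reads)[vapply(names(reads), function(id) {
    nrow(oracle_map(reads[id], all_refs, 3)) == 0L
  }, logical(1))]
  expect_setequal(surv, oracle_surv)

  # boundary: read at Hamming distance 4 from every window is retained
  base <- substr(contams[[1]], 1, 25)
  far <- paste0(chartr("ACGT", "GTAC", substr(base, 1, 4)),
                substr(base, 5, 25))
  lib4 <- read_library("far", far)
  lib4 <- filter_contaminants(lib4, contams, max_mismatch = 3)
  expect_equal(nrow(lib4$reads),
               as.integer(nrow(oracle_map(c(far = far), contams, 3)) == 0L))
})

test_that("length selection is inclusive at 23 and 29 nt", {
  seqs <- strrep("A", c(22, 23, 29, 30))
  lib <- read_library(paste0("r", 1:4), seqs)
  out <- select_length(lib)
  expect_equal(nchar(out$reads$seq), c(23L, 29L))
  expect_error(select_length(lib, 30, 20), "min_nt")
  empty <- select_length(read_library(character(0), character(0)))
  expect_equal(nrow(empty$reads), 0L)
})

test_that("rpm normalizes to the pre-miRNA depth and is linear", {
  expect_equal(rpm(50, 1e6), 50)
  expect_equal(rpm(0, 1e6), 0)
  expect_equal(round(rpm(1112, 999730), 1), 1112.3)
  expect_equal(rpm(c(1, 2, 4), 2e6), c(0.5, 1, 2))
  expect_error(rpm(5, 0), "depth")
  lib <- read_library("a", "ACGTACGTACGTACGTACGTACG")
  expect_error(rpm(1, lib), "depth")   # not yet normalized
})

test_that("stage depths are monotone and an all-miRNA library keeps its
           normalization depth", {
  mirnas <- synthetic_mirnas(seed = 3, n = 4)
  reads <- stats::setNames(unname(mirnas[c(1, 2, 3, 4)]), paste0("r", 1:4))
  lib <- read_library(names(reads), reads)
  lib <- filter_contaminants(lib, synthetic_contaminants(seed = 4), 3)
  lib <- filter_mirna(lib, mirnas, 3)
  expect_equal(nrow(lib$reads), 0L)
  expect_equal(lib$normalization_depth, 4L)
  expect_true(all(diff(lib$stage_depths) <= 0))
})

test_that("the full cascade records every stage in order", {
  panel <- fixture_panel(3, 600, 2)
  sc <- pirna_scenario(panel, library_size = 2000,
                       contaminant_fraction = 0.2, seed = 5)
  sim <- simulate_small_rna_library(sc)
  lib <- process_small_rna(sim$lib,
                           contaminant_refs = sc$contaminant_refs,
                           mirna_refs = sc$mirna_refs)
  expect_equal(names(lib$stage_depths),
               c("raw", "quality_kept", "contaminant_filtered",
                 "mirna_filtered", "length_selected"))
  expect_true(all(diff(lib$stage_depths) <= 0))
  # JSON report round-trips the depth bookkeeping
  report <- withr::local_tempfile(fileext = ".json")
  write_stage_report(lib, report)
  back <- jsonlite::read_json(report)
  expect_equal(back$normalization_depth, lib$normalization_depth)
  expect_equal(unlist(back$stage_depths),
               c(lib$stage_depths))
  # every surviving read is TE-derived ground truth
  origins <- sim$truth$origin[match(lib$reads$id, sim$truth$read_id)]
  expect_false(any(origins %in% c("rRNA", "miRNA")))
})
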