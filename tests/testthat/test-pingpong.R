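aln_row <- function(id, start, strand, width, ref = "TE") {
  data.frame(read_id = id, ref_id = ref, start = start, strand = strand,
             mismatches = 0L, width = width, stringsAsFactors = FALSE)
}

test_that("overlap arithmetic: a 10-nt 5'-overlap pair lands in bin 10", {
  # sense 5' at 100; antisense spanning [91,115] has its 5' at 115... the
  # antisense 5' is the highest coordinate: start 91, width 25 -> 5' 115.
  # For bin 10 the antisense 5' must sit at 109: start 85, width 25.
  aln <- rbind(aln_row("s", 100L, "+", 25L),
               aln_row("a", 85L, "-", 25L))
  h <- overlap_histogram(aln)
  expect_equal(unname(h$counts[10]), 1)
  expect_equal(sum(h$counts), h$n_pairs_total)
  expect_equal(h$n_pairs_total, 1)
  expect_equal(unname(h$normalized[10]), 0.5)  # 2 piRNAs on the reference

  # o = q - p + 1 for every bin
  for (o in c(1L, 15L, 30L)) {
    aln2 <- rbind(aln_row("s", 100L, "+", 25L),
                  aln_row("a", 100L + o - 1L - 24L, "-", 25L))
    h2 <- overlap_histogram(aln2)
    expect_equal(unname(h2$counts[o]), 1, info = paste("o =", o))
  }
})

test_that("abundance weighting multiplies pair counts", {
  aln <- rbind(aln_row("s", 100L, "+", 25L), aln_row("a", 85L, "-", 25L))
  aln$count <- c(3, 4)
  h <- overlap_histogram(aln)
  expect_equal(unname(h$counts[10]), 12)
})

test_that("histogram requires a single reference and empty sets give
           all-zero histograms", {
  aln <- rbind(aln_row("s", 10L, "+", 25L, "A"),
               aln_row("a", 20L, "-", 25L, "B"))
  expect_error(overlap_histogram(aln), "one reference")
  h <- overlap_histogram(aln_row("s", 10L, "+", 25L))
  expect_true(all(h$counts == 0))
})

test_that("z10 handles flat, degenerate and empty histograms", {
  mkhist <- function(counts) {
    structure(list(counts = stats::setNames(counts, 1:30),
                   n_pairs_total = sum(counts), n_pirnas = 100,
                   normalized = counts / 100),
              class = "overlap_histogram")
  }
  flat <- pp_zscore(mkhist(rep(5, 30)))
  expect_true(flat$defined)
  expect_equal(flat$z10, 0)

  spike <- pp_zscore(mkhist(c(rep(0, 9), 100, rep(0, 20))))
  expect_false(spike$defined)

  empty <- pp_zscore(mkhist(rep(0, 30)))
  expect_false(empty$defined)

  # oracle recomputation over random Poisson histograms
  withr::with_seed(77, {
    for (i in 1:50) {
      counts <- rpois(30, 5); counts[10] <- 50
      z <- pp_zscore(mkhist(counts))
      expect_equal(z$z10, oracle_z10(counts))
    }
  })
})

test_that("planted ping-pong signal dominates bin 10 and null libraries
           score near zero", {
  panel <- fixture_panel(1, 600, 4)
  refs <- panel_refs(panel)
  sc <- pirna_scenario(panel, library_size = 20000,
                       pingpong_fraction = 0.8, seed = 11)
  sim <- simulate_small_rna_library(sc)
  aln <- map_reads(sim$lib, refs, 0, "one_best")
  h <- overlap_histogram(aln)
  expect_true(h$counts[10] > max(h$counts[-10]))
  z <- pp_zscore(h)
  expect_gt(z$z10, 3)
})

test_that("cross-set ping-pong is symmetric and finds planted pairs
           split across sets", {
  panel <- fixture_panel(1, 600, 4)
  refs <- panel_refs(panel)
  sc <- pirna_scenario(panel, library_size = 10000,
                       pingpong_fraction = 0.9, seed = 13)
  sim <- simulate_small_rna_library(sc)
  aln <- map_reads(sim$lib, refs, 0, "one_best")
  a <- aln[aln$strand == "+", ]
  b <- aln[aln$strand == "-", ]
  ab <- cross_pingpong(a, b)
  ba <- cross_pingpong(b, a)
  expect_equal(ab$histogram$counts, ba$histogram$counts)
  expect_equal(ab$score$z10, ba$score$z10)
  expect_gt(ab$score$z10, 3)

  # empty second set: all-zero histogram, undefined score
  none <- cross_pingpong(a, a[0, ])
  expect_true(all(none$histogram$counts == 0))
  expect_false(none$score$defined)

  # disjoint references error
  b2 <- b; b2$ref_id <- "other"
  expect_error(cross_pingpong(a, b2), "disjoint")
})
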