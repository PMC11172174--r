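test_that("species pairs honour the divergence model and are
           reproducible", {
  # zero divergence: identical sequences
  p0 <- generate_species_pair(10, 500, 0.0, seed = 1)
  expect_identical(p0$genes$seq_mel, p0$genes$seq_sim)

  # pooled mismatch fraction within 3 binomial SDs of the target
  p <- generate_species_pair(100, 1000, 0.05, seed = 7)
  mm <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, p$genes$seq_mel, p$genes$seq_sim))
  frac <- mm / 1e5
  sigma <- sqrt(0.05 * 0.95 / 1e5)
  expect_lte(abs(frac - 0.05), 3 * sigma)

  # same seed -> byte-identical FASTA output
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a_mel.fa"); f2 <- file.path(d, "a_sim.fa")
  g1 <- file.path(d, "b_mel.fa"); g2 <- file.path(d, "b_sim.fa")
  write_species_pair(generate_species_pair(20, 300, 0.05, seed = 7),
                     f1, f2)
  write_species_pair(generate_species_pair(20, 300, 0.05, seed = 7),
                     g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))

  expect_error(generate_species_pair(10, 100, 0.3, seed = 1),
               "divergence")
  expect_error(generate_species_pair(0, 100, 0.1, seed = 1), "n_genes")
})

test_that("small-RNA libraries conserve read counts exactly and keep
           faithful ground truth", {
  panel <- fixture_panel(3, 600, 2)
  sc <- pirna_scenario(panel, library_size = 5000,
                       pingpong_fraction = 0.5,
                       sense_antisense_ratio = 2,
                       contaminant_fraction = 0.15, seed = 61)
  sim <- simulate_small_rna_library(sc)
  expect_equal(nrow(sim$lib$reads), 5000L)           # exact conservation
  expect_equal(nrow(sim$truth), 5000L)
  expect_true(all(nchar(sim$lib$reads$seq) >= 23 &
                    nchar(sim$lib$reads$seq) <= 29 |
                    sim$truth$origin == "miRNA"))

  # determinism
  sim2 <- simulate_small_rna_library(sc)
  expect_identical(sim$lib$reads, sim2$lib$reads)
  expect_identical(sim$truth, sim2$truth)

  # sense:antisense ratio per family near the planted value
  te <- sim$truth[!(sim$truth$origin %in% c("rRNA", "miRNA")), ]
  frac_sense <- mean(te$strand == "+")
  expect_lte(abs(frac_sense - 2 / 3), 3 * sqrt(2 / 9 / nrow(te)) + 0.01)

  # planted pairs: mate's 5' ends overlap by exactly 10 nt when mapped
  aln <- map_reads(sim$lib, panel_refs(panel), 0, "one_best")
  pp <- sim$truth[!is.na(sim$truth$pingpong_mate), ][1:50, ]
  a5 <- function(id) {
    r <- aln[aln$read_id == id, ][1, ]
    if (r$strand == "+") r$start else r$start + r$width - 1L
  }
  o <- vapply(seq_len(nrow(pp)), function(i) {
    a5(pp$read_id[i]) - a5(pp$pingpong_mate[i]) + 1L
  }, numeric(1))
  expect_true(all(o == 10))

  # all-contaminant scenario: nothing survives the filters
  sc_c <- pirna_scenario(panel, library_size = 400,
                         contaminant_fraction = 1, seed = 62)
  sim_c <- simulate_small_rna_library(sc_c)
  lib_c <- process_small_rna(sim_c$lib,
                             contaminant_refs = sc_c$contaminant_refs,
                             mirna_refs = sc_c$mirna_refs)
  expect_equal(nrow(lib_c$reads), 0L)

  expect_error(pirna_scenario(panel[0, ], 100), "at least one family")
  expect_error(pirna_scenario(panel, 100, pingpong_fraction = 1.2),
               "0, 1")
})

test_that("downstream z10 recovers the planted ping-pong ordering across
           families", {
  panel <- fixture_panel(5, 600, 3)
  fracs <- c(0, 0.2, 0.4, 0.6, 0.8)
  rhos <- vapply(c(71, 72, 73), function(seed) {
    sc <- pirna_scenario(panel, library_size = 15000,
                         pingpong_fraction = fracs, seed = seed)
    sim <- simulate_small_rna_library(sc)
    aln <- map_reads(sim$lib, panel_refs(panel), 0, "one_best")
    z <- te_pingpong_scores(aln)
    z <- z[match(panel$family, z$family), ]
    cor(z$z10, fracs, method = "spearman")
  }, numeric(1))
  expect_true(all(rhos >= 0.9 - 1e-9))
})

test_that("negative-binomial counts follow the planted dosage model", {
  pair <- generate_species_pair(200, 300, 0.05, seed = 81)
  # all genes 'expected': hybrid allele mean ~ 0.5 x parental mean
  plan <- dosage_plan(c(expected = 1), nb_mean = 200,
                      nb_dispersion = 0.05)
  sim <- simulate_rnaseq_counts(pair, plan, 3, seed = 82)
  mh <- mean(sim$counts$hybrid_mel)
  mp <- mean(sim$counts$parent_mel)
  se <- sqrt(stats::var(as.vector(sim$counts$hybrid_mel)) / (200 * 3))
  expect_lte(abs(mh - 0.5 * mp), 3 * se)

  # both_under at fold 4: both allele means ~ 0.125 x parental mean
  plan_u <- dosage_plan(c(both_under = 1), nb_mean = 400,
                        nb_dispersion = 0.05, effect_fold = 4)
  sim_u <- simulate_rnaseq_counts(pair, plan_u, 3, seed = 83)
  for (al in c("hybrid_mel", "hybrid_sim")) {
    m <- mean(sim_u$counts[[al]])
    se_u <- sqrt(stats::var(as.vector(sim_u$counts[[al]])) / (200 * 3))
    expect_lte(abs(m - 0.125 * 400), 3 * se_u)
  }

  # zero mean -> all-zero matrix
  plan_0 <- dosage_plan(c(expected = 1), nb_mean = 0)
  sim_0 <- simulate_rnaseq_counts(pair, plan_0, 2, seed = 84)
  expect_true(all(sim_0$counts$parent_mel == 0))

  # determinism and parameter validation
  sim_b <- simulate_rnaseq_counts(pair, plan, 3, seed = 82)
  expect_identical(sim$counts, sim_b$counts)
  expect_error(dosage_plan(c(expected = 1), nb_dispersion = 0),
               "nb_dispersion")
  expect_error(simulate_rnaseq_counts(pair, plan, 1, seed = 1),
               "n_replicates")
})
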