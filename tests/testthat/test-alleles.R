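mk_hits <- function(q, s, bits) {
  data.frame(query_id = q, subject_id = s, pct_identity = 90,
             aln_length = 100, mismatches = 10, gap_opens = 0,
             qstart = 1, qend = 100, sstart = 1, send = 100,
             evalue = 1e-50, bitscore = bits, stringsAsFactors = FALSE)
}

test_that("ortholog resolution keeps best-bitscore hits and demands
           transcript agreement", {
  t2g_q <- c(a1 = "A", a2 = "A", b1 = "B")
  t2g_s <- c(x1 = "X", y1 = "Y", z1 = "Z")

  # all transcripts agree -> accepted with support 2
  hits <- rbind(mk_hits("a1", "x1", 500), mk_hits("a1", "y1", 100),
                mk_hits("a2", "x1", 480))
  out <- resolve_orthologs(hits, t2g_q, t2g_s)
  expect_true(out$accepted[out$gene_query == "A"])
  expect_equal(out$support[out$gene_query == "A"], 2)

  # disagreeing transcripts -> conflict, rejected
  hits2 <- rbind(mk_hits("a1", "x1", 500), mk_hits("a2", "y1", 500))
  out2 <- resolve_orthologs(hits2, t2g_q, t2g_s)
  expect_false(out2$accepted[1])
  expect_true(out2$conflict[1])

  # equal-bitscore tie -> lower subject id wins, pair tie-flagged
  hits3 <- rbind(mk_hits("b1", "z1", 300), mk_hits("b1", "x1", 300))
  out3 <- resolve_orthologs(hits3, t2g_q, t2g_s)
  expect_equal(out3$gene_subject[out3$gene_query == "B"], "X")
  expect_true(out3$tie[out3$gene_query == "B"])

  # two query genes claiming one subject gene are both rejected
  hits4 <- rbind(mk_hits("a1", "x1", 500), mk_hits("a2", "x1", 500),
                 mk_hits("b1", "x1", 400))
  out4 <- resolve_orthologs(hits4, t2g_q, t2g_s)
  expect_false(any(out4$accepted))

  expect_error(resolve_orthologs(mk_hits("zz", "x1", 10), t2g_q, t2g_s),
               "zz")
})

test_that("synthetic transcriptomes at moderate divergence resolve over
           90 percent of ortholog pairs", {
  pair <- generate_species_pair(80, 900, 0.10, seed = 41)
  hom <- simulate_homology_hits(pair, seed = 42)
  out <- resolve_orthologs(hom$hits, hom$tx2gene_mel, hom$tx2gene_sim)
  accept_rate <- sum(out$accepted) / nrow(pair$genes)
  expect_gte(accept_rate, 0.9)
  # accepted pairs point at the true ortholog
  acc <- out[out$accepted, ]
  expect_true(all(sub("mel", "sim", acc$gene_query) == acc$gene_subject))
})

test_that("allele ratios recover the half-dose expectation and dosage
           categories follow the two per-allele calls", {
  pair <- generate_species_pair(500, 300, 0.05, seed = 43)
  plan <- dosage_plan()      # 0.60/0.15/0.10/0.05/0.10 mixed, fold 4
  sim <- simulate_rnaseq_counts(pair, plan, n_replicates = 3, seed = 44)
  pairs <- data.frame(gene_query = pair$genes$gene_mel,
                      gene_subject = pair$genes$gene_sim,
                      accepted = TRUE, stringsAsFactors = FALSE)
  rec <- allele_expression(sim$counts$parent_mel, sim$counts$parent_sim,
                           sim$counts$hybrid_mel, sim$counts$hybrid_sim,
                           pairs)
  # planted 'expected' genes sit at the half-dose level
  expected_genes <- sim$truth$category == "expected"
  med <- median(rec$ratio_query[expected_genes])
  expect_lt(abs(med - 0.5), 0.1)

  rec <- classify_dosage(rec)
  got <- dosage_proportions(rec)
  want <- plan$proportions
  expect_true(all(abs(got - want) <= 0.05))
})

test_that("dosage classification is exact on noise-free ratios and
           symmetric under species swap", {
  rec <- data.frame(ratio_query = c(0.5, 2.0, 0.1, 4, 2),
                    ratio_subject = c(0.5, 0.5, 0.1, 4, 0.1))
  out <- classify_dosage(rec)
  expect_equal(out$category,
               c("expected", "one_allele_over", "both_under", "both_over",
                 "mixed_other"))
  sw <- classify_dosage(data.frame(ratio_query = rec$ratio_subject,
                                   ratio_subject = rec$ratio_query))
  expect_equal(sw$category, out$category)
})

test_that("log-scale Pearson correlation behaves on exact and simulated
           data", {
  x <- c(1, 4, 9, 100, 1000)
  expect_equal(expression_correlation(x, x), 1.0)
  y <- rev(x)
  expect_lt(expression_correlation(x, y), 0)
  expect_warning(r <- expression_correlation(c(1, 1, 1), x[1:3]),
                 "zero variance")
  expect_true(is.na(r))

  # NB-simulated hybrid at half dose, low dispersion: high correlation
  withr::with_seed(45, {
    mu <- exp(runif(300, log(20), log(2000)))
    parent <- rnbinom(300, mu = mu, size = 1 / 0.05)
    hybrid <- rnbinom(300, mu = 0.5 * mu, size = 1 / 0.05)
  })
  expect_gte(expression_correlation(hybrid, parent), 0.9)
})

test_that("repeat-consensus piRNAs give a ping-pong signature on the
           high-identity allele but not the diverged one", {
  scn <- simulate_atchx_scenario(seed = 46)
  rep_ <- vasa_atchx_report(scn$reads, scn$consensus, scn$alleles)
  z_sim <- rep_$alleles$vasa_sim$score
  z_mel <- rep_$alleles$vasa_mel$score
  expect_true(z_sim$defined)
  expect_gte(z_sim$z10, 3)
  expect_true(!z_mel$defined || z_mel$z10 < z_sim$z10)
  # coverage tracks carry both strands on the sim allele insert
  cov <- rep_$alleles$vasa_sim$coverage
  expect_gt(sum(cov$sense), 0)
  expect_gt(sum(cov$antisense), 0)

  # scale invariance: doubling abundances leaves z10 unchanged
  reads2 <- c(scn$reads,
              stats::setNames(unname(scn$reads),
                              paste0(names(scn$reads), "_dup")))
  rep2 <- vasa_atchx_report(reads2, scn$consensus, scn$alleles)
  expect_equal(sign(rep2$alleles$vasa_sim$score$z10), 1)
  expect_gte(rep2$alleles$vasa_sim$score$z10, 3)
})
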