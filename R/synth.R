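# Seeded generators for every synthetic input the pipeline consumes:
# diverged ortholog transcriptome pairs, transposon-derived small-RNA
# libraries with planted ping-pong pairs and contaminants, NB RNA-seq
# counts with planted allele-dosage categories, homology hits for
# ortholog resolution, piRNA-cluster genome segments, and an AT-chX-like
# repeat/allele scenario. All draws come from a single seeded stream per
# call; identical seeds give identical outputs.

# Integer allocation by largest remainder so parts sum exactly to `total`.
allocate_exact <- function(total, weights) {
  w <- weights / sum(weights)
  raw <- total * w
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a pair of diverged species transcriptomes
#'
#' Orthologous gene pairs differ only by independent per-site
#' substitutions (probability `divergence`, never to the same base), so
#' paired coordinates align 1:1 and the mismatch model is exactly
#' binomial.
#'
#' @param n_genes Number of ortholog pairs (>= 1).
#' @param gene_length Transcript length in nt.
#' @param divergence Per-site substitution probability in [0, 0.25].
#' @param seed Integer seed.
#' @return Object of class `species_pair`: a `genes` data.frame
#'   (`gene_mel`, `gene_sim`, `seq_mel`, `seq_sim`) plus the call
#'   parameters.
#' @export
generate_species_pair <- function(n_genes, gene_length, divergence, seed) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  gene_length <- check_count(gene_length, "gene_length", min = 1L)
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.25) {
    stop("`divergence` must be in [0, 0.25]", call. = FALSE)
  }
  with_seed(seed, {
    seq_mel <- rand_dna(n_genes, gene_length)
    seq_sim <- vapply(seq_mel, mutate_dna, character(1), p = divergence,
                      USE.NAMES = FALSE)
    structure(list(
      genes = data.frame(
        gene_mel = sprintf("mel_g%04d", seq_len(n_genes)),
        gene_sim = sprintf("sim_g%04d", seq_len(n_genes)),
        seq_mel = seq_mel, seq_sim = seq_sim, stringsAsFactors = FALSE),
      divergence = divergence, gene_length = gene_length, seed = seed
    ), class = "species_pair")
  })
}

#' Write a species pair as two FASTA files
#'
#' @param pair A `species_pair`.
#' @param mel_path,sim_path Output FASTA paths.
#' @return Invisibly, the two paths.
#' @export
write_species_pair <- function(pair, mel_path, sim_path) {
  stopifnot(inherits(pair, "species_pair"))
  write_fasta(stats::setNames(pair$genes$seq_mel, pair$genes$gene_mel),
              mel_path)
  write_fasta(stats::setNames(pair$genes$seq_sim, pair$genes$gene_sim),
              sim_path)
  invisible(c(mel_path, sim_path))
}

#' Synthetic transposon consensus panel
#'
#' @param n_families Number of TE families.
#' @param consensus_length Consensus length in nt (must be at least three
#'   times the longest read generated from it).
#' @param seed Integer seed.
#' @return data.frame with columns `family`, `te_class`, `consensus`.
#' @export
synthetic_te_panel <- function(n_families = 7L, consensus_length = 600L,
                               seed = 1L) {
  n_families <- check_count(n_families, "n_families", min = 1L)
  with_seed(seed, {
    data.frame(
      family = sprintf("TE%02d", seq_len(n_families)),
      te_class = rep(c("LTR", "LINE", "DNA"), length.out = n_families),
      consensus = rand_dna(n_families, consensus_length),
      stringsAsFactors = FALSE)
  })
}

#' Synthetic structural-RNA contaminant references
#'
#' rRNA/tRNA-like decoy sequences for the contaminant filter.
#'
#' @param seed Integer seed.
#' @param n Number of reference sequences.
#' @param length Length of each reference.
#' @return Named character vector.
#' @export
synthetic_contaminants <- function(seed = 1L, n = 4L, length = 1200L) {
  with_seed(seed, stats::setNames(rand_dna(n, length),
                                  sprintf("rRNA%02d", seq_len(n))))
}

#' Synthetic mature microRNA references
#'
#' @param seed Integer seed.
#' @param n Number of miRNAs.
#' @param length Mature miRNA length (default 22 nt).
#' @return Named character vector.
#' @export
synthetic_mirnas <- function(seed = 1L, n = 20L, length = 22L) {
  with_seed(seed, stats::setNames(rand_dna(n, length),
                                  sprintf("mir%03d", seq_len(n))))
}

#' Describe a synthetic small-RNA library scenario
#'
#' @param te_panel data.frame from [synthetic_te_panel()] (columns
#'   `family`, `te_class`, `consensus`; family names unique; consensus at
#'   least three times the longest read).
#' @param library_size Total number of reads to emit (exactly).
#' @param pingpong_fraction Per-family fraction of antisense reads planted
#'   as ping-pong partners (recycled across families).
#' @param sense_antisense_ratio Per-family sense:antisense read ratio
#'   (recycled).
#' @param contaminant_fraction Fraction of the library drawn from the
#'   contaminant/miRNA references.
#' @param read_length_range Inclusive read-length bounds (default 23-29).
#' @param family_weights Relative family abundances (default equal).
#' @param contaminant_refs,mirna_refs Reference sets the contaminant reads
#'   are drawn from; defaults are generated from `seed`.
#' @param seed Integer seed.
#' @return A validated list of class `pirna_scenario`.
#' @export
pirna_scenario <- function(te_panel, library_size,
                           pingpong_fraction = 0,
                           sense_antisense_ratio = 1,
                           contaminant_fraction = 0,
                           read_length_range = c(23L, 29L),
                           family_weights = NULL,
                           contaminant_refs = NULL, mirna_refs = NULL,
                           seed = 1L) {
  if (is.null(te_panel) || nrow(te_panel) == 0L) {
    stop("`te_panel` must contain at least one family", call. = FALSE)
  }
  stopifnot(all(c("family", "te_class", "consensus") %in% names(te_panel)))
  if (anyDuplicated(te_panel$family)) {
    stop("family names must be unique", call. = FALSE)
  }
  library_size <- check_count(library_size, "library_size")
  check_prob(pingpong_fraction, "pingpong_fraction")
  check_prob(contaminant_fraction, "contaminant_fraction")
  if (any(sense_antisense_ratio <= 0)) {
    stop("`sense_antisense_ratio` must be positive", call. = FALSE)
  }
  if (read_length_range[1L] > read_length_range[2L]) {
    stop("invalid read_length_range", call. = FALSE)
  }
  if (any(nchar(te_panel$consensus) < 3L * read_length_range[2L])) {
    stop("consensus length must be >= 3 x max read length", call. = FALSE)
  }
  n_fam <- nrow(te_panel)
  # Distinct, well-separated sub-seeds: references generated from the
  # same stream as the TE panel (or each other) share long substrings,
  # which would silently divert reads to the wrong filter stage.
  if (is.null(contaminant_refs)) {
    contaminant_refs <- synthetic_contaminants(
      (seed + 104729L) %% .Machine$integer.max)
  }
  if (is.null(mirna_refs)) {
    mirna_refs <- synthetic_mirnas((seed + 224737L) %% .Machine$integer.max)
  }
  structure(list(
    te_panel = te_panel,
    library_size = library_size,
    pingpong_fraction = rep_len(pingpong_fraction, n_fam),
    sense_antisense_ratio = rep_len(sense_antisense_ratio, n_fam),
    contaminant_fraction = contaminant_fraction,
    read_length_range = as.integer(read_length_range),
    family_weights = if (is.null(family_weights)) rep(1, n_fam) else
      rep_len(family_weights, n_fam),
    contaminant_refs = contaminant_refs,
    mirna_refs = mirna_refs,
    seed = check_count(seed, "seed")
  ), class = "pirna_scenario")
}

#' Simulate a small-RNA library from a scenario
#'
#' Emits exactly `library_size` reads: TE-derived sense and antisense
#' reads per family (per the sense:antisense ratio), a planted fraction of
#' antisense reads whose 5' ends overlap a sense mate's 5' end by exactly
#' 10 nt (ping-pong pairs by construction), and contaminant reads drawn
#' half from the structural-RNA references and half from the miRNA
#' references. Positions along the consensus are uniform. Ground truth
#' (origin, strand, ping-pong mate) is returned per read.
#'
#' @param scenario A `pirna_scenario`.
#' @return List with elements `lib` (a `read_library`), `truth`
#'   (data.frame `read_id`, `origin`, `strand`, `pingpong_mate`) and
#'   `scenario`.
#' @export
simulate_small_rna_library <- function(scenario) {
  stopifnot(inherits(scenario, "pirna_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    lmin <- sc$read_length_range[1L]; lmax <- sc$read_length_range[2L]
    rlen <- function(n) sample(lmin:lmax, n, replace = TRUE)

    n_contam <- round(sc$contaminant_fraction * sc$library_size)
    n_te_total <- sc$library_size - n_contam
    fam_n <- allocate_exact(n_te_total, sc$family_weights)

    ids <- character(0); seqs <- character(0)
    origin <- character(0); strand <- character(0); mate <- character(0)
    counter <- 0L
    next_ids <- function(n) sprintf("read_%06d", counter + seq_len(n))

    for (f in seq_len(nrow(sc$te_panel))) {
      cons <- sc$te_panel$consensus[f]
      fam <- sc$te_panel$family[f]
      clen <- nchar(cons)
      nf <- fam_n[f]
      if (nf == 0L) next
      r <- sc$sense_antisense_ratio[f]
      n_anti <- round(nf / (1 + r))
      n_sense <- nf - n_anti
      n_pp <- round(sc$pingpong_fraction[f] * n_anti)
      if (n_sense == 0L) n_pp <- 0L

      # Sense reads: uniform 5' positions (0-based starts).
      ls <- rlen(n_sense)
      ss <- vapply(ls, function(L) sample.int(clen - L + 1L, 1L) - 1L,
                   integer(1))
      sense_seq <- substring(cons, ss + 1L, ss + ls)
      sense_ids <- next_ids(n_sense); counter <- counter + n_sense

      # Planted ping-pong antisense: 5' end 10 nt into a sense read.
      pp_seq <- character(n_pp); pp_mate <- character(n_pp)
      if (n_pp > 0L) {
        mate_idx <- sample.int(n_sense, n_pp, replace = TRUE)
        for (i in seq_len(n_pp)) {
          s <- ss[mate_idx[i]]
          q <- s + 9L                       # antisense 5' (0-based)
          lmax_i <- min(lmax, q + 1L)       # read must fit in [0, q]
          if (lmax_i < lmin) {              # too close to the 5' edge:
            s <- clen %/% 2L; q <- s + 9L   # fall back to a mid placement
            lmax_i <- min(lmax, q + 1L)
            pp_mate[i] <- NA_character_
          } else {
            pp_mate[i] <- sense_ids[mate_idx[i]]
          }
          L2 <- if (lmax_i > lmin) sample(lmin:lmax_i, 1L) else lmin
          pp_seq[i] <- revcomp(substring(cons, q - L2 + 2L, q + 1L))
        }
      }
      pp_ids <- next_ids(n_pp); counter <- counter + n_pp

      # Remaining antisense reads at uniform positions.
      n_bg <- n_anti - n_pp
      lb <- rlen(n_bg)
      sb <- vapply(lb, function(L) sample.int(clen - L + 1L, 1L) - 1L,
                   integer(1))
      bg_seq <- revcomp(substring(cons, sb + 1L, sb + lb))
      bg_ids <- next_ids(n_bg); counter <- counter + n_bg

      ids <- c(ids, sense_ids, pp_ids, bg_ids)
      seqs <- c(seqs, sense_seq, pp_seq, bg_seq)
      origin <- c(origin, rep(fam, nf))
      strand <- c(strand, rep("+", n_sense), rep("-", n_pp + n_bg))
      mate <- c(mate, rep(NA_character_, n_sense), pp_mate,
                rep(NA_character_, n_bg))
    }

    # Contaminants: half structural-RNA substrings, half exact miRNAs.
    n_rrna <- n_contam %/% 2L
    n_mirna <- n_contam - n_rrna
    if (n_rrna > 0L) {
      src <- sample.int(length(sc$contaminant_refs), n_rrna, replace = TRUE)
      lr <- rlen(n_rrna)
      rs <- vapply(seq_len(n_rrna), function(i) {
        sample.int(nchar(sc$contaminant_refs[[src[i]]]) - lr[i] + 1L, 1L)
      }, integer(1))
      cseq <- substring(sc$contaminant_refs[src], rs, rs + lr - 1L)
      cids <- next_ids(n_rrna); counter <- counter + n_rrna
      ids <- c(ids, cids); seqs <- c(seqs, cseq)
      origin <- c(origin, rep("rRNA", n_rrna))
      strand <- c(strand, rep(NA_character_, n_rrna))
      mate <- c(mate, rep(NA_character_, n_rrna))
    }
    if (n_mirna > 0L) {
      mseq <- unname(sample(sc$mirna_refs, n_mirna, replace = TRUE))
      mids <- next_ids(n_mirna); counter <- counter + n_mirna
      ids <- c(ids, mids); seqs <- c(seqs, mseq)
      origin <- c(origin, rep("miRNA", n_mirna))
      strand <- c(strand, rep(NA_character_, n_mirna))
      mate <- c(mate, rep(NA_character_, n_mirna))
    }

    list(
      lib = read_library(ids, seqs),
      truth = data.frame(read_id = ids, origin = origin, strand = strand,
                         pingpong_mate = mate, stringsAsFactors = FALSE),
      scenario = sc)
  })
}

#' Describe a planted allele-dosage plan
#'
#' @param proportions Named numeric vector of category proportions over
#'   `expected`, `one_allele_over`, `both_over`, `both_under`,
#'   `mixed_other` (must sum to 1; omitted categories default to 0).
#' @param nb_mean Parental NB mean count per gene.
#' @param nb_dispersion NB dispersion (variance = mu + a mu^2); must be
#'   positive.
#' @param effect_fold Fold effect applied by the planted categories
#'   (>= 2).
#' @return List of class `dosage_plan`.
#' @export
dosage_plan <- function(proportions = c(expected = 0.60,
                                        one_allele_over = 0.15,
                                        both_over = 0.10,
                                        both_under = 0.05,
                                        mixed_other = 0.10),
                        nb_mean = 200, nb_dispersion = 0.05,
                        effect_fold = 4) {
  lv <- c("expected", "one_allele_over", "both_over", "both_under",
          "mixed_other")
  p <- stats::setNames(numeric(5L), lv)
  if (is.null(names(proportions)) ||
      !all(names(proportions) %in% lv)) {
    stop("proportions must be named with valid categories", call. = FALSE)
  }
  p[names(proportions)] <- proportions
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1",
                                   call. = FALSE)
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (nb_mean < 0) stop("nb_mean must be >= 0", call. = FALSE)
  if (effect_fold < 2) stop("effect_fold must be >= 2", call. = FALSE)
  structure(list(proportions = p, nb_mean = nb_mean,
                 nb_dispersion = nb_dispersion, effect_fold = effect_fold),
            class = "dosage_plan")
}

#' Simulate RNA-seq counts with planted allele-dosage categories
#'
#' Parental counts are NB(`nb_mean`, `nb_dispersion`) per replicate.
#' Hybrid allele counts are NB at half the parental mean scaled by the
#' planted category effect: `expected` leaves both alleles at the
#' half-dose level; `one_allele_over` multiplies one random allele by
#' `effect_fold`; `both_over`/`both_under` scale both alleles up/down;
#' `mixed_other` puts one allele over and the other under.
#'
#' @param pair A `species_pair`.
#' @param plan A `dosage_plan`.
#' @param n_replicates Replicates per sample class (>= 2).
#' @param seed Integer seed.
#' @return List with `counts` (matrices `parent_mel`, `parent_sim`,
#'   `hybrid_mel`, `hybrid_sim`, genes x replicates) and `truth`
#'   (data.frame `gene_mel`, `gene_sim`, `category`, `over_allele`).
#' @export
simulate_rnaseq_counts <- function(pair, plan, n_replicates, seed) {
  stopifnot(inherits(pair, "species_pair"), inherits(plan, "dosage_plan"))
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  n <- nrow(pair$genes)
  with_seed(seed, {
    cat_n <- allocate_exact(n, plan$proportions)
    categories <- sample(rep(names(plan$proportions), times = cat_n))
    which_allele <- sample(c("mel", "sim"), n, replace = TRUE)
    f <- plan$effect_fold
    mult <- function(allele) {
      m <- rep(1, n)
      m[categories == "both_over"] <- f
      m[categories == "both_under"] <- 1 / f
      over_this <- which_allele == allele
      m[categories == "one_allele_over" & over_this] <- f
      m[categories == "mixed_other" & over_this] <- f
      m[categories == "mixed_other" & !over_this] <- 1 / f
      m
    }
    draw <- function(mu) {
      matrix(stats::rnbinom(n * n_replicates, mu = rep(mu, n_replicates),
                            size = 1 / plan$nb_dispersion),
             nrow = n, ncol = n_replicates)
    }
    counts <- list(
      parent_mel = draw(rep(plan$nb_mean, n)),
      parent_sim = draw(rep(plan$nb_mean, n)),
      hybrid_mel = draw(0.5 * plan$nb_mean * mult("mel")),
      hybrid_sim = draw(0.5 * plan$nb_mean * mult("sim")))
    rownames(counts$parent_mel) <- pair$genes$gene_mel
    rownames(counts$hybrid_mel) <- pair$genes$gene_mel
    rownames(counts$parent_sim) <- pair$genes$gene_sim
    rownames(counts$hybrid_sim) <- pair$genes$gene_sim
    for (i in seq_along(counts)) {
      colnames(counts[[i]]) <- paste0("rep", seq_len(n_replicates))
    }
    list(counts = counts,
         truth = data.frame(gene_mel = pair$genes$gene_mel,
                            gene_sim = pair$genes$gene_sim,
                            category = categories,
                            over_allele = ifelse(
                              categories %in% c("one_allele_over",
                                                "mixed_other"),
                              which_allele, NA_character_),
                            stringsAsFactors = FALSE))
  })
}

# Positionwise identity between two equal-length sequences.
seq_matches <- function(a, b) {
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  L <- min(length(ai), length(bi))
  sum(ai[seq_len(L)] == bi[seq_len(L)])
}

#' Simulate tabular homology hits between two transcriptomes
#'
#' Each gene of the pair gets 1-3 transcripts per species (copies of the
#' gene sequence). For every query (mel) transcript, hits are emitted
#' against the orthologous subject transcripts plus a few random decoy
#' transcripts, with bitscores proportional to positionwise identity. An
#' optional `conflict_rate` redirects a transcript's best hit to a wrong
#' gene, producing the disagreements the resolver must reject.
#'
#' @param pair A `species_pair`.
#' @param seed Integer seed.
#' @param max_transcripts Maximum transcripts per gene (default 3).
#' @param n_decoys Decoy subject transcripts per query (default 3).
#' @param conflict_rate Probability a query transcript's hits are
#'   corrupted toward a wrong subject gene (default 0.02).
#' @return List with `hits` (12-column data.frame as from
#'   [read_blast_tab()]), `tx2gene_mel`, `tx2gene_sim`.
#' @export
simulate_homology_hits <- function(pair, seed, max_transcripts = 3L,
                                   n_decoys = 3L, conflict_rate = 0.02) {
  stopifnot(inherits(pair, "species_pair"))
  g <- pair$genes
  n <- nrow(g)
  with_seed(seed, {
    n_tx_mel <- sample.int(max_transcripts, n, replace = TRUE)
    n_tx_sim <- sample.int(max_transcripts, n, replace = TRUE)
    tx_mel <- unlist(lapply(seq_len(n), function(i)
      sprintf("%s_t%d", g$gene_mel[i], seq_len(n_tx_mel[i]))))
    tx_sim <- unlist(lapply(seq_len(n), function(i)
      sprintf("%s_t%d", g$gene_sim[i], seq_len(n_tx_sim[i]))))
    tx2gene_mel <- stats::setNames(rep(g$gene_mel, n_tx_mel), tx_mel)
    tx2gene_sim <- stats::setNames(rep(g$gene_sim, n_tx_sim), tx_sim)
    sim_gene_of_tx <- rep(seq_len(n), n_tx_sim)

    L <- pair$gene_length
    rows <- list(); nr <- 0L
    for (qi in seq_len(n)) {
      # True target gene; corrupted queries point at a random wrong gene.
      for (t in seq_len(n_tx_mel[qi])) {
        qid <- sprintf("%s_t%d", g$gene_mel[qi], t)
        target <- qi
        if (n > 1L && stats::runif(1L) < conflict_rate) {
          target <- sample(setdiff(seq_len(n), qi), 1L)
        }
        subj_tx <- which(sim_gene_of_tx == target)
        decoys <- if (n > 1L)
          sample(which(sim_gene_of_tx != target),
                 min(n_decoys, sum(sim_gene_of_tx != target))) else integer(0)
        for (si in c(subj_tx, decoys)) {
          is_target <- sim_gene_of_tx[si] == target
          m <- if (is_target) seq_matches(g$seq_mel[qi],
                                          g$seq_sim[target]) else
            seq_matches(g$seq_mel[qi], g$seq_sim[sim_gene_of_tx[si]])
          nr <- nr + 1L
          rows[[nr]] <- data.frame(
            query_id = qid, subject_id = tx_sim[si],
            pct_identity = 100 * m / L, aln_length = L,
            mismatches = L - m, gap_opens = 0L,
            qstart = 1L, qend = L, sstart = 1L, send = L,
            evalue = 10^(-pmin(180, m / 6)), bitscore = round(2 * m, 1),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(hits = do.call(rbind, rows), tx2gene_mel = tx2gene_mel,
         tx2gene_sim = tx2gene_sim)
  })
}

#' Simulate a piRNA-cluster scenario on a merged two-genome reference
#'
#' Two kilobase-scale genome segments stand in for the two parental
#' genomes. The melanogaster-like segment carries a dual-strand cluster
#' and a uni-strand cluster; a copy of part of the dual cluster is planted
#' in the simulans-like segment so reads from it occur verbatim in both
#' genomes and are discarded by the best-unique rule. Per genotype, a
#' library of fixed size is emitted: cluster-derived reads (scaled by
#' `hybrid_factor` in the hybrid) plus random background reads filling the
#' library to size, so rpm ratios recover `hybrid_factor`.
#'
#' @param seed Integer seed.
#' @param segment_length Length of each genome segment (default 4000).
#' @param library_size Reads per genotype library (default 4000).
#' @param cluster_reads Cluster-derived reads per cluster in the parent
#'   (default 600).
#' @param hybrid_factor Hybrid/parent activity ratio planted for both
#'   clusters (default 0.5, the half-dose expectation).
#' @param shared_fraction Fraction of cluster reads drawn from the shared
#'   (two-genome) segment (default 0.1).
#' @param read_length_range Inclusive read-length bounds.
#' @return List with `references` (merged named vector), `intervals`,
#'   `libs` (list of `read_library` per genotype with normalization depth
#'   set to the library size), and `truth` counts.
#' @export
simulate_cluster_scenario <- function(seed, segment_length = 4000L,
                                      library_size = 4000L,
                                      cluster_reads = 600L,
                                      hybrid_factor = 0.5,
                                      shared_fraction = 0.1,
                                      read_length_range = c(23L, 29L)) {
  with_seed(seed, {
    lmin <- read_length_range[1L]; lmax <- read_length_range[2L]
    mel <- rand_dna(1L, segment_length)
    sim <- rand_dna(1L, segment_length)
    # Shared block: copy 400 nt of the dual cluster into the sim segment.
    shared_start <- 700L                    # 0-based, inside dual cluster
    block <- substring(mel, shared_start + 1L, shared_start + 400L)
    sim <- paste0(substring(sim, 1L, 1999L), block,
                  substring(sim, 2400L, segment_length))
    refs <- c(mel_seg = mel, sim_seg = sim)
    intervals <- data.frame(
      genome_label = "mel", chrom = "mel_seg",
      start = c(500L, 2500L), end = c(1500L, 3500L),
      name = c("cluster_dual", "cluster_uni"),
      cluster_type = c("dual", "uni"), stringsAsFactors = FALSE)

    draw_from <- function(n, lo, hi, strand_plus_prob) {
      if (n == 0L) return(character(0))
      L <- sample(lmin:lmax, n, replace = TRUE)
      s <- vapply(L, function(l) sample(lo:(hi - l), 1L), integer(1))
      w <- substring(mel, s + 1L, s + L)
      flip <- stats::runif(n) >= strand_plus_prob
      w[flip] <- revcomp(w[flip])
      w
    }
    make_lib <- function(scale, tag) {
      n_dual <- round(cluster_reads * scale)
      n_uni <- round(cluster_reads * scale)
      n_shared <- round(shared_fraction * n_dual)
      n_dual_u <- n_dual - n_shared
      seqs <- c(
        # unique part of the dual cluster, both strands
        draw_from(n_dual_u, 1100L, 1500L, 0.5),
        # shared block: present verbatim in both genomes
        draw_from(n_shared, shared_start, shared_start + 400L, 0.5),
        # uni-strand cluster: sense only
        draw_from(n_uni, 2500L, 3500L, 1))
      n_bg <- library_size - length(seqs)
      seqs <- c(seqs, rand_dna(n_bg, lmax))
      lib <- read_library(sprintf("%s_%06d", tag, seq_along(seqs)), seqs)
      lib$normalization_depth <- library_size
      lib
    }
    libs <- list(mel = make_lib(1, "mel"),
                 hybrid = make_lib(hybrid_factor, "hyb"))
    list(references = refs, intervals = intervals, libs = libs,
         truth = list(hybrid_factor = hybrid_factor,
                      cluster_reads = cluster_reads,
                      shared_fraction = shared_fraction))
  })
}

#' Simulate an AT-chX-like repeat / vasa-allele scenario
#'
#' A repeat consensus plus two allele transcripts carrying a copy of the
#' consensus at the stated identities (95% for the simulans-like allele,
#' 80% for the melanogaster-like allele by default). Reads comprise
#' planted ping-pong pairs -- sense reads from each allele's insert region
#' paired with consensus-derived antisense reads whose 5' ends overlap by
#' 10 nt -- plus unpaired sense background from each allele.
#'
#' @param seed Integer seed.
#' @param consensus_length Repeat consensus length (default 600).
#' @param transcript_length Allele transcript length (default 1800).
#' @param identity_sim,identity_mel Insert identity per allele.
#' @param n_pairs Ping-pong pairs planted per allele (default 300).
#' @param n_background Unpaired sense reads per allele (default 300).
#' @param read_length_range Inclusive read-length bounds.
#' @return List with `consensus` (named length-1 vector), `alleles`
#'   (named vector `vasa_mel`, `vasa_sim`), `reads` (named vector) and
#'   `insert_start` (0-based insert offset in both transcripts).
#' @export
simulate_atchx_scenario <- function(seed, consensus_length = 600L,
                                    transcript_length = 1800L,
                                    identity_sim = 0.95,
                                    identity_mel = 0.80,
                                    n_pairs = 300L, n_background = 300L,
                                    read_length_range = c(23L, 29L)) {
  with_seed(seed, {
    lmin <- read_length_range[1L]; lmax <- read_length_range[2L]
    cons <- rand_dna(1L, consensus_length)
    insert_start <- 600L                     # 0-based offset in transcript
    make_allele <- function(identity) {
      ins <- mutate_dna(cons, 1 - identity)
      backbone <- rand_dna(1L, transcript_length)
      paste0(substring(backbone, 1L, insert_start), ins,
             substring(backbone, insert_start + consensus_length + 1L,
                       transcript_length))
    }
    alleles <- c(vasa_mel = make_allele(identity_mel),
                 vasa_sim = make_allele(identity_sim))
    ids <- character(0); seqs <- character(0)
    counter <- 0L
    for (al in names(alleles)) {
      tr <- alleles[[al]]
      # Sense 5' positions inside the insert, in consensus coordinates,
      # leaving room for the antisense mate on the consensus.
      smax <- consensus_length - lmax - 1L
      s_cons <- sample(20:smax, n_pairs, replace = TRUE)
      for (i in seq_len(n_pairs)) {
        L1 <- sample(lmin:lmax, 1L)
        # Sense read from the allele transcript.
        a <- insert_start + s_cons[i]
        counter <- counter + 1L
        ids <- c(ids, sprintf("%s_pp_%05d", al, counter))
        seqs <- c(seqs, substring(tr, a + 1L, a + L1))
        # Antisense mate from the consensus: 5' at s + 9.
        q <- s_cons[i] + 9L
        L2 <- sample(lmin:min(lmax, q + 1L), 1L)
        counter <- counter + 1L
        ids <- c(ids, sprintf("atchx_%05d", counter))
        seqs <- c(seqs, revcomp(substring(cons, q - L2 + 2L, q + 1L)))
      }
      # Unpaired sense background across the transcript.
      Lb <- sample(lmin:lmax, n_background, replace = TRUE)
      sb <- vapply(Lb, function(l)
        sample.int(transcript_length - l, 1L) - 1L, integer(1))
      ids <- c(ids, sprintf("%s_bg_%05d", al, seq_len(n_background)))
      seqs <- c(seqs, substring(tr, sb + 1L, sb + Lb))
    }
    reads <- stats::setNames(seqs, ids)
    list(consensus = c(atchx_consensus = cons), alleles = alleles,
         reads = reads, insert_start = insert_start)
  })
}

#' Write a ground-truth table as TSV
#'
#' @param truth data.frame of per-read ground truth.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
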