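---
title: "Methods: piRNA and allele-specific expression analysis in interspecific Drosophila hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA and allele-specific expression analysis in interspecific Drosophila hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridpirna)
```

# Scope and model

`hybridpirna` re-implements, at desk scale, the computational analyses
used to characterise female sterility in F1 hybrids of *Drosophila
melanogaster* mothers and *D. simulans* fathers: small-RNA (piRNA)
library processing, ping-pong signature statistics, per-transposon-family
piRNA quantification and silencing-potential classification, piRNA
cluster activity via unique mapping to a merged two-genome reference,
ortholog resolution, and allele-specific dosage classification of hybrid
expression. A seeded synthetic-data generator supplies every input with
the statistical structure the analyses assume, so the whole pipeline is
testable without external sequence downloads.

# Small-RNA processing and rpm normalization

Reads pass through an ordered cascade — adapter trimming, quality
filtering (FASTQ only), structural-RNA (rRNA/snRNA/snoRNA/tRNA)
filtering, miRNA filtering, and 23–29 nt length selection — with the
surviving depth recorded at each stage. Two conventions matter:

* **Normalization depth.** Reads-per-million values are normalized to
  the library depth *before miRNA filtration*, i.e. the depth recorded
  after contaminant removal. Whether the denominator should also precede
  structural-RNA filtering is ambiguous in the field; we pin it to the
  post-contaminant depth (the literal reading of "before microRNA
  filtration") and treat the raw-depth alternative as a user decision —
  `rpm()` accepts an explicit depth.
* **Length bounds.** "23–29 nt" is inclusive on both ends, the naming
  convention for the ovarian piRNA fraction.

Adapter trimming removes the longest exact suffix/prefix overlap of at
least 3 nt; no error tolerance is applied because the synthetic reads
are generated error-free. Both reference filters remove reads aligning
anywhere in the reference set, either strand, ungapped, with at most 3
mismatches.

# The mapper

At 23–29 nt and at most 3 mismatches, heuristic seed-based mappers are
unnecessary: `map_reads()` performs an exact ungapped Hamming search. A
pigeonhole seed index (k+1 disjoint seeds, so any placement with at most
k mismatches contains one exact seed) accelerates the scan; with zero
mismatches an exact window hash is used. Either way the output equals
the exhaustive window scan, which the test suite asserts against an
independent brute-force implementation. `N` mismatches everything,
including `N` — a conservative choice.

Three reporting policies mirror the two mapping modes of the original
analysis:

* `all_hits` — every qualifying placement (used for overlap
  histograms and coverage tracks);
* `one_best` — one minimum-mismatch placement per read, tie-broken
  deterministically (reference id, then start, then `+` strand): the TE
  quantification mode (`-m 1`-like, 0–3 mm);
* `best_unique` — reads whose best placement is not unique are
  discarded entirely: the species-specificity device. With 0 mismatches
  on a merged two-genome reference, any read occurring in both genomes
  contributes to neither.

The original runs constrained mismatches in the seed region only, so
totals could exceed 3; we pin "at most 3 mismatches over the whole
read", which matches the 0–3 mm convention used for reporting antisense
piRNA abundances.

# Ping-pong statistics

For a sense alignment with 5′ end at coordinate `p` (= start) and an
antisense alignment with 5′ end at `q` (= start + length − 1), the pair
contributes to overlap `o = q − p + 1`; a perfect ping-pong pair gives
`o = 10`. Counting is exhaustive over read pairs with abundance
weighting, computed as a convolution of the two weighted 5′-position
profiles, so it is exact at desk scale. The z10 statistic compares bin
10 against the background of bins 1–30 excluding 10 (mean and sample
SD); including bin 10 in the background only shrinks the score and is
exposed as an option. A flat histogram scores exactly 0; an all-zero
histogram or a zero-variance background with a deviating focal bin is
reported as undefined (flagged), never as an exception. Multi-mapped
and mismatched (≤3 mm) reads participate unweighted by mismatch count.

The cross-set variant builds the histogram only from pairs with one
member in each of two populations on a shared coordinate system (either
strand arrangement), and is symmetric in its arguments. In
`vasa_atchx_report()` set A holds the allele placements of
repeat-consensus-matching piRNAs and set B all allele-mapped piRNAs;
membership may overlap, because excluding consensus-matching reads from
set B would discard planted pairs whose sense member also matches the
consensus within the mismatch gate.

One behaviour worth knowing: at fixed planted pair fraction, z10 is not
monotone in sequencing depth. As read density per consensus position
grows, random sense/antisense pairings inflate every bin, and the
planted excess in bin 10 shrinks relative to the inter-bin background
variance. The package's simulations therefore spread reads over a
multi-family panel (about 7 × 10³ reads per 600 nt family at the 50,000
read library size), which keeps densities in the regime where a planted
0.8 fraction yields z10 well above 3 while null libraries stay near 0.

# TE quantification and silencing potential

TE-mapped piRNAs (one best placement, 0–3 mm, consensus stored in sense
orientation) are split by strand and converted to rpm. Classification
rules:

* **Silencing potential** is a strict threshold: antisense rpm > 100.
  Exactly 100 rpm fails.
* **Fold reduction** is parent rpm / hybrid rpm. Reported values are
  rounded half-up to one decimal; *classification* (the fivefold
  cohort) uses unrounded ratios with an inclusive `>= 5` boundary. The
  inclusive boundary is forced by the reported cohort counts: one
  family sits at 5.04-fold versus one parent and is counted.

On the shipped table of antisense rpm values for the seven TE families
derepressed in hybrid ovaries, the pipeline reproduces: hybrid
silencing-potential pass set {blood, gypsy12, rover} and fail set
{Burdock, diver, HMS-Beagle, jockey}; fold reductions versus
*D. melanogaster* spanning 2.6–13.4; and fivefold-loss cohort counts of
3 (versus both parents) and 6 (versus at least one).

```{r te}
tab <- derepressed_te_table()
data.frame(family = tab$family,
           fold_vs_mel = fold_reduction(tab$mel, tab$hybrid),
           silencing_hybrid = silencing_potential(tab$hybrid))
cohort_summary(tab)[c("n_vs_both", "n_vs_at_least_one")]
```

# Differential expression

The DE engine is deliberately transparent rather than shrinkage-based:
the decisions it feeds are threshold rules, not fitter subtleties.

* **Size factors**: median-of-ratios over features with nonzero
  geometric mean, rescaled to geometric mean 1.
* **Test**: per feature, group means of normalized counts and a pooled
  method-of-moments NB dispersion `alpha = max(0, (var − mu)/mu²)`
  (df-weighted across groups). By the delta method,
  `Var(log mean) ≈ (1/mu + alpha)/n`, giving a Wald statistic for the
  log fold change. The statistic is referred to a t distribution with
  `nA + nB − 2` degrees of freedom: with 2–3 replicates the plug-in
  dispersion is noisy and a normal reference is anticonservative; the
  t reference keeps the empirical type-I error within [0.03, 0.08] at
  nominal 0.05 on NB nulls, which the acceptance suite checks.
* **Thresholds** are strict: `|log2FC| > threshold` and adjusted
  `p < 0.05`. The TE convention uses 2.32, chosen so that a true
  fivefold change (log2(5) = 2.3219…) passes while 2.32 exactly fails.
* When either group mean is zero, a pseudocount of 0.5 enters the
  reported log2FC and the row is flagged; all-zero features get p = 1.

A boundary property worth stating: an effect planted *exactly at* a
threshold is detected about half the time, whatever the fitter, because
the estimate is symmetric around the boundary. Power statements are
therefore only meaningful for effects strictly beyond the threshold;
the suite demonstrates >90% detection for tenfold effects under the
fivefold rule.

# Ortholog resolution and allele dosage

Per query transcript the maximum-bitscore hit is kept (ties resolved
toward the lexicographically lower subject id and flagged); a gene pair
is accepted only if all transcripts of the query gene agree on one
subject gene, and a subject gene claimed by more than one query gene
rejects all claimants, so accepted pairs are one-to-one.

Hybrid allele expression uses the half-dose expectation: one copy per
allele in the F1, so expected expression is half the two-copy parental
level. Ratios are computed on replicate-averaged values after
median-of-ratios normalization *within* each sample class. Cross-library
rescaling is deliberately not applied: a global factor estimated from
the hybrid would absorb exactly the dosage shifts being measured, and
per-sample total-count scaling lets planted over/under categories shift
the library composition and bias all ratios toward the band edges.
Inputs must therefore be comparable across libraries (tpm-like
abundances, or counts generated at a common depth, as the synthetic
generator does).

The "expected level" band is nowhere quantified in the source analyses;
we pin expected = half-dose within a twofold band (`band_log2 = 1`),
consistent with the twofold DE convention, and expose it as a
parameter. Per allele the call is over / expected / under; the pair of
calls maps onto five categories (`expected`, `one_allele_over`,
`both_over`, `both_under`, `mixed_other`). The reported real-data split
(60.3/15.2/9.8/5.2%) depends on genome-scale data and the original
band choice, and is not reproducible at desk scale; the package instead
demonstrates recovery of *planted* category proportions within ±5
percentage points (500 genes, 3 replicates, fourfold effects).

# Cluster activity

Cluster-derived piRNA activity is counted from best-unique,
zero-mismatch placements on the merged two-genome reference. A read is
assigned to an interval when its 5′ end lies in `[start, end)` — a
single unambiguous rule for boundary reads; full containment is
available as an option. The hybrid/parent rpm ratio is reported per
cluster with 0.5 as the expected line for a single-copy inherited
cluster. Synthetic "genomes" are kilobase-scale segments carrying the
intervals — a declared desk-scale stand-in, with a planted shared block
that exercises the uniqueness rule.

# The synthetic generator: what it emulates, and what it does not

* **Transcriptomes**: ortholog pairs differ by independent per-site
  substitutions only (no indels), so coordinates align 1:1 and the
  mismatch model is exactly binomial — testable, at the cost of
  realism in indel-rich regions.
* **piRNA libraries**: reads are uniform along each consensus;
  ping-pong pairs are planted *by construction* (antisense 5′ placed
  10 nt into a sense read's span), not by simulating slicing kinetics,
  because the statistic depends only on 5′–5′ geometry. Real piRNA
  abundance is highly non-uniform across positions; uniformity is an
  unvalidated default, declared here.
* **Contaminants**: half structural-RNA substrings, half exact mature
  miRNAs. The miRNA reference set is derived from `seed + 1` so the two
  reference sets never share a generator stream (a shared stream makes
  the first miRNA a literal prefix of the first rRNA reference and
  removes those reads one filter stage early).
* **RNA-seq counts**: negative binomial with common mean (default 200)
  and dispersion 0.05 — typical of replicate-level gene counts — and
  two biological replicates in the emulated design (the generator
  requires at least 2; recovery analyses use 3). No GC, length, or
  batch structure is modelled.
* **Determinism**: every generator takes one integer seed, draws from a
  single stream under `withr::with_seed` (caller RNG state untouched),
  and is bit-reproducible; read counts are conserved exactly via
  largest-remainder allocation.

Passing tests on these inputs show the *rules and statistics* are
implemented correctly and recover planted structure; they do not show
robustness to indels, positional piRNA bias, ligation bias, or
genome-scale multi-mapping complexity.

# Numerical choices and degenerate inputs

* Half-up rounding (not banker's) for reported 1-decimal folds.
* z10 of a flat histogram is 0 by convention; all-zero histograms and
  zero-variance backgrounds are flagged undefined rather than raising.
* `fold_reduction` and `relative_activity` return flagged `NA` on zero
  denominators.
* Deterministic tie-breaks everywhere (mapper placement order, ortholog
  subject ids) — no RNG outside the generators.
* Problem sizes used by the test and acceptance runs: 50,000-read
  libraries over seven 600-nt families for the planted ping-pong check;
  20 seeds × 8,000 reads for the null; 200 reads × 5 kb for mapper
  oracle equivalence; 500 genes × 3 replicates for dosage recovery;
  1,000-feature nulls for test calibration. These are the package's
  declared desk-scale study conditions.

# Known limitations

Ungapped mapping only (no indels or splicing); no quality-aware
scoring; no 1U/10A nucleotide-bias or phasing statistics; no dispersion
shrinkage, independent filtering, or outlier handling in the DE engine;
ortholog resolution assumes transcript-to-gene maps are complete and
errors otherwise. Genome-scale reported values that depend on the full
deposited libraries (expression correlations near 0.94, TE DE cohort
sizes, absolute cluster levels) are out of reach of synthetic desk-scale
data and are covered instead by the recovery and invariance properties
above.
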