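# Transparent count-based differential-expression engine: median-of-ratios
# size factors, a method-of-moments negative-binomial Wald test, and BH
# correction. Deliberately shrinkage-free: the decisions downstream hinge
# on fold-change/FDR thresholds, not on the fitter, and every formula here
# is stated in the vignette.

#' Median-of-ratios size factors
#'
#' For each sample, the median over features of the ratio of its count to
#' the feature's geometric mean across samples, computed over features
#' with a nonzero geometric mean, then rescaled so the factors themselves
#' have geometric mean 1.
#'
#' @param counts Numeric matrix, features x samples.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_gm <- rowMeans(log(counts))           # -Inf where any count is 0
  use <- is.finite(log_gm)
  if (!any(use)) {
    stop("no feature has nonzero counts in all samples", call. = FALSE)
  }
  sf <- apply(counts[use, , drop = FALSE], 2L, function(cnts) {
    stats::median(exp(log(cnts) - log_gm[use]))
  })
  sf / exp(mean(log(sf)))
}

# Method-of-moments NB dispersion pooled across the two groups:
# alpha = (var - mu) / mu^2 per group, variance-weighted by df, floored
# at 0 (Poisson).
pooled_dispersion <- function(na_, ma, va, nb_, mb, vb) {
  d1 <- ifelse(ma > 0, (va - ma) / ma^2, 0)
  d2 <- ifelse(mb > 0, (vb - mb) / mb^2, 0)
  a <- ((na_ - 1) * d1 + (nb_ - 1) * d2) / (na_ + nb_ - 2)
  pmax(a, 0)
}

#' Negative-binomial Wald test between two groups
#'
#' Counts are divided by their size factors; per feature, group means and
#' a pooled method-of-moments dispersion are estimated, and the log fold
#' change is tested with a Wald statistic. Using the delta method on the
#' log of a group mean of NB counts, `Var(log mean) ~ (1/mu + alpha)/n`;
#' the statistic is referred to a t distribution with `nA + nB - 2`
#' degrees of freedom as a small-sample correction for the plug-in
#' dispersion. When either group mean is zero, a pseudocount of 0.5 is
#' added to both means for the reported log2 fold change (flagged).
#' All-zero features get `p = 1`, `log2FC = 0`, flagged.
#'
#' @param counts_a,counts_b Numeric matrices, features x replicates, with
#'   identical rownames (feature ids) and >= 2 replicates each.
#' @param sf Size factors for `cbind(counts_a, counts_b)`; computed with
#'   [size_factors()] when `NULL`.
#' @return data.frame with columns `feature_id`, `mean_expression`,
#'   `log2_fold_change`, `p_value`, `p_adj`, `dispersion`, `flagged`.
#' @export
nb_test <- function(counts_a, counts_b, sf = NULL) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (ncol(counts_a) < 2L || ncol(counts_b) < 2L) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  if (nrow(counts_a) != nrow(counts_b)) {
    stop("feature sets differ between groups", call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(cbind(counts_a, counts_b))
  na_ <- ncol(counts_a); nb_ <- ncol(counts_b)
  norm_a <- sweep(counts_a, 2L, sf[seq_len(na_)], "/")
  norm_b <- sweep(counts_b, 2L, sf[na_ + seq_len(nb_)], "/")
  ma <- rowMeans(norm_a); mb <- rowMeans(norm_b)
  va <- apply(norm_a, 1L, stats::var)
  vb <- apply(norm_b, 1L, stats::var)
  alpha <- pooled_dispersion(na_, ma, va, nb_, mb, vb)

  zero_either <- ma == 0 | mb == 0
  all_zero <- ma == 0 & mb == 0
  lfc <- ifelse(zero_either, log2(mb + 0.5) - log2(ma + 0.5),
                log2(mb) - log2(ma))
  lfc[all_zero] <- 0

  se_ln <- sqrt(ifelse(ma > 0, (1 / ma + alpha) / na_, 0) +
                  ifelse(mb > 0, (1 / mb + alpha) / nb_, 0))
  wald <- ifelse(se_ln > 0, (lfc * log(2)) / se_ln, 0)
  df <- na_ + nb_ - 2L
  p <- 2 * stats::pt(-abs(wald), df = df)
  p[all_zero] <- 1
  p[zero_either & !all_zero] <-
    2 * stats::pt(-abs(lfc[zero_either & !all_zero] * log(2) /
                         pmax(se_ln[zero_either & !all_zero], 1e-8)),
                  df = df)

  ids <- rownames(counts_a)
  if (is.null(ids)) ids <- paste0("feature_", seq_len(nrow(counts_a)))
  data.frame(feature_id = ids,
             mean_expression = (ma + mb) / 2,
             log2_fold_change = lfc,
             p_value = p,
             p_adj = bh_adjust(p),
             dispersion = alpha,
             flagged = zero_either,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR correction with monotonicity enforcement. Values outside
#' [0, 1] are rejected.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Flag differentially expressed features
#'
#' A feature is significant when `|log2FC|` strictly exceeds the
#' configured threshold and the BH-adjusted p-value is strictly below
#' `alpha`. The TE-family convention uses threshold 2.32 ("fivefold"):
#' log2(5) = 2.3219 passes while exactly 2.32 does not.
#'
#' @param results data.frame from [nb_test()].
#' @param log2fc_threshold Positive log2 fold-change threshold.
#' @param alpha FDR level (default 0.05).
#' @return `results` with a logical `significant` column added.
#' @export
classify_de <- function(results, log2fc_threshold, alpha = 0.05) {
  if (log2fc_threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  results$significant <- abs(results$log2_fold_change) > log2fc_threshold &
    results$p_adj < alpha
  results
}
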