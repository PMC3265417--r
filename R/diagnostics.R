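#' Principal components of a beta matrix
#'
#' Projects samples onto the principal axes of the probe-centered matrix
#' (each CpG centered across samples) via singular value decomposition.
#'
#' @param beta numeric beta matrix (probes x samples).
#' @param center center each probe before decomposition.
#' @return list with `scores` (samples x components) and
#'   `variance_fractions` (per-component fraction of total variance,
#'   summing to 1).
#' @export
beta_pca <- function(beta, center = TRUE) {
  if (ncol(beta) < 2) stop("PCA needs at least 2 samples")
  x <- t(beta[rowSums(is.na(beta)) == 0, , drop = FALSE])
  if (ncol(x) == 0) stop("no complete CpGs")
  pc <- stats::prcomp(x, center = center, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot <= .Machine$double.eps)
    stop("matrix has no variance across samples")
  list(scores = pc$x, variance_fractions = pc$sdev^2 / tot)
}

#' Test the first principal components for batch association
#'
#' For each of the first `k` components, tests whether the sample scores
#' differ by batch: a two-sample Wilcoxon rank-sum test for 2 batches
#' (exact whenever sample sizes permit), Kruskal-Wallis for more.
#'
#' @param scores sample x component score matrix from [beta_pca()].
#' @param samples a [sample_sheet()].
#' @param k number of leading components to test (truncated with a
#'   warning if fewer are available).
#' @param alpha significance threshold for the `flag` column.
#' @return data.frame with columns `pc`, `p_value`, `flag`.
#' @export
pc_batch_association <- function(scores, samples, k = 10, alpha = 0.01) {
  sheet <- .align_sheet(samples, rownames(scores))
  batch <- factor(sheet$batch)
  if (k > ncol(scores)) {
    warning("only ", ncol(scores), " components available; truncating k")
    k <- ncol(scores)
  }
  p <- vapply(seq_len(k), function(i) {
    s <- scores[, i]
    if (nlevels(batch) == 2) {
      g <- split(s, batch)
      stats::wilcox.test(g[[1]], g[[2]])$p.value
    } else {
      stats::kruskal.test(s, batch)$p.value
    }
  }, 0)
  data.frame(pc = seq_len(k), p_value = p, flag = p < alpha)
}

#' Per-CpG one-way ANOVA
#'
#' Fixed-effects one-way F-test of each CpG against a categorical factor
#' (batch, or a biological outcome), vectorized over CpGs. A CpG with no
#' between-group difference and no within-group variance gets p = 1.
#'
#' @param beta numeric beta matrix (probes x samples).
#' @param fac per-sample factor (coerced), one level per group; every
#'   level needs at least 2 samples.
#' @return named vector of p-values, one per CpG (`NA` where the CpG has
#'   missing values).
#' @export
per_cpg_anova <- function(beta, fac) {
  fac <- factor(fac)
  if (length(fac) != ncol(beta))
    stop("factor length must equal the number of samples")
  kl <- nlevels(fac)
  if (kl < 2) stop("need at least 2 groups")
  nn <- table(fac)
  if (any(nn < 2))
    stop("every group needs at least 2 samples: ",
         paste(names(nn)[nn < 2], collapse = ", "))
  ok <- rowSums(is.na(beta)) == 0
  Y <- beta[ok, , drop = FALSE]
  N <- ncol(Y)
  grand <- rowMeans(Y)
  gm <- t(rowsum(t(Y), fac) / as.numeric(nn))     # probes x groups
  ssb <- as.numeric((gm - grand)^2 %*% as.numeric(nn))
  sst <- rowSums((Y - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- kl - 1
  df2 <- N - kl
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[ssb <= .Machine$double.eps & ssw <= .Machine$double.eps] <- 1
  p[ssw <= .Machine$double.eps & ssb > .Machine$double.eps] <- 0
  out <- rep(NA_real_, nrow(beta))
  names(out) <- rownames(beta)
  out[ok] <- p
  out
}

#' Count significant p-values
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha threshold; significance is strict (`p < alpha`).
#' @return list with `count` and `fraction` (of non-missing p-values).
#' @export
count_significant <- function(pvalues, alpha = 0.01) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) == 0) stop("no p-values to count")
  if (min(pvalues) < 0 || max(pvalues) > 1)
    stop("p-values must lie in [0, 1]")
  n <- sum(pvalues < alpha)
  list(count = n, fraction = n / length(pvalues))
}

#' Technical-replicate error metrics
#'
#' For each replicate pair, computes per-CpG differences (first member
#' minus second, in sample-sheet order) and summarizes them by the mean
#' error and the average absolute deviation from zero (sum of absolute
#' differences divided by the number of CpGs). Both should be near zero
#' for a clean assay; the mean captures systematic shift, the absolute
#' deviation captures spread. Replicate groups larger than 2 are
#' expanded into all pairs.
#'
#' @param beta numeric beta matrix (probes x samples).
#' @param samples a [sample_sheet()] with a `replicate_group` column.
#' @return data.frame of class `ReplicateErrorSummary` with one row per
#'   pair: `replicate_group`, `sample_1`, `sample_2`, `n_cpgs`,
#'   `mean_error`, `avg_abs_deviation`.
#' @export
replicate_errors <- function(beta, samples) {
  stopifnot(inherits(samples, "SampleSheet"))
  if (!"replicate_group" %in% names(samples) ||
      all(is.na(samples$replicate_group))) {
    warning("sample sheet has no replicate groups")
    return(structure(
      data.frame(replicate_group = character(), sample_1 = character(),
                 sample_2 = character(), n_cpgs = integer(),
                 mean_error = numeric(), avg_abs_deviation = numeric()),
      class = c("ReplicateErrorSummary", "data.frame")))
  }
  sheet <- samples[!is.na(samples$replicate_group), , drop = FALSE]
  sheet <- sheet[sheet$sample_id %in% colnames(beta), , drop = FALSE]
  rows <- list()
  for (grp in unique(sheet$replicate_group)) {
    ids <- sheet$sample_id[sheet$replicate_group == grp]
    if (length(ids) < 2) next
    if (length(ids) > 2)
      warning("replicate group '", grp, "' has ", length(ids),
              " members; using all pairs")
    for (pair in utils::combn(ids, 2, simplify = FALSE)) {
      d <- beta[, pair[1]] - beta[, pair[2]]
      d <- d[!is.na(d)]
      rows[[length(rows) + 1]] <- data.frame(
        replicate_group = grp, sample_1 = pair[1], sample_2 = pair[2],
        n_cpgs = length(d), mean_error = mean(d),
        avg_abs_deviation = sum(abs(d)) / length(d),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("ReplicateErrorSummary", "data.frame"))
}

#' Hierarchical clustering of samples versus batch labels
#'
#' Clusters samples on 1 minus the Pearson correlation of their CpG
#' profiles with average linkage, cuts the tree at the number of
#' batches, and quantifies agreement between the resulting clusters and
#' the batch labels with the adjusted Rand index (1 = clusters reproduce
#' the chips exactly, ~0 = no association).
#'
#' @param beta numeric beta matrix (probes x samples, >= 3 samples).
#' @param samples a [sample_sheet()].
#' @return list with `hclust` (the tree), `clusters` (cut at k =
#'   number of batches) and `concordance` (adjusted Rand index).
#' @export
hcluster_batch <- function(beta, samples) {
  if (ncol(beta) < 3) stop("clustering needs at least 3 samples")
  sheet <- .align_sheet(samples, colnames(beta))
  sds <- apply(beta, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds)))
    stop("zero-variance sample column(s): ",
         paste(colnames(beta)[sds == 0 | is.na(sds)], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(beta, use = "pairwise.complete.obs"))
  tree <- stats::hclust(d, method = "average")
  k <- length(unique(sheet$batch))
  cl <- stats::cutree(tree, k = max(k, 1))
  ari <- mclust::adjustedRandIndex(cl, sheet$batch)
  list(hclust = tree, clusters = cl, concordance = ari)
}

#' Per-sample M-A deviation curves
#'
#' For each CpG, the abscissa is the mean beta across samples and each
#' sample's ordinate is its deviation from that mean. A robust locally
#' weighted smoother (lowess) is fitted per sample and evaluated on a
#' common grid; a flat curve at zero indicates no intensity-dependent
#' bias, a curved one the kind of nonlinear chip bias that motivates
#' signal-level normalization.
#'
#' @param beta numeric beta matrix (probes x samples, >= 3 samples).
#' @param span lowess smoother span in (0, 1].
#' @param robust_iters number of robustifying iterations.
#' @param grid_size number of evaluation points.
#' @return list with `grid` (abscissa) and `curves` (grid x samples
#'   matrix of fitted deviations).
#' @export
ma_lowess <- function(beta, span = 2 / 3, robust_iters = 3,
                      grid_size = 100) {
  if (ncol(beta) < 3) stop("M-A curves need at least 3 samples")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  ok <- rowSums(is.na(beta)) == 0
  Y <- beta[ok, , drop = FALSE]
  a <- rowMeans(Y)
  grid <- seq(min(a), max(a), length.out = grid_size)
  curves <- vapply(seq_len(ncol(Y)), function(j) {
    fit <- stats::lowess(a, Y[, j] - a, f = span, iter = robust_iters)
    stats::approx(fit$x, fit$y, xout = grid, rule = 2, ties = mean)$y
  }, numeric(grid_size))
  colnames(curves) <- colnames(Y)
  list(grid = grid, curves = curves)
}

#' Evaluate differential-methylation p-values on control panels
#'
#' Given per-CpG p-values from a differential test and two disjoint probe
#' panels — positives expected to be truly differential (e.g. genes
#' hypermethylated in tumors) and negatives expected null (housekeeping
#' genes) — counts significant probes in each at `alpha`, reports the
#' expected false-positive count `round(alpha * n_negatives)`, and runs
#' a Kolmogorov-Smirnov uniformity check on the negative-panel p-values.
#' A well-behaved normalization leaves the negative panel at its nominal
#' type I error.
#'
#' @param pvalues named vector of p-values (names = probe ids).
#' @param positive_ids,negative_ids disjoint probe id sets, present in
#'   `pvalues`.
#' @param alpha significance threshold.
#' @return list with `n_significant_positive`, `n_significant_negative`,
#'   `expected_false_positives`, `ks_statistic`, `ks_p_value`.
#' @export
control_panel_eval <- function(pvalues, positive_ids, negative_ids,
                               alpha = 0.05) {
  if (length(intersect(positive_ids, negative_ids)))
    stop("positive and negative panels must be disjoint")
  miss <- setdiff(c(positive_ids, negative_ids), names(pvalues))
  if (length(miss))
    stop("panel probes absent from p-values: ",
         paste(utils::head(miss, 5), collapse = ", "))
  pp <- pvalues[positive_ids]
  np <- pvalues[negative_ids]
  ks <- suppressWarnings(stats::ks.test(np, "punif"))
  list(n_significant_positive = sum(pp < alpha, na.rm = TRUE),
       n_significant_negative = sum(np < alpha, na.rm = TRUE),
       expected_false_positives = round(alpha * length(negative_ids)),
       ks_statistic = unname(ks$statistic),
       ks_p_value = ks$p.value)
}

#' Full batch-effect report for one beta matrix
#'
#' Computes the quantitative batch diagnostics in one pass: per-sample
#' beta quantiles, cluster/batch concordance, PCA variance fractions,
#' batch association of the leading components, and the fraction of CpGs
#' whose per-CpG ANOVA against batch is significant.
#'
#' @param beta numeric beta matrix (probes x samples).
#' @param samples a [sample_sheet()].
#' @param alpha per-CpG and per-PC significance threshold.
#' @param k_pcs number of leading components to test.
#' @param cluster include the hierarchical-clustering concordance
#'   (requires >= 3 samples and no zero-variance sample).
#' @return object of class `batch_report`.
#' @export
batch_report <- function(beta, samples, alpha = 0.01, k_pcs = 10,
                         cluster = TRUE) {
  sheet <- .align_sheet(samples, colnames(beta))
  pc <- beta_pca(beta)
  assoc <- pc_batch_association(pc$scores, samples, k = k_pcs,
                                alpha = alpha)
  pv <- per_cpg_anova(beta, sheet$batch)
  sig <- count_significant(pv, alpha = alpha)
  conc <- if (cluster) hcluster_batch(beta, samples)$concordance
          else NA_real_
  structure(list(
    per_sample_quantiles = qc_summary(beta),
    cluster_batch_concordance = conc,
    pc_scores = pc$scores,
    pc_variance_fractions = pc$variance_fractions,
    pc_batch = assoc,
    batch_p_values = pv,
    batch_cpg_count = sig$count,
    batch_cpg_fraction = sig$fraction,
    alpha = alpha
  ), class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("batch_report (alpha = %g)\n", x$alpha))
  cat(sprintf("  CpGs associated with batch: %d (%.1f%%)\n",
              x$batch_cpg_count, 100 * x$batch_cpg_fraction))
  sig_pcs <- x$pc_batch$pc[x$pc_batch$flag]
  cat(sprintf("  PCs associated with batch:  %s\n",
              if (length(sig_pcs)) paste(sig_pcs, collapse = ", ")
              else "none"))
  if (length(sig_pcs))
    cat(sprintf("  variance explained by them: %s\n",
                paste(sprintf("%.1f%%",
                              100 * x$pc_variance_fractions[sig_pcs]),
                      collapse = ", ")))
  if (!is.na(x$cluster_batch_concordance))
    cat(sprintf("  cluster/batch concordance (ARI): %.3f\n",
                x$cluster_batch_concordance))
  invisible(x)
}
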