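test_that("beta_pca decomposes the probe-centered matrix", {
  set.seed(1)
  b <- rand_beta(50, 10)
  pc <- beta_pca(b)
  expect_equal(sum(pc$variance_fractions), 1, tolerance = 1e-9)
  # scores are uncorrelated across components
  cv <- crossprod(scale(pc$scores, center = TRUE, scale = FALSE))
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-9)
  # agree with a direct eigendecomposition of the sample covariance
  ev <- eigen(stats::cov(t(b - rowMeans(b))), symmetric = TRUE)$values
  nv <- ncol(pc$scores)
  expect_equal(pc$variance_fractions[seq_len(nv)] * sum(pmax(ev, 0)),
               ev[seq_len(nv)], tolerance = 1e-9, ignore_attr = TRUE)
  # three samples on a line in probe space: PC1 carries everything
  base <- runif(50, 0.2, 0.8)
  dirn <- runif(50, -0.1, 0.1)
  line <- cbind(s1 = base - dirn, s2 = base, s3 = base + dirn)
  rownames(line) <- rownames(b)
  expect_equal(beta_pca(line)$variance_fractions[1], 1,
               tolerance = 1e-9)
  # constant matrix has no variance
  flat <- matrix(0.5, 10, 4,
                 dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  expect_error(beta_pca(flat), "variance")
})

test_that("PC-batch association reproduces exact rank-sum p-values", {
  scores <- cbind(PC1 = c(1, 2, 3, 4, 5, 6),
                  PC2 = c(1, 4, 5, 8, 2, 3),
                  PC3 = c(2, 3, 6, 7, 1, 8))
  rownames(scores) <- paste0("s", 1:6)
  sheet <- sample_sheet(data.frame(
    sample_id = rownames(scores),
    batch = rep(c("a", "b"), each = 3)))
  expect_warning(res <- pc_batch_association(scores, sheet, k = 10),
                 "truncating")
  # complete separation: the most extreme 2 of C(6,3)=20 splits
  expect_equal(res$p_value[1], 0.1)
  expect_true(res$flag[1] == (0.1 < 0.01))
  # enumeration oracle on the other columns
  for (j in 2:3)
    expect_equal(res$p_value[j],
                 wilcox_oracle(scores[1:3, j], scores[4:6, j]))
  # rank-balanced scores: p = 1 under the exact test
  bal <- cbind(PC1 = c(1, 4, 5, 8, 2, 3, 6, 7))
  rownames(bal) <- paste0("s", 1:8)
  sheet8 <- sample_sheet(data.frame(sample_id = rownames(bal),
                                    batch = rep(c("a", "b"), each = 4)))
  expect_equal(pc_batch_association(bal, sheet8, k = 1)$p_value, 1)
})

test_that("wilcoxon agrees with exhaustive enumeration up to n = 12", {
  set.seed(2)
  sizes <- list(c(3, 3), c(4, 4), c(5, 5), c(6, 6), c(4, 8), c(2, 6))
  for (sz in sizes) {
    x <- sample(100, sz[1]); y <- sample(200, sz[2]) + 0.5
    p_pkg <- stats::wilcox.test(x, y)$p.value
    expect_equal(p_pkg, wilcox_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("more than two batches fall back to Kruskal-Wallis", {
  set.seed(3)
  scores <- cbind(PC1 = rnorm(12))
  rownames(scores) <- paste0("s", 1:12)
  sheet <- sample_sheet(data.frame(sample_id = rownames(scores),
                                   batch = rep(c("a", "b", "c"), 4)))
  res <- pc_batch_association(scores, sheet, k = 1)
  expect_equal(res$p_value,
               stats::kruskal.test(scores[, 1],
                                   factor(sheet$batch))$p.value)
})

test_that("null PC-batch flags fire at about the nominal rate", {
  set.seed(4)
  sheet <- two_chip_sheet(paste0("s", 1:24))
  flags <- replicate(200, {
    sc <- cbind(PC1 = rnorm(24))
    rownames(sc) <- sheet$sample_id
    pc_batch_association(sc, sheet, k = 1)$flag
  })
  expect_lte(mean(flags), 0.04)  # nominal 0.01
})

test_that("per-CpG ANOVA matches first-principles sums of squares", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  oracle <- anova_oracle(g)
  expect_equal(oracle$f, 3)  # SSB = 6 on 2 df, SSW = 6 on 6 df
  b <- matrix(unlist(g) / 10, 1, 9,
              dimnames = list("cg01", paste0("s", 1:9)))
  p <- per_cpg_anova(b, rep(c("a", "b", "c"), each = 3))
  expect_equal(unname(p), oracle$p, tolerance = 1e-12)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(5)
  b <- rand_beta(30, 10)
  fac <- rep(c("x", "y"), each = 5)
  p <- per_cpg_anova(b, fac)
  for (i in sample(30, 5)) {
    tt <- stats::t.test(b[i, 1:5], b[i, 6:10], var.equal = TRUE)
    expect_equal(unname(p[i]), tt$p.value, tolerance = 1e-9)
  }
  # identical groups: F = 0, p = 1
  flat <- matrix(rep(c(0.1, 0.2), 2), 1, 4,
                 dimnames = list("cg01", paste0("s", 1:4)))
  expect_equal(unname(per_cpg_anova(flat, c("a", "a", "b", "b"))), 1)
  expect_error(per_cpg_anova(b, rep(c("x", "y", "z"), c(8, 1, 1))),
               "at least 2 samples")
})

test_that("ANOVA p-values are uniform under a simulated global null", {
  set.seed(6)
  b <- matrix(rnorm(10000 * 12, 0.5, 0.02), 10000, 12,
              dimnames = list(sprintf("cg%05d", 1:10000),
                              paste0("s", 1:12)))
  p <- per_cpg_anova(b, rep(c("a", "b"), each = 6))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("count_significant uses a strict threshold", {
  res <- count_significant(c(0.005, 0.02, 0.5), 0.01)
  expect_equal(res$count, 1)
  expect_equal(res$fraction, 1 / 3)
  expect_error(count_significant(numeric(0)), "no p-values")
  expect_error(count_significant(c(0.5, 1.2)), "0, 1")
  set.seed(7)
  expect_lt(abs(count_significant(runif(10000), 0.01)$fraction - 0.01),
            0.004)
})

test_that("replicate errors capture shift, spread and orientation", {
  b <- rand_beta(100, 2, seed = 8)
  colnames(b) <- c("r1", "r2")
  sheet <- sample_sheet(data.frame(sample_id = c("r1", "r2"),
                                   batch = "chip1",
                                   replicate_group = "rep1"))
  # identical replicates
  ident <- b; ident[, 2] <- ident[, 1]
  res <- replicate_errors(ident, sheet)
  expect_equal(res$mean_error, 0)
  expect_equal(res$avg_abs_deviation, 0)
  # constant shift c: mean = -c with this orientation, AAD = |c|
  shifted <- b; shifted[, 2] <- shifted[, 1] + 0.05
  res2 <- replicate_errors(shifted, sheet)
  expect_equal(res2$mean_error, -0.05)
  expect_equal(res2$avg_abs_deviation, 0.05)
  # swapped orientation flips the sign of the mean only
  sheet_sw <- sample_sheet(data.frame(sample_id = c("r2", "r1"),
                                      batch = "chip1",
                                      replicate_group = "rep1"))
  res3 <- replicate_errors(shifted, sheet_sw)
  expect_equal(res3$mean_error, 0.05)
  expect_equal(res3$avg_abs_deviation, 0.05)
  # cancellation: differences +0.1 / -0.1 over 2 CpGs
  two <- matrix(c(0.5, 0.5, 0.4, 0.6), 2, 2,
                dimnames = list(c("cg1", "cg2"), c("r1", "r2")))
  res4 <- replicate_errors(two, sheet)
  expect_equal(res4$mean_error, 0)
  expect_equal(res4$avg_abs_deviation, 0.1)
  # probe order invariance and AAD >= |mean|
  perm <- sample(nrow(b))
  res5 <- replicate_errors(shifted[perm, ], sheet)
  expect_equal(res5$avg_abs_deviation, res2$avg_abs_deviation)
  expect_gte(res2$avg_abs_deviation, abs(res2$mean_error))
  # no replicates: empty summary with warning
  lone <- sample_sheet(data.frame(sample_id = c("r1", "r2"),
                                  batch = "chip1"))
  expect_warning(res6 <- replicate_errors(b, lone), "no replicate")
  expect_equal(nrow(res6), 0)
})

test_that("average-linkage clustering matches a brute-force oracle", {
  set.seed(9)
  b <- rand_beta(30, 4)
  b[, 2] <- 0.8 * b[, 1] + 0.2 * b[, 2]  # correlate s1/s2
  sheet <- two_chip_sheet(colnames(b))
  res <- hcluster_batch(b, sheet)
  d <- stats::as.dist(1 - stats::cor(b))
  expect_equal(sort(res$hclust$height), sort(avg_linkage_oracle(d)),
               tolerance = 1e-12)
})

test_that("cluster-batch concordance is 1 for duplicated groups", {
  b <- rand_beta(40, 2, seed = 10)
  noise <- function(x) x + rnorm(length(x), 0, 0.001)
  mat <- cbind(a1 = noise(b[, 1]), a2 = noise(b[, 1]),
               a3 = noise(b[, 1]), b1 = noise(b[, 2]),
               b2 = noise(b[, 2]), b3 = noise(b[, 2]))
  rownames(mat) <- rownames(b)
  sheet <- sample_sheet(data.frame(sample_id = colnames(mat),
                                   batch = rep(c("c1", "c2"), each = 3)))
  expect_equal(hcluster_batch(mat, sheet)$concordance, 1)
  # zero-variance sample is rejected by name
  mat[, 2] <- 0.5
  expect_error(hcluster_batch(mat, sheet), "a2")
})

test_that("random batch labels give near-zero concordance on average", {
  set.seed(11)
  aris <- replicate(50, {
    b <- matrix(runif(20 * 8, 0.05, 0.95), 20, 8,
                dimnames = list(paste0("p", 1:20), paste0("s", 1:8)))
    sheet <- sample_sheet(data.frame(
      sample_id = colnames(b),
      batch = sample(rep(c("x", "y"), 4))))
    hcluster_batch(b, sheet)$concordance
  })
  expect_lt(abs(mean(aris)), 0.1)
})

test_that("M-A curves recover flat, offset and linear biases", {
  set.seed(12)
  base <- sort(runif(200, 0.1, 0.9))
  ident <- matrix(base, 200, 3,
                  dimnames = list(sprintf("p%03d", 1:200),
                                  paste0("s", 1:3)))
  res <- ma_lowess(ident)
  expect_lt(max(abs(res$curves)), 1e-12)
  # sample 1 offset by +0.02, means corrected to keep the abscissa fixed
  off <- ident
  off[, 1] <- base + 0.03
  off[, 2] <- base - 0.015
  off[, 3] <- base - 0.015
  res2 <- ma_lowess(off)
  expect_lt(max(abs(res2$curves[, 1] - 0.03)), 1e-6)
  # linear intensity-dependent bias
  lin <- ident
  lin[, 1] <- base + 0.1 * (base - 0.5)
  lin[, 2] <- base - 0.05 * (base - 0.5)
  lin[, 3] <- base - 0.05 * (base - 0.5)
  res3 <- ma_lowess(lin)
  interior <- res3$grid > 0.2 & res3$grid < 0.8
  expect_lt(max(abs(res3$curves[interior, 1] -
                      0.1 * (res3$grid[interior] - 0.5))), 0.005)
  expect_error(ma_lowess(ident, span = 0), "span")
})

test_that("control panels report significance counts and uniformity", {
  set.seed(13)
  p <- c(stats::runif(358), rep(1e-6, 85))
  names(p) <- sprintf("cg%04d", seq_along(p))
  neg <- names(p)[1:358]
  pos <- names(p)[359:443]
  res <- control_panel_eval(p, pos, neg, alpha = 0.05)
  expect_equal(res$expected_false_positives, 18)
  expect_equal(res$n_significant_positive, 85)
  expect_lte(res$n_significant_negative,
             res$expected_false_positives +
               2 * sqrt(res$expected_false_positives))
  expect_lt(res$ks_statistic, 0.1)
  expect_error(control_panel_eval(p, pos, c(pos[1], neg)), "disjoint")
  expect_error(control_panel_eval(p, c(pos, "cg9999"), neg), "absent")
})

test_that("batch_report assembles the full metric set coherently", {
  d <- simulate_methylation(sim_regime("shift", seed = 14, n_cpgs = 300))
  rep <- batch_report(d$beta, d$samples, alpha = 0.01, k_pcs = 5)
  expect_equal(sum(rep$pc_variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(rep$pc_variance_fractions >= 0 &
                    rep$pc_variance_fractions <= 1))
  expect_true(rep$pc_batch$flag[1])       # strong shift loads on PC1
  expect_gt(rep$batch_cpg_fraction, 0.5)  # and most CpGs are affected
  expect_equal(rep$batch_cpg_count,
               count_significant(
                 per_cpg_anova(d$beta, d$samples$batch), 0.01)$count)
  expect_output(print(rep), "CpGs associated with batch")
})
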