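# Independent brute-force oracles, deliberately coded differently from
# the package implementations they check.

# Quantile normalization by literal sort/average: reference is the mean
# of the column-sorted values; each entry receives the mean of the
# reference values at the positions its value occupies in its sorted
# column (ties averaged). Complete matrices only.
qn_oracle <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    sv <- sort(v)
    for (i in seq_along(v)) {
      out[i, j] <- mean(ref[which(sv == v[i])])
    }
  }
  out
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every split
# of the combined ranks (tie-free inputs).
wilcox_oracle <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ws <- utils::combn(n, n1, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# One-way ANOVA p-value from first-principles sums of squares.
anova_oracle <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Brute-force agglomerative average-linkage clustering: returns the
# sequence of merge heights.
avg_linkage_oracle <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- mean(d[clusters[[a]], clusters[[b]]])
        if (h < best_h) {
          best_h <- h
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Small labeled beta matrix with values away from the [0,1) edges.
rand_beta <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(n * m, 0.05, 0.95), n, m,
         dimnames = list(sprintf("cg%05d", seq_len(n)),
                         sprintf("s%02d", seq_len(m))))
}

# Two-chip sample sheet for a labeled matrix.
two_chip_sheet <- function(ids, outcome = NULL) {
  n <- length(ids)
  half <- ceiling(n / 2)
  df <- data.frame(sample_id = ids,
                   batch = rep(c("chip1", "chip2"),
                               c(half, n - half)),
                   stringsAsFactors = FALSE)
  if (!is.null(outcome)) df$outcome <- outcome
  sample_sheet(df)
}
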