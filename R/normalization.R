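#' Quantile normalization with explicit tie handling
#'
#' Forces every column (sample) of a matrix onto a common reference
#' distribution. The reference is the per-rank mean of the column-sorted
#' values; each entry is then replaced by the reference value at its
#' within-column rank. Columns with missing entries are ranked over their
#' non-missing values against a reference linearly interpolated to that
#' length, and contribute to the reference through the same
#' interpolation.
#'
#' Two tie policies are offered. `average_ties` (default) gives tied
#' entries the mean of the reference values spanning their rank range,
#' which keeps tied inputs tied on output — important for beta matrices,
#' which pile up near 0 and 1. `sorted_assign` distributes the sorted
#' reference over tied entries in order of appearance, reproducing the
#' classic sort/assign algorithm bit for bit.
#'
#' @param x numeric matrix with at least 2 columns.
#' @param tie_policy `"average_ties"` or `"sorted_assign"`.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x, tie_policy = c("average_ties",
                                                 "sorted_assign")) {
  tie_policy <- match.arg(tie_policy)
  if (!is.matrix(x) || !is.numeric(x))
    stop("x must be a numeric matrix")
  if (ncol(x) < 2)
    stop("quantile normalization needs at least 2 columns")
  n <- nrow(x)
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0))
    stop("column has no non-missing values: ",
         paste(colnames(x)[n_obs == 0], collapse = ", "))

  grid_n <- seq(0, 1, length.out = n)
  contrib <- vapply(seq_len(ncol(x)), function(j) {
    v <- sort(x[, j], na.last = NA)
    if (length(v) == n) v
    else stats::approx(seq(0, 1, length.out = length(v)), v, grid_n,
                       rule = 2)$y
  }, numeric(n))
  ref <- rowMeans(contrib)

  out <- x
  for (j in seq_len(ncol(x))) {
    obs <- which(!is.na(x[, j]))
    m <- length(obs)
    refm <- if (m == n) ref
            else stats::approx(grid_n, ref,
                               seq(0, 1, length.out = max(m, 2)),
                               rule = 2)$y[seq_len(m)]
    v <- x[obs, j]
    if (tie_policy == "sorted_assign") {
      out[obs[order(v)], j] <- refm
    } else {
      rmin <- rank(v, ties.method = "min")
      rmax <- rank(v, ties.method = "max")
      cs <- cumsum(refm)
      out[obs, j] <- (cs[rmax] - c(0, cs)[rmin]) / (rmax - rmin + 1)
    }
  }
  out
}

#' Quantile-normalize beta values directly
#'
#' Applies [quantile_normalize()] to the beta matrix itself, making every
#' sample's beta distribution identical. This is the most aggressive of
#' the three strategies: it equalizes distributions regardless of where
#' the difference comes from, and is effective when batch effects are
#' severe and the samples are biologically comparable.
#'
#' @param beta numeric beta matrix (probes x samples), values in `[0, 1)`.
#' @inheritParams quantile_normalize
#' @return normalized beta matrix.
#' @export
qn_beta <- function(beta, tie_policy = "average_ties") {
  validate_beta(beta)
  quantile_normalize(beta, tie_policy = tie_policy)
}

#' Separate A/B signal quantile normalization
#'
#' Quantile-normalizes the unmethylated (A) and methylated (B) signal
#' matrices independently across samples, then recomputes average beta
#' from the normalized signals with [compute_beta()]. Operating on
#' signals corrects intensity bias at its source, before the nonlinear
#' transform to beta.
#'
#' @param signals a [signal_matrix()].
#' @param offset beta regularizer, as in [compute_beta()].
#' @inheritParams quantile_normalize
#' @return list with `beta` (recomputed beta matrix) and `signals`
#'   (normalized [signal_matrix()]).
#' @export
abnorm <- function(signals, offset = 100, tie_policy = "average_ties") {
  stopifnot(inherits(signals, "SignalMatrix"))
  An <- quantile_normalize(signals$A, tie_policy = tie_policy)
  Bn <- quantile_normalize(signals$B, tie_policy = tie_policy)
  sn <- signal_matrix(An, Bn)
  list(beta = compute_beta(sn, offset = offset), signals = sn)
}

# Monotone quantile mapping of each color channel's intensities onto the
# sample's pooled (combined-channel) distribution. x is the pooled
# per-sample intensity vector (A stacked over B), channel the matching
# channel labels; probes with unknown channel are left untouched.
.adjust_channels <- function(x, channel) {
  obs <- !is.na(x)
  combined <- sort(x[obs])
  M <- length(combined)
  if (M < 2) return(x)
  probs <- (seq_len(M) - 0.5) / M
  for (ch in c("red", "green")) {
    sel <- which(obs & channel == ch)
    m <- length(sel)
    if (m == 0) next
    r <- rank(x[sel], ties.method = "average")
    x[sel] <- stats::approx(probs, combined, xout = (r - 0.5) / m,
                            rule = 2)$y
  }
  x
}

#' Two-step signal normalization with color-channel adjustment
#'
#' Per-sample color bias is removed first: the probe intensities of each
#' dye channel (red, green) are mapped by monotone quantile mapping onto
#' the sample's pooled combined-channel distribution, using the pooled A
#' and B intensities of that sample. The adjusted A and B matrices are
#' then stacked into a single (2 x probes) x samples matrix and
#' quantile-normalized across samples, and average beta is recomputed
#' from the result.
#'
#' Probes with `unknown` channel are included in the pooled distribution
#' but are not themselves adjusted; when no probe has a known channel the
#' color step is skipped entirely with a warning.
#'
#' @param signals a [signal_matrix()].
#' @param annotation a [probe_annotation()] providing `color_channel`.
#' @param offset beta regularizer, as in [compute_beta()].
#' @inheritParams quantile_normalize
#' @return list with `beta` and normalized `signals`.
#' @export
lumi_norm <- function(signals, annotation, offset = 100,
                      tie_policy = "average_ties") {
  stopifnot(inherits(signals, "SignalMatrix"),
            inherits(annotation, "ProbeAnnotation"))
  probes <- rownames(signals$A)
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx))
    stop("probes missing from annotation: ",
         paste(utils::head(probes[is.na(idx)], 5), collapse = ", "))
  channel <- annotation$color_channel[idx]
  n <- length(probes)
  stacked <- rbind(signals$A, signals$B)
  if (all(channel == "unknown")) {
    warning("no probe has a known color channel; skipping color adjustment")
  } else {
    chan2 <- rep(channel, 2)
    for (j in seq_len(ncol(stacked)))
      stacked[, j] <- .adjust_channels(stacked[, j], chan2)
  }
  stacked <- quantile_normalize(stacked, tie_policy = tie_policy)
  sn <- signal_matrix(stacked[seq_len(n), , drop = FALSE],
                      stacked[n + seq_len(n), , drop = FALSE])
  list(beta = compute_beta(sn, offset = offset), signals = sn)
}

#' Apply one of the normalization strategies by name
#'
#' Dispatch helper used by the pipeline: `"qn-beta"` normalizes the beta
#' matrix directly, `"abnorm"` and `"lumi"` normalize signals and
#' recompute beta, `"none"` passes the beta matrix through unchanged.
#'
#' @param method one of `"qn-beta"`, `"abnorm"`, `"lumi"`, `"none"`.
#' @param beta beta matrix (required for `"qn-beta"` and `"none"`).
#' @param signals [signal_matrix()] (required for `"abnorm"`/`"lumi"`).
#' @param annotation [probe_annotation()] (required for `"lumi"`).
#' @param offset beta regularizer.
#' @return normalized beta matrix.
#' @export
normalize_beta <- function(method = c("qn-beta", "abnorm", "lumi", "none"),
                           beta = NULL, signals = NULL, annotation = NULL,
                           offset = 100) {
  method <- match.arg(method)
  switch(method,
    "none" = {
      if (is.null(beta)) stop("method 'none' needs a beta matrix")
      beta
    },
    "qn-beta" = {
      if (is.null(beta)) stop("method 'qn-beta' needs a beta matrix")
      qn_beta(beta)
    },
    "abnorm" = {
      if (is.null(signals)) stop("method 'abnorm' needs signals")
      abnorm(signals, offset = offset)$beta
    },
    "lumi" = {
      if (is.null(signals) || is.null(annotation))
        stop("method 'lumi' needs signals and a probe annotation")
      lumi_norm(signals, annotation, offset = offset)$beta
    })
}
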