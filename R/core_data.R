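#' methbatch: normalization and empirical Bayes batch correction for
#' Infinium methylation arrays
#'
#' Beta-value and signal-level quantile normalization, covariate-aware
#' empirical Bayes batch adjustment, quantitative batch diagnostics, and a
#' synthetic two-signal array generator.
#'
#' Matrices are always probe-major: rows are CpG probes, columns are
#' samples, with dimnames carrying probe and sample identifiers.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a paired signal matrix object
#'
#' Bundles the unmethylated (A) and methylated (B) fluorescence intensity
#' matrices of an Infinium-style assay. Both matrices must share shape and
#' dimnames (rows = probes, columns = samples). Intensities are
#' non-negative; missing measurements are `NA`, never sentinel values.
#'
#' @param A numeric matrix of unmethylated-allele intensities.
#' @param B numeric matrix of methylated-allele intensities, same shape
#'   and dimnames as `A`.
#' @return An object of class `SignalMatrix`: a list with elements `A`
#'   and `B`.
#' @export
signal_matrix <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (!identical(dim(A), dim(B)))
    stop("A and B must have identical dimensions")
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("A must have probe rownames and sample colnames")
  if (!identical(dimnames(A), dimnames(B)))
    stop("A and B must have identical dimnames")
  if (anyDuplicated(rownames(A)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(A)[duplicated(rownames(A))]), collapse = ", "))
  if (anyDuplicated(colnames(A)))
    stop("duplicate sample ids")
  .check_nonnegative(A, "A")
  .check_nonnegative(B, "B")
  structure(list(A = A, B = B), class = "SignalMatrix")
}

.check_nonnegative <- function(m, what) {
  bad <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "negative %s signal at probe '%s', sample '%s'", what,
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  invisible(TRUE)
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat(sprintf("SignalMatrix: %d probes x %d samples\n",
              nrow(x$A), ncol(x$A)))
  invisible(x)
}

#' @export
dim.SignalMatrix <- function(x) dim(x$A)

#' Compute average beta values from paired probe signals
#'
#' The average beta of a CpG is the methylated signal as a fraction of
#' total signal, regularized by a positive offset in the denominator:
#' `beta = B / (A + B + offset)`. The default offset of 100 reproduces
#' the BeadStudio/GenomeStudio computation exactly. Output values lie in
#' `[0, 1)`; an entry is `NA` whenever either signal is missing.
#'
#' @param signals a [signal_matrix()] object.
#' @param offset positive regularizer added to the total intensity.
#' @return numeric matrix of beta values (probes x samples), with
#'   attribute `offset`.
#' @examples
#' sig <- signal_matrix(
#'   matrix(c(0, 100), 1, 2, dimnames = list("cg01", c("s1", "s2"))),
#'   matrix(c(900, 100), 1, 2, dimnames = list("cg01", c("s1", "s2"))))
#' compute_beta(sig)  # 0.9 and 1/3
#' @export
compute_beta <- function(signals, offset = 100) {
  stopifnot(inherits(signals, "SignalMatrix"))
  if (!is.numeric(offset) || length(offset) != 1 || is.na(offset) ||
      offset <= 0)
    stop("offset must be a single positive number")
  .check_nonnegative(signals$A, "A")
  .check_nonnegative(signals$B, "B")
  beta <- signals$B / (signals$A + signals$B + offset)
  attr(beta, "offset") <- offset
  beta
}

#' Validate a beta matrix
#'
#' Checks that a matrix of average beta values has unique probe and
#' sample labels and that all non-missing entries are within `[0, 1)`
#' (1 itself is unreachable under the offset formula; values equal to 1
#' are tolerated only when `allow_one = TRUE`, as clipped corrected data
#' may contain them).
#'
#' @param beta numeric matrix, probes x samples.
#' @param allow_one logical; accept entries equal to 1.
#' @return `beta`, invisibly.
#' @export
validate_beta <- function(beta, allow_one = FALSE) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("beta must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta)) || anyDuplicated(colnames(beta)))
    stop("beta labels must be unique")
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  v <- beta[!is.na(beta)]
  if (length(v) && (min(v) < 0 || max(v) > hi))
    stop("beta values must lie in [0, 1)")
  invisible(beta)
}

#' Construct and validate a probe annotation table
#'
#' @param probe_id character vector of unique CpG identifiers.
#' @param chromosome chromosome label per probe (`NA` allowed).
#' @param color_channel `"red"`, `"green"` or `"unknown"` per probe.
#' @return data.frame of class `ProbeAnnotation`.
#' @export
probe_annotation <- function(probe_id, chromosome = NA_character_,
                             color_channel = "unknown") {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id))
    stop("probe_id values must be unique")
  color_channel <- as.character(color_channel)
  ok <- color_channel %in% c("red", "green", "unknown")
  if (!all(ok))
    stop("color_channel must be one of red/green/unknown; got: ",
         paste(unique(color_channel[!ok]), collapse = ", "))
  ann <- data.frame(probe_id = probe_id,
                    chromosome = as.character(chromosome),
                    color_channel = color_channel,
                    stringsAsFactors = FALSE)
  class(ann) <- c("ProbeAnnotation", "data.frame")
  ann
}

# Chromosome labels compared case-insensitively with optional "chr"
# prefix stripped, so "chrX", "X" and "x" all match.
.norm_chrom <- function(x) {
  x <- tolower(as.character(x))
  sub("^chr", "", x)
}

#' Drop probes on excluded chromosomes
#'
#' Removes rows whose annotated chromosome is in `exclude_chromosomes`
#' (typically the sex chromosomes, to avoid male/female methylation
#' differences masquerading as signal). Comparison is case-insensitive
#' and ignores a `"chr"` prefix. Probes without a chromosome annotation
#' are retained. Row order of the survivors is preserved; the number of
#' rows removed is attached as attribute `removed`.
#'
#' @param x a beta matrix or [signal_matrix()].
#' @param annotation a [probe_annotation()] covering the probes of `x`.
#' @param exclude_chromosomes character vector of chromosome labels.
#' @return object of the same type as `x` with excluded rows dropped.
#' @export
filter_probes <- function(x, annotation, exclude_chromosomes = c("X", "Y")) {
  stopifnot(inherits(annotation, "ProbeAnnotation"))
  probes <- if (inherits(x, "SignalMatrix")) rownames(x$A) else rownames(x)
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx))
    stop("probes missing from annotation: ",
         paste(utils::head(probes[is.na(idx)], 5), collapse = ", "))
  chrom <- .norm_chrom(annotation$chromosome[idx])
  drop <- !is.na(chrom) & chrom %in% .norm_chrom(exclude_chromosomes)
  if (all(drop))
    stop("filter would exclude every probe")
  keep <- which(!drop)
  out <- if (inherits(x, "SignalMatrix")) {
    signal_matrix(x$A[keep, , drop = FALSE], x$B[keep, , drop = FALSE])
  } else {
    x[keep, , drop = FALSE]
  }
  attr(out, "removed") <- sum(drop)
  out
}

#' Per-sample quality-control summary
#'
#' For each sample reports the number of detected CpGs (detection
#' p-value below `detection_threshold`; all probes count as detected when
#' no detection matrix is supplied), the mean detection p-value, and the
#' five-number summary of the beta distribution.
#'
#' @param beta numeric beta matrix (probes x samples).
#' @param detection optional matrix of detection p-values, same shape and
#'   dimnames as `beta`.
#' @param detection_threshold detection p-value cutoff in (0, 1).
#' @return data.frame with one row per sample.
#' @export
qc_summary <- function(beta, detection = NULL, detection_threshold = 0.05) {
  validate_beta(beta, allow_one = TRUE)
  if (detection_threshold <= 0 || detection_threshold >= 1)
    stop("detection_threshold must be in (0, 1)")
  if (!is.null(detection)) {
    if (!identical(dim(detection), dim(beta)))
      stop("detection matrix shape must match beta")
    v <- detection[!is.na(detection)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("detection p-values must lie in [0, 1]")
  }
  qs <- t(apply(beta, 2, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE))
  colnames(qs) <- c("beta_min", "beta_q25", "beta_median", "beta_q75",
                    "beta_max")
  if (is.null(detection)) {
    detected <- colSums(!is.na(beta))
    mean_p <- rep(NA_real_, ncol(beta))
  } else {
    detected <- colSums(detection < detection_threshold, na.rm = TRUE)
    mean_p <- colMeans(detection, na.rm = TRUE)
  }
  data.frame(sample_id = colnames(beta),
             n_detected = as.integer(detected),
             mean_detection_p = mean_p,
             qs,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
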