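#' Configuration for the synthetic array generator
#'
#' Describes an Infinium-27k-like two-signal experiment: chips of up to
#' 12 samples, a bimodal baseline methylation distribution, log-normal
#' total intensities, chip-level batch biases (on the beta scale and/or
#' the signal scale), a binary outcome partially balanced across chips,
#' technical replicate pairs, and sex-chromosome probe annotation.
#'
#' Defaults emulate the structure of a real 27k study: 27,578 CpGs of
#' which 1,092 annotate to chromosome X or Y, two chips of 12 samples
#' with a 6/6 case-control split on each, a low/high bimodal beta
#' baseline, per-CpG beta noise of 0.02 between samples and 0.01 between
#' technical replicates (replicate standard deviations stay well under
#' 0.05), and no batch or outcome effect until one is requested.
#'
#' @param n_cpgs number of CpG probes.
#' @param batches named integer vector: samples per chip (<= 12 each).
#' @param outcome_balance named list, one `c(case =, control =)` pair
#'   per chip, summing to that chip's sample count.
#' @param baseline bimodal mixture: `weight_low`, and `low_shape` /
#'   `high_shape` Beta-distribution shape pairs (modes near 0.1 / 0.85).
#' @param intensity log-normal total-intensity model: `meanlog`,
#'   `sdlog` (per-probe affinity) and `sample_sdlog` (per-sample
#'   wobble).
#' @param beta_noise_sd per-CpG between-sample beta noise SD.
#' @param batch_effect named list, one entry per affected chip, each a
#'   list with any of `beta_shift` (additive shift on the beta scale),
#'   `add_a`, `add_b` (additive signal biases), `mult_a`, `mult_b`
#'   (multiplicative signal biases), `frac` (affected-CpG fraction,
#'   default 1) and `intensity_coef` (additive bias growing with total
#'   intensity). `NULL` = no batch effect.
#' @param outcome_effect list with `delta_beta` (absolute beta change in
#'   cases, random sign per CpG) and `frac` (affected-CpG fraction).
#' @param replicate_pairs number of technical replicate pairs.
#' @param replicate_noise_sd per-CpG beta noise SD between replicates.
#' @param chrXY_fraction fraction of probes annotated to chrX/chrY.
#' @param seed integer seed; mandatory, every draw derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cpgs = 27578,
                       batches = c(chip1 = 12, chip2 = 12),
                       outcome_balance = NULL,
                       baseline = list(weight_low = 0.6,
                                       low_shape = c(2, 10),
                                       high_shape = c(12, 3)),
                       intensity = list(meanlog = log(4000), sdlog = 0.3,
                                        sample_sdlog = 0.05),
                       beta_noise_sd = 0.02,
                       batch_effect = NULL,
                       outcome_effect = list(delta_beta = 0, frac = 0),
                       replicate_pairs = 0,
                       replicate_noise_sd = 0.01,
                       chrXY_fraction = 1092 / 27578,
                       seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducibility")
  if (is.null(names(batches)) || any(!nzchar(names(batches))))
    stop("batches must be a named vector of chip sizes")
  if (any(batches < 1) || any(batches > 12))
    stop("chips hold between 1 and 12 samples")
  if (is.null(outcome_balance)) {
    outcome_balance <- lapply(batches, function(n)
      c(case = floor(n / 2), control = ceiling(n / 2)))
  }
  if (!identical(sort(names(outcome_balance)), sort(names(batches))))
    stop("outcome_balance must name the same chips as batches")
  for (chip in names(batches)) {
    if (sum(outcome_balance[[chip]]) != batches[[chip]])
      stop("outcome_balance for ", chip,
           " does not sum to its sample count")
  }
  if (outcome_effect$frac < 0 || outcome_effect$frac > 1 ||
      chrXY_fraction < 0 || chrXY_fraction > 1)
    stop("fractions must lie in [0, 1]")
  structure(list(n_cpgs = n_cpgs, batches = batches,
                 outcome_balance = outcome_balance, baseline = baseline,
                 intensity = intensity, beta_noise_sd = beta_noise_sd,
                 batch_effect = batch_effect,
                 outcome_effect = outcome_effect,
                 replicate_pairs = replicate_pairs,
                 replicate_noise_sd = replicate_noise_sd,
                 chrXY_fraction = chrXY_fraction, seed = seed),
            class = "sim_config")
}

#' Preset simulation regimes
#'
#' Shorthand configurations spanning the spectrum seen in practice:
#' `"null"` (no batch effect), `"minor"` (a small shift on part of one
#' chip's CpGs), `"shift"` (a global additive beta shift on one chip,
#' the distribution-shift pattern), and `"scale"` (a multiplicative
#' methylated-signal compression on one chip, depressing the upper
#' quartile).
#'
#' @param regime one of `"null"`, `"minor"`, `"shift"`, `"scale"`.
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return a [sim_config()].
#' @export
sim_regime <- function(regime = c("null", "minor", "shift", "scale"),
                       seed, ...) {
  regime <- match.arg(regime)
  eff <- switch(regime,
    "null" = NULL,
    "minor" = list(chip2 = list(beta_shift = 0.02, frac = 0.3)),
    "shift" = list(chip2 = list(beta_shift = 0.1, frac = 1)),
    "scale" = list(chip2 = list(mult_b = 0.7, frac = 1)))
  sim_config(batch_effect = eff, seed = seed, ...)
}

.defaults <- function(x, defs) {
  for (k in names(defs)) if (is.null(x[[k]])) x[[k]] <- defs[[k]]
  x
}

#' Simulate a two-signal methylation dataset
#'
#' Draws a baseline beta per CpG from the bimodal mixture, applies the
#' outcome effect to affected CpGs in case samples on the beta scale,
#' adds per-sample beta noise, constructs signals as `B = beta * T`,
#' `A = (1 - beta) * T` with log-normal total intensity `T`, applies
#' chip-level biases (beta-scale shifts before signal construction,
#' additive/multiplicative/intensity-dependent biases on the signal
#' scale after), and appends technical replicate columns with
#' independent beta-scale noise.
#'
#' @param config a [sim_config()].
#' @return list with `signals` ([signal_matrix()]), `beta` (average beta
#'   recomputed from the signals), `detection` (matrix of small uniform
#'   detection p-values), `samples` ([sample_sheet()]), `annotation`
#'   ([probe_annotation()]), `truth` (data.frame flagging batch- and
#'   outcome-affected CpGs, plus the intended noise-free baseline), and
#'   `config`.
#' @export
simulate_methylation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cpgs
  probes <- sprintf("cg%07d", seq_len(n))

  # annotation: chrX/Y block first (deterministic count), autosomes after
  n_xy <- round(n * config$chrXY_fraction)
  chrom <- c(sample(c("X", "Y"), n_xy, replace = TRUE),
             sample(as.character(1:22), n - n_xy, replace = TRUE))
  chrom <- sample(chrom)  # shuffle positions
  ann <- probe_annotation(probes, chromosome = chrom,
                          color_channel = sample(c("red", "green"), n,
                                                 replace = TRUE))

  # sample layout
  chips <- names(config$batches)
  sample_id <- character(0); batch <- character(0); outcome <- character(0)
  for (chip in chips) {
    nsmp <- config$batches[[chip]]
    bal <- config$outcome_balance[[chip]]
    ids <- sprintf("%s_s%02d", chip, seq_len(nsmp))
    sample_id <- c(sample_id, ids)
    batch <- c(batch, rep(chip, nsmp))
    outcome <- c(outcome,
                 sample(rep(c("case", "control"), times = bal)))
  }
  N <- length(sample_id)

  # baseline methylation: bimodal Beta mixture
  bl <- config$baseline
  low <- stats::rbinom(n, 1, bl$weight_low) == 1
  base_beta <- ifelse(low,
                      stats::rbeta(n, bl$low_shape[1], bl$low_shape[2]),
                      stats::rbeta(n, bl$high_shape[1], bl$high_shape[2]))

  # truth tables
  n_out <- round(config$outcome_effect$frac * n)
  outcome_idx <- sort(sample.int(n, n_out))
  out_sign <- sample(c(-1, 1), n, replace = TRUE)
  eff <- config$batch_effect
  batch_idx <- integer(0)
  eff_full <- list()
  if (!is.null(eff)) {
    for (chip in names(eff)) {
      e <- .defaults(eff[[chip]],
                     list(beta_shift = 0, add_a = 0, add_b = 0,
                          mult_a = 1, mult_b = 1, frac = 1,
                          intensity_coef = 0))
      e$idx <- sort(sample.int(n, round(e$frac * n)))
      eff_full[[chip]] <- e
      batch_idx <- union(batch_idx, e$idx)
    }
  }

  # per-sample beta values
  Tg <- stats::rlnorm(n, config$intensity$meanlog, config$intensity$sdlog)
  squeeze <- function(b) pmin(pmax(b, 1e-3), 0.999)
  make_sample <- function(src_beta, chip, is_case, noise_sd) {
    b <- src_beta
    if (n_out > 0 && is_case)
      b[outcome_idx] <- b[outcome_idx] +
        out_sign[outcome_idx] * config$outcome_effect$delta_beta
    e <- eff_full[[chip]]
    if (!is.null(e) && e$beta_shift != 0)
      b[e$idx] <- b[e$idx] + e$beta_shift
    b <- squeeze(b + stats::rnorm(n, 0, noise_sd))
    Tj <- Tg * stats::rlnorm(n, 0, config$intensity$sample_sdlog)
    B <- b * Tj
    A <- (1 - b) * Tj
    if (!is.null(e)) {
      i <- e$idx
      A[i] <- pmax(A[i] * e$mult_a + e$add_a +
                     e$intensity_coef * Tj[i], 0)
      B[i] <- pmax(B[i] * e$mult_b + e$add_b +
                     e$intensity_coef * Tj[i], 0)
    }
    list(A = A, B = B)
  }

  A <- matrix(NA_real_, n, N, dimnames = list(probes, sample_id))
  B <- A
  for (j in seq_len(N)) {
    s <- make_sample(base_beta, batch[j], outcome[j] == "case",
                     config$beta_noise_sd)
    A[, j] <- s$A; B[, j] <- s$B
  }

  replicate_group <- rep(NA_character_, N)
  if (config$replicate_pairs > 0) {
    if (config$replicate_pairs > N)
      stop("more replicate pairs than samples")
    src <- sample.int(N, config$replicate_pairs)
    for (k in seq_along(src)) {
      j <- src[k]
      grp <- sprintf("rep%02d", k)
      replicate_group[j] <- grp
      rid <- paste0(sample_id[j], "_rep")
      # replicate re-assays the source sample: same totals, fresh
      # beta-scale noise; zero noise duplicates the signals exactly
      Tj <- A[, j] + B[, j]
      if (config$replicate_noise_sd == 0) {
        A <- cbind(A, A[, j])
        B <- cbind(B, B[, j])
      } else {
        src_b <- squeeze(B[, j] / Tj +
                           stats::rnorm(n, 0, config$replicate_noise_sd))
        A <- cbind(A, (1 - src_b) * Tj)
        B <- cbind(B, src_b * Tj)
      }
      colnames(A)[ncol(A)] <- rid
      colnames(B)[ncol(B)] <- rid
      sample_id <- c(sample_id, rid)
      batch <- c(batch, batch[j])
      outcome <- c(outcome, outcome[j])
      replicate_group <- c(replicate_group, grp)
    }
  }

  signals <- signal_matrix(A, B)
  beta <- compute_beta(signals)
  detection <- matrix(stats::runif(length(A), 0, 0.01), nrow(A), ncol(A),
                      dimnames = dimnames(A))
  sheet <- sample_sheet(data.frame(
    sample_id = sample_id, batch = batch, outcome = outcome,
    replicate_group = replicate_group, stringsAsFactors = FALSE))
  truth <- data.frame(
    probe_id = probes,
    baseline_beta = base_beta,
    outcome_affected = seq_len(n) %in% outcome_idx,
    outcome_sign = ifelse(seq_len(n) %in% outcome_idx,
                          out_sign, 0L),
    batch_affected = seq_len(n) %in% batch_idx,
    stringsAsFactors = FALSE)
  list(signals = signals, beta = beta, detection = detection,
       samples = sheet, annotation = ann, truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits a GenomeStudio-style final report (signals, beta, detection),
#' the sample sheet, the probe annotation and the truth table, all as
#' plain text that round-trips through the package readers.
#'
#' @param dataset a [simulate_methylation()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(report = file.path(dir, "final_report.tsv"),
             samples = file.path(dir, "samples.csv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_final_report(paths[["report"]], signals = dataset$signals,
                     beta = dataset$beta,
                     detection = dataset$detection)
  write_sample_sheet(dataset$samples, paths[["samples"]])
  utils::write.table(dataset$annotation, paths[["annotation"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
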