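#' Orchestrate the full assessment / normalization / correction procedure
#'
#' Runs the sequential two-step procedure on one dataset and reports the
#' batch and outcome diagnostics at every stage: raw data, after
#' normalization, and after normalization plus empirical Bayes batch
#' correction. The result is a stage-by-metric comparison table (CpGs
#' associated with batch, leading principal components associated with
#' batch and their variance fractions, CpGs associated with the outcome)
#' plus the per-stage reports.
#'
#' `config` is a list (or a path to a YAML file parsing to one) with:
#' \describe{
#'   \item{`sim`}{either a [sim_config()], or a list of arguments for
#'     [sim_regime()] (e.g. `list(regime = "shift", seed = 7)`);
#'     mutually exclusive with file inputs.}
#'   \item{`report` / `beta` / `samples` / `annotation`}{paths: a final
#'     report (or plain beta matrix TSV), a sample sheet, and optionally
#'     a probe annotation TSV with `probe_id`, `chromosome`,
#'     `color_channel` columns.}
#'   \item{`method`}{normalization: `"qn-beta"`, `"abnorm"`, `"lumi"` or
#'     `"none"` (default `"qn-beta"`).}
#'   \item{`eb`}{logical, run EB correction after normalization
#'     (default `TRUE`).}
#'   \item{`covariates`}{sample-sheet columns protected during EB
#'     (default `"outcome"` when present).}
#'   \item{`outcome`}{sample-sheet column tested for differential
#'     methylation (default `"outcome"` when present).}
#'   \item{`exclude_chromosomes`}{probes on these chromosomes are
#'     dropped before any analysis (needs an annotation).}
#'   \item{`alpha`, `k_pcs`}{significance threshold (default 0.01) and
#'     number of leading components tested (default 10).}
#'   \item{`out_dir`}{if set, corrected matrices, the comparison table
#'     and a run manifest are written there.}
#' }
#'
#' @param config list or YAML path, see Details.
#' @return object of class `pipeline_result`: `comparison` (data.frame,
#'   one row per stage), `reports` (per-stage [batch_report()]s),
#'   `corrected` (final beta matrix), `model` (the [fit_eb()] model or
#'   `NULL`), `replicates` (per-stage [replicate_errors()] when the
#'   sheet has replicate pairs).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  method <- config$method %||% "qn-beta"
  if (!method %in% c("qn-beta", "abnorm", "lumi", "none"))
    stop("unknown normalization method: ", method)
  eb <- config$eb %||% TRUE
  alpha <- config$alpha %||% 0.01
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  k_pcs <- config$k_pcs %||% 10

  # ---- inputs -------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- if (inherits(config$sim, "sim_config")) config$sim
           else do.call(sim_regime, config$sim)
    data <- simulate_methylation(sim)
    signals <- data$signals; beta <- data$beta
    sheet <- data$samples; ann <- data$annotation
  } else {
    signals <- NULL; beta <- NULL; ann <- NULL
    if (!is.null(config$report)) {
      rep_in <- read_final_report(config$report)
      signals <- rep_in$signals
      beta <- rep_in$beta
      if (is.null(beta) && !is.null(signals)) beta <- compute_beta(signals)
    } else if (!is.null(config$beta)) {
      beta <- read_matrix_tsv(config$beta)
    } else stop("config needs either 'sim', 'report' or 'beta'")
    if (is.null(config$samples)) stop("config needs a 'samples' sheet")
    sheet <- read_sample_sheet(config$samples)
    if (!is.null(config$annotation)) {
      df <- utils::read.table(config$annotation, header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
      ann <- probe_annotation(df$probe_id, df$chromosome,
                              df$color_channel)
    }
  }
  if (!is.null(config$exclude_chromosomes)) {
    if (is.null(ann)) stop("chromosome filtering needs an annotation")
    if (!is.null(signals))
      signals <- filter_probes(signals, ann, config$exclude_chromosomes)
    beta <- filter_probes(beta, ann, config$exclude_chromosomes)
  }

  outcome_col <- config$outcome %||%
    (if ("outcome" %in% names(sheet)) "outcome" else NULL)
  covariates <- config$covariates %||%
    (if (is.null(outcome_col)) character(0) else outcome_col)

  # ---- stages -------------------------------------------------------
  aligned <- .align_sheet(sheet, colnames(beta))
  has_reps <- "replicate_group" %in% names(aligned) &&
    any(!is.na(aligned$replicate_group))
  assess <- function(b) {
    rep_b <- batch_report(b, sheet, alpha = alpha, k_pcs = k_pcs,
                          cluster = ncol(b) >= 3)
    outcome <- if (!is.null(outcome_col))
      count_significant(per_cpg_anova(b, aligned[[outcome_col]]),
                        alpha = alpha)
    else list(count = NA_integer_, fraction = NA_real_)
    list(report = rep_b, outcome = outcome)
  }

  stages <- list(raw = beta)
  if (method != "none")
    stages[[method]] <- normalize_beta(method, beta = beta,
                                       signals = signals,
                                       annotation = ann)
  model <- NULL
  if (eb) {
    last <- stages[[length(stages)]]
    cb <- correct_batch(last, sheet, covariates = covariates)
    stages[[paste0(names(stages)[length(stages)], "+eb")]] <- cb$beta
    model <- cb$model
  }

  evals <- lapply(stages, assess)
  comparison <- do.call(rbind, lapply(names(evals), function(nm) {
    e <- evals[[nm]]
    sig <- e$report$pc_batch$pc[e$report$pc_batch$flag]
    data.frame(
      stage = nm,
      batch_cpg_count = e$report$batch_cpg_count,
      batch_cpg_fraction = e$report$batch_cpg_fraction,
      batch_pcs = if (length(sig)) paste(sig, collapse = ",") else "none",
      batch_pc1_var = if (length(sig))
        e$report$pc_variance_fractions[sig[1]] else NA_real_,
      outcome_cpg_count = e$outcome$count,
      outcome_cpg_fraction = e$outcome$fraction,
      stringsAsFactors = FALSE)
  }))
  replicates <- if (has_reps)
    lapply(stages, replicate_errors, samples = sheet) else NULL

  result <- structure(list(
    comparison = comparison,
    reports = lapply(evals, `[[`, "report"),
    corrected = stages[[length(stages)]],
    stages = stages,
    model = model,
    replicates = replicates,
    config = config
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) .write_pipeline(result, config$out_dir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$comparison, file.path(dir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(result$corrected, file.path(dir, "corrected_beta.tsv"))
  manifest <- list(
    package = "methbatch",
    version = as.character(utils::packageVersion("methbatch")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = result$config[setdiff(names(result$config), "sim")],
    stages = names(result$stages))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("methbatch pipeline result\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}
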