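#' Describe a final-report column dialect
#'
#' GenomeStudio/BeadStudio final reports are wide tab-separated tables
#' with one row per probe and per-sample column families such as
#' `Sample1.Signal_A`, `Sample1.Signal_B`, `Sample1.AVG_Beta`,
#' `Sample1.Detection Pval`. Export versions differ in the exact suffixes
#' and delimiter, so the dialect is configurable.
#'
#' @param probe_id_col name of the probe identifier column.
#' @param signal_a_suffix,signal_b_suffix,avg_beta_suffix,detection_suffix
#'   per-sample column suffixes; the sample id is the prefix before the
#'   separator.
#' @param sep separator between sample id and suffix within a column name.
#' @param delimiter single field-delimiter character.
#' @param header_marker line prefix opening a bracketed header block that
#'   is skipped until the data-section marker.
#' @param data_marker bracketed line introducing the probe table.
#' @return a `FinalReportDialect` list.
#' @export
final_report_dialect <- function(probe_id_col = "TargetID",
                                 signal_a_suffix = "Signal_A",
                                 signal_b_suffix = "Signal_B",
                                 avg_beta_suffix = "AVG_Beta",
                                 detection_suffix = "Detection Pval",
                                 sep = ".",
                                 delimiter = "\t",
                                 header_marker = "[Header]",
                                 data_marker = "[Sample Methylation Profile]") {
  if (nchar(delimiter) != 1)
    stop("delimiter must be a single character")
  for (v in c(probe_id_col, signal_a_suffix, signal_b_suffix,
              avg_beta_suffix)) {
    if (!nzchar(v)) stop("dialect column names must be non-empty")
  }
  structure(list(probe_id_col = probe_id_col,
                 signal_a_suffix = signal_a_suffix,
                 signal_b_suffix = signal_b_suffix,
                 avg_beta_suffix = avg_beta_suffix,
                 detection_suffix = detection_suffix,
                 sep = sep, delimiter = delimiter,
                 header_marker = header_marker,
                 data_marker = data_marker),
            class = "FinalReportDialect")
}

.parse_family <- function(header, suffix, sep) {
  # columns named "<sample><sep><suffix>"; returns sample id per match
  tail_str <- paste0(sep, suffix)
  hits <- endsWith(header, tail_str)
  ids <- substr(header[hits], 1, nchar(header[hits]) - nchar(tail_str))
  list(cols = which(hits), ids = ids)
}

#' Read a GenomeStudio-style final report
#'
#' Parses the wide per-sample column families of a final report into
#' aligned probe-by-sample matrices. A leading bracketed header block
#' (`[Header]` ... `[Sample Methylation Profile]`) is skipped when
#' present. At least one of the signal family pair or the beta family
#' must be present.
#'
#' @param path file path.
#' @param dialect a [final_report_dialect()].
#' @return list with elements `signals` ([signal_matrix()] or `NULL`),
#'   `beta` (matrix or `NULL`), `detection` (matrix or `NULL`).
#' @export
read_final_report <- function(path, dialect = final_report_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  skip <- 0
  if (length(lines) && startsWith(lines[1], "[")) {
    dm <- which(lines == dialect$data_marker)
    if (length(dm) == 0)
      stop("header block present but data marker '", dialect$data_marker,
           "' not found")
    skip <- dm[1]
  }
  lines <- lines[(skip + 1):length(lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) stop("no data rows in ", path)
  fields <- strsplit(lines, dialect$delimiter, fixed = TRUE)
  header <- fields[[1]]
  widths <- lengths(fields)
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad + skip, widths[bad], length(header)))
  }
  pid_col <- which(header == dialect$probe_id_col)
  if (length(pid_col) != 1)
    stop(sprintf("probe-id column '%s' not found in header (line %d)",
                 dialect$probe_id_col, skip + 1))
  body <- fields[-1]
  probes <- vapply(body, `[[`, "", pid_col)
  if (anyDuplicated(probes))
    stop("duplicate probe ids in report: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))

  grab <- function(suffix) {
    fam <- .parse_family(header, suffix, dialect$sep)
    if (length(fam$cols) == 0) return(NULL)
    m <- vapply(fam$cols, function(j) {
      .parse_numeric(vapply(body, `[[`, "", j), j)
    }, numeric(length(body)))
    m <- matrix(m, nrow = length(body),
                dimnames = list(probes, fam$ids))
    m
  }
  A <- grab(dialect$signal_a_suffix)
  B <- grab(dialect$signal_b_suffix)
  beta <- grab(dialect$avg_beta_suffix)
  det <- grab(dialect$detection_suffix)
  if (is.null(beta) && (is.null(A) || is.null(B)))
    stop("report contains neither a Signal_A/Signal_B pair nor AVG_Beta")
  signals <- NULL
  if (!is.null(A) && !is.null(B)) {
    if (!identical(colnames(A), colnames(B)))
      stop("Signal_A and Signal_B sample sets differ")
    signals <- signal_matrix(A, B)
  }
  list(signals = signals, beta = beta, detection = det)
}

.parse_numeric <- function(x, col) {
  x[x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' at data row %d, column %d",
                 x[bad[1]], bad[1], col))
  out
}

#' Write a final report for a signal/beta/detection set
#'
#' Emits a GenomeStudio-style wide report (with a minimal bracketed
#' header block) that [read_final_report()] round-trips. Values are
#' written at full double precision, so the round trip is value-exact.
#'
#' @param path output path.
#' @param signals optional [signal_matrix()].
#' @param beta optional beta matrix.
#' @param detection optional detection p-value matrix.
#' @param dialect a [final_report_dialect()].
#' @return `path`, invisibly.
#' @export
write_final_report <- function(path, signals = NULL, beta = NULL,
                               detection = NULL,
                               dialect = final_report_dialect()) {
  ref <- if (!is.null(signals)) signals$A else beta
  if (is.null(ref)) stop("nothing to write")
  probes <- rownames(ref)
  ids <- colnames(ref)
  cols <- list()
  header <- dialect$probe_id_col
  add <- function(m, suffix) {
    for (j in seq_len(ncol(m))) {
      header <<- c(header, paste0(ids[j], dialect$sep, suffix))
      cols[[length(cols) + 1]] <<- .fmt_num(m[, j])
    }
  }
  if (!is.null(signals)) {
    add(signals$A, dialect$signal_a_suffix)
    add(signals$B, dialect$signal_b_suffix)
  }
  if (!is.null(beta)) add(beta, dialect$avg_beta_suffix)
  if (!is.null(detection)) add(detection, dialect$detection_suffix)
  tbl <- do.call(cbind, c(list(probes), cols))
  lines <- c(dialect$header_marker,
             paste0("Generated", dialect$delimiter, "methbatch"),
             dialect$data_marker,
             paste(header, collapse = dialect$delimiter),
             apply(tbl, 1, paste, collapse = dialect$delimiter))
  writeLines(lines, path)
  invisible(path)
}

.fmt_num <- function(x) {
  # 17 significant digits round-trips IEEE doubles exactly
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Write / read a plain probe-by-sample matrix as TSV
#'
#' Row 1 holds sample ids, column 1 probe ids. Values are written at full
#' double precision so a write/read round trip is value-exact; missing
#' entries round-trip as empty cells.
#'
#' @param m numeric matrix with probe rownames and sample colnames.
#' @param path file path.
#' @return `write_matrix_tsv`: `path` invisibly; `read_matrix_tsv`: the
#'   matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    stop("m must be a non-empty matrix")
  if (any(grepl("\t", c(rownames(m), colnames(m)))))
    stop("labels must not contain the delimiter")
  lines <- c(paste(c("probe_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], .fmt_num(m[i, ])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix file has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # trailing empty cells are dropped by strsplit; pad back
  p <- length(fields[[1]])
  fields <- lapply(fields, function(f) c(f, rep("", p - length(f))))
  header <- fields[[1]]
  body <- fields[-1]
  probes <- vapply(body, `[[`, "", 1)
  m <- vapply(seq_len(p - 1), function(j) {
    .parse_numeric(vapply(body, `[[`, "", j + 1), j + 1)
  }, numeric(length(body)))
  matrix(m, nrow = length(body), dimnames = list(probes, header[-1]))
}

#' Read a sample sheet from CSV or TSV
#'
#' The delimiter is inferred from the file extension (`.csv` = comma,
#' anything else = tab). Requires `sample_id` and `batch` columns; all
#' other columns are preserved as covariates.
#'
#' @param path file path.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(sheet, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
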