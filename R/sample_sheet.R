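#' Construct and validate a sample sheet
#'
#' A sample sheet carries per-sample metadata: the mandatory `sample_id`
#' and `batch` (chip) columns, optionally an outcome or other covariates,
#' and an optional `replicate_group` identifier shared by technical
#' replicates of the same source sample.
#'
#' @param df data.frame with at least `sample_id` and `batch` columns.
#' @return data.frame of class `SampleSheet`.
#' @export
sample_sheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("sample_id", "batch")) {
    if (!col %in% names(df))
      stop("sample sheet must contain a '", col, "' column")
  }
  df$sample_id <- as.character(df$sample_id)
  df$batch <- as.character(df$batch)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  if ("replicate_group" %in% names(df)) {
    grp <- df$replicate_group
    grp[grp %in% c("", "NA")] <- NA
    df$replicate_group <- as.character(grp)
    sizes <- table(df$replicate_group)
    if (any(sizes < 2))
      stop("replicate groups must have at least 2 members: ",
           paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  class(df) <- c("SampleSheet", "data.frame")
  df
}

# Align a sample sheet to a matrix's columns; every sample must have
# exactly one metadata row.
.align_sheet <- function(samples, sample_ids) {
  stopifnot(inherits(samples, "SampleSheet"))
  idx <- match(sample_ids, samples$sample_id)
  if (anyNA(idx))
    stop("samples missing from sample sheet: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  samples[idx, , drop = FALSE]
}
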