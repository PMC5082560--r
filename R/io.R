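# Plain-text I/O for summarized association data and simulated
# individual-level data.

#' Read and write summarized association data as TSV
#'
#' The documented schema is a tab-separated file with header columns
#' `variant_id`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#' `se_outcome` and optional `eaf`, `n_exposure`, `n_outcome`. Malformed
#' rows (missing values, non-numeric betas/SEs, non-positive SEs) are
#' reported with their row numbers. Writing and re-reading a
#' [summary_data()] object is the identity up to column order.
#'
#' @param path File path.
#' @param summary A [summary_data()] data frame.
#' @return `read_summary_tsv()` returns a [summary_data()] data frame;
#'   `write_summary_tsv()` returns `path` invisibly.
#' @export
read_summary_tsv <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_summary_data(df)
}

#' @rdname read_summary_tsv
#' @export
write_summary_tsv <- function(summary, path) {
  summary <- validate_summary_data(summary)
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated individual-level data as TSV
#'
#' Columns: `id`, one column per variant (`g1`..`gK`), `x`, `y`, and `case`
#' when the case indicator is present.
#'
#' @param data An [mr_data()] object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_individual_tsv <- function(data, path) {
  stopifnot(inherits(data, "mr_data"))
  df <- data.frame(id = seq_len(nrow(data$genotypes)), data$genotypes,
                   x = data$risk_factor, y = data$outcome)
  if (!is.null(data$case)) df$case <- as.integer(data$case)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
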