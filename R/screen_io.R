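# Tabular IO for the three screen tables and the prediction output.
#
# File schemas (long format, comma-separated, header required):
#   single-agent: drug,cell_line,dose_uM,response
#   combination:  drug_a,drug_b,cell_line,dose_a_uM,dose_b_uM,response
#   panel:        cell_line,genotype          (genotype in {BRAF, RAS, WT})
#
# Responses are fractions of growth inhibited in [0,1]. Tables whose
# response column contains any value above 1.5 are taken to be in percent
# and rescaled to fractions, with a message.

GENOTYPES <- c("BRAF", "RAS", "WT")

read_screen_table <- function(path, required) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("malformed header in '%s': missing column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

# Percent vs fraction auto-detection on a response column.
normalize_response <- function(resp, context) {
  if (any(resp > 1.5, na.rm = TRUE)) {
    message(sprintf("%s: responses look like percentages (max %.3g); rescaling to fractions",
                    context, max(resp, na.rm = TRUE)))
    resp <- resp / 100
  }
  resp
}

drop_incomplete <- function(df, cols, context) {
  keep <- stats::complete.cases(df[cols])
  if (any(!keep)) {
    message(sprintf("%s: dropped %d row(s) with missing values", context, sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  df
}

validate_response_range <- function(resp, context) {
  bad <- which(resp < 0 | resp > 1)
  if (length(bad)) {
    stop(sprintf("%s: response outside [0,1] at data row %d (value %g)",
                 context, bad[1], resp[bad[1]]), call. = FALSE)
  }
}

#' Read a single-agent dose-response table
#'
#' Expects columns `drug,cell_line,dose_uM,response`. Rows with missing dose
#' or response are dropped with a logged count; replicate rows (same drug,
#' cell line and dose) are kept and averaged later by the curve fitter.
#'
#' @param path Path to a delimited text file.
#' @return A data.frame with one row per observation, responses as fractions
#'   in `[0,1]`, sorted by drug, cell line, dose.
#' @export
read_single_agent_table <- function(path) {
  df <- read_screen_table(path, c("drug", "cell_line", "dose_uM", "response"))
  if (nrow(df) == 0) {
    warning(sprintf("'%s' contains a valid header but no data rows", path))
    return(df)
  }
  df <- drop_incomplete(df, c("drug", "cell_line", "dose_uM", "response"), path)
  if (any(df$dose_uM <= 0)) {
    stop(sprintf("%s: non-positive dose at data row %d", path,
                 which(df$dose_uM <= 0)[1]), call. = FALSE)
  }
  df$response <- normalize_response(df$response, path)
  validate_response_range(df$response, path)
  df[order(df$drug, df$cell_line, df$dose_uM), , drop = FALSE]
}

#' Read a combination-measurement table
#'
#' Expects columns `drug_a,drug_b,cell_line,dose_a_uM,dose_b_uM,response`.
#' Each pair is canonicalized so `drug_a <= drug_b` (doses travel with their
#' drug); duplicate (pair, cell line, dose pair) rows are kept as replicates.
#'
#' @param path Path to a delimited text file.
#' @param allow_sham Permit rows where a drug is combined with itself
#'   (sham combinations, used as negative controls).
#' @return A data.frame of combination measurements with fractional responses.
#' @export
read_combination_table <- function(path, allow_sham = FALSE) {
  df <- read_screen_table(
    path, c("drug_a", "drug_b", "cell_line", "dose_a_uM", "dose_b_uM", "response"))
  if (nrow(df) == 0) {
    warning(sprintf("'%s' contains a valid header but no data rows", path))
    return(df)
  }
  df <- drop_incomplete(
    df, c("drug_a", "drug_b", "cell_line", "dose_a_uM", "dose_b_uM", "response"), path)
  if (any(df$dose_a_uM < 0 | df$dose_b_uM < 0)) {
    stop(sprintf("%s: negative dose at data row %d", path,
                 which(df$dose_a_uM < 0 | df$dose_b_uM < 0)[1]), call. = FALSE)
  }
  zero <- df$dose_a_uM == 0 & df$dose_b_uM == 0
  if (any(zero)) {
    stop(sprintf("%s: both doses zero at data row %d", path, which(zero)[1]),
         call. = FALSE)
  }
  if (!allow_sham && any(df$drug_a == df$drug_b)) {
    stop(sprintf("%s: drug combined with itself at data row %d (use allow_sham = TRUE for sham controls)",
                 path, which(df$drug_a == df$drug_b)[1]), call. = FALSE)
  }
  df$response <- normalize_response(df$response, path)
  validate_response_range(df$response, path)
  df <- canonicalize_pairs(df)
  df[order(df$drug_a, df$drug_b, df$cell_line, df$dose_a_uM, df$dose_b_uM), ,
     drop = FALSE]
}

#' Read a cell-line genotype table
#'
#' Expects columns `cell_line,genotype` with genotypes drawn from
#' BRAF / RAS / WT and unique cell-line ids.
#'
#' @param path Path to a delimited text file.
#' @return A data.frame with columns `cell_line` and `genotype`.
#' @export
read_panel_table <- function(path) {
  df <- read_screen_table(path, c("cell_line", "genotype"))
  if (anyDuplicated(df$cell_line)) {
    stop(sprintf("%s: duplicated cell line id '%s'", path,
                 df$cell_line[duplicated(df$cell_line)][1]), call. = FALSE)
  }
  bad <- setdiff(unique(df$genotype), GENOTYPES)
  if (length(bad)) {
    stop(sprintf("%s: unknown genotype '%s' (expected %s)", path, bad[1],
                 paste(GENOTYPES, collapse = "/")), call. = FALSE)
  }
  df
}

#' Write per-pair predictions
#'
#' Emits a delimited table with one row per drug pair: predicted
#' probabilities for the three outcomes and the corresponding boolean calls.
#' The table round-trips losslessly through [read_predictions()].
#'
#' @param predictions A data.frame with columns `pair`, `p_synergy`,
#'   `p_effective`, `p_selective`, `call_synergy`, `call_effective`,
#'   `call_selective`.
#' @param path Output file path.
#' @param seed Optional seed echoed into a header comment line.
#' @export
write_predictions <- function(predictions, path, seed = NULL) {
  required <- c("pair", "p_synergy", "p_effective", "p_selective",
                "call_synergy", "call_effective", "call_selective")
  missing <- setdiff(required, names(predictions))
  if (length(missing)) {
    stop(sprintf("predictions table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("p_synergy", "p_effective", "p_selective")) {
    p <- predictions[[col]]
    if (any(!is.na(p) & (p < 0 | p > 1))) {
      stop(sprintf("refusing to write: %s outside [0,1]", col), call. = FALSE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(predictions[required], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a predictions table written by [write_predictions()]
#'
#' @param path Path to the predictions file.
#' @return The predictions data.frame (header comment lines skipped).
#' @export
read_predictions <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write any screen table as delimited text
#'
#' Thin wrapper used by the pipeline to persist intermediate stage outputs.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @export
write_screen_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
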