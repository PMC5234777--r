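#' @keywords internal
"_PACKAGE"

# Shared small helpers: pair ids, fraction clipping, input checks.

#' Canonical identifier for an unordered drug pair
#'
#' Pairs are stored with the lexicographically smaller drug first so that an
#' unordered pair maps to exactly one identifier. The operation is idempotent
#' and insensitive to the order of its two arguments.
#'
#' @param drug_a,drug_b Character vectors of drug identifiers (recycled).
#' @param sep Separator used in the id string.
#' @return Character vector of pair ids, e.g. `"drugA|drugB"`.
#' @examples
#' pair_id("vemurafenib", "trametinib")
#' @export
pair_id <- function(drug_a, drug_b, sep = "|") {
  a <- as.character(drug_a)
  b <- as.character(drug_b)
  paste(pmin(a, b), pmax(a, b), sep = sep)
}

#' Canonicalize drug pair columns in place
#'
#' @param df A data.frame with `drug_a` and `drug_b` columns.
#' @return The same data.frame with `drug_a <= drug_b` row-wise.
#' @export
canonicalize_pairs <- function(df) {
  stopifnot(all(c("drug_a", "drug_b") %in% names(df)))
  a <- as.character(df$drug_a)
  b <- as.character(df$drug_b)
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
    # dose columns travel with their drug
    if (all(c("dose_a_uM", "dose_b_uM") %in% names(df))) {
      tmpd <- df$dose_a_uM[swap]
      df$dose_a_uM[swap] <- df$dose_b_uM[swap]
      df$dose_b_uM[swap] <- tmpd
    }
  }
  df$drug_a <- a
  df$drug_b <- b
  df
}

# Clip fractions into the open interval used for log-odds transforms.
clip_fraction <- function(x, eps = 1e-3) {
  pmin(pmax(x, eps), 1 - eps)
}

# TRUE for values strictly inside (eps, 1 - eps): usable in log-odds space.
is_interior <- function(x, eps = 1e-3) {
  !is.na(x) & x > eps & x < (1 - eps)
}

assert_fraction <- function(x, what = "value") {
  bad <- which(!is.na(x) & (x < 0 | x > 1))
  if (length(bad)) {
    stop(sprintf("%s outside [0,1] at position(s) %s (first offending value: %g)",
                 what, paste(utils::head(bad, 5), collapse = ", "), x[bad[1]]),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
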