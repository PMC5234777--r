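# Pairwise feature construction from the single-agent GI50 matrix.
#
# For each cell line c the pair (a, b) contributes two features built from
# the transformed GI50 values t_a,c and t_b,c:
#   mu_c    = (t_a,c + t_b,c) / 2
#   delta_c = |t_a,c - t_b,c|
# so a panel of C cell lines gives a vector of length 2C (54 features for a
# 27-line panel). The absolute difference makes the vector invariant to the
# order of the two drugs; a signed variant (with canonical drug ordering) is
# available behind a flag.

transform_gi50 <- function(x, transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  switch(transform, log10 = log10(x), identity = x)
}

#' Feature vector for one drug pair
#'
#' @param gi50 Drug-by-cell-line GI50 matrix (uM), as from [gi50_matrix()].
#' @param drug_a,drug_b Drug ids (rows of `gi50`).
#' @param transform Transform applied to GI50 doses before combining
#'   (default `"log10"`; imputed/capped entries pass through it unchanged).
#' @param signed_delta Use the signed difference `t_a - t_b` after canonical
#'   drug ordering instead of the absolute difference.
#' @return Named numeric vector `c(mu_<line>..., delta_<line>...)` of length
#'   twice the number of cell lines, in the matrix's column order.
#' @export
build_pair_features <- function(gi50, drug_a, drug_b, transform = "log10",
                                signed_delta = FALSE) {
  for (d in c(drug_a, drug_b)) {
    if (!d %in% rownames(gi50)) stop(sprintf("unknown drug '%s'", d), call. = FALSE)
  }
  if (drug_a > drug_b) { tmp <- drug_a; drug_a <- drug_b; drug_b <- tmp }
  ta <- transform_gi50(gi50[drug_a, ], transform)
  tb <- transform_gi50(gi50[drug_b, ], transform)
  mu <- (ta + tb) / 2
  delta <- if (signed_delta) ta - tb else abs(ta - tb)
  stats::setNames(c(mu, delta),
                  c(paste0("mu_", colnames(gi50)),
                    paste0("delta_", colnames(gi50))))
}

#' Feature matrix for a list of pairs
#'
#' @param gi50 Drug-by-cell-line GI50 matrix.
#' @param pairs Data.frame with `drug_a`, `drug_b` (canonicalized here).
#' @inheritParams build_pair_features
#' @return Numeric matrix (pairs x 2C) with pair ids as row names and the
#'   cell-line ordering recorded in attribute `"cell_lines"`.
#' @export
featurize_pairs <- function(gi50, pairs, transform = "log10",
                            signed_delta = FALSE) {
  pairs <- canonicalize_pairs(pairs)
  ta <- transform_gi50(gi50[pairs$drug_a, , drop = FALSE], transform)
  tb <- transform_gi50(gi50[pairs$drug_b, , drop = FALSE], transform)
  mu <- (ta + tb) / 2
  delta <- if (signed_delta) ta - tb else abs(ta - tb)
  X <- cbind(mu, delta)
  colnames(X) <- c(paste0("mu_", colnames(gi50)),
                   paste0("delta_", colnames(gi50)))
  rownames(X) <- pair_id(pairs$drug_a, pairs$drug_b)
  attr(X, "cell_lines") <- colnames(gi50)
  X
}

#' Sham (self-combination) feature vectors
#'
#' A sham combination pairs a drug with itself: the mean block equals the
#' drug's own transformed GI50 profile and the difference block is all
#' zeros. Shams are the negative controls a synergy predictor should call
#' non-synergistic.
#'
#' @param gi50 Drug-by-cell-line GI50 matrix.
#' @param drugs Drug ids (default: every row of `gi50`).
#' @inheritParams build_pair_features
#' @return Feature matrix with one sham row per drug, flagged with
#'   attribute `"sham" = TRUE`.
#' @export
make_sham_features <- function(gi50, drugs = rownames(gi50),
                               transform = "log10") {
  X <- featurize_pairs(gi50,
                       data.frame(drug_a = drugs, drug_b = drugs),
                       transform = transform)
  rownames(X) <- pair_id(drugs, drugs)
  attr(X, "sham") <- TRUE
  X
}

#' Enumerate untested drug pairs
#'
#' All C(n,2) unordered pairs of `all_drugs` minus the tested ones,
#' canonically ordered and deduplicated.
#'
#' @param all_drugs Character vector of drug ids.
#' @param tested_pairs Data.frame with `drug_a`, `drug_b`, or NULL for none.
#' @return Data.frame of untested pairs (`drug_a < drug_b`).
#' @examples
#' nrow(enumerate_untested_pairs(letters[1:5]))  # choose(5, 2) = 10
#' @export
enumerate_untested_pairs <- function(all_drugs, tested_pairs = NULL) {
  all_drugs <- sort(unique(as.character(all_drugs)))
  if (length(all_drugs) < 2) {
    return(data.frame(drug_a = character(), drug_b = character()))
  }
  cmb <- utils::combn(all_drugs, 2)
  pairs <- data.frame(drug_a = cmb[1, ], drug_b = cmb[2, ])
  if (!is.null(tested_pairs) && nrow(tested_pairs)) {
    tested <- unique(pair_id(tested_pairs$drug_a, tested_pairs$drug_b))
    unknown <- setdiff(tested, pair_id(pairs$drug_a, pairs$drug_b))
    if (length(unknown)) {
      stop(sprintf("tested pair(s) not formed from all_drugs: %s",
                   paste(utils::head(unknown, 3), collapse = ", ")),
           call. = FALSE)
    }
    pairs <- pairs[!(pair_id(pairs$drug_a, pairs$drug_b) %in% tested), ,
                   drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Correlation of two drugs' efficacy profiles
#'
#' Pearson correlation of the transformed GI50 vectors of the two drugs over
#' a cell-line subset — e.g. across the mutant-BRAF lines, where weakly
#' correlated profiles were over-represented among synergy predictions.
#'
#' @param gi50 Drug-by-cell-line GI50 matrix.
#' @param drug_a,drug_b Drug ids.
#' @param lines Cell-line subset (default: all columns).
#' @inheritParams build_pair_features
#' @return Pearson correlation (NA when a profile is constant).
#' @export
pair_efficacy_correlation <- function(gi50, drug_a, drug_b,
                                      lines = colnames(gi50),
                                      transform = "log10") {
  ta <- transform_gi50(gi50[drug_a, lines], transform)
  tb <- transform_gi50(gi50[drug_b, lines], transform)
  if (stats::sd(ta) == 0 || stats::sd(tb) == 0) return(NA_real_)
  stats::cor(ta, tb)
}
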