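# Chou-Talalay combination index, plus Bliss excess as a secondary metric.
#
# At an observed combination effect fa, each drug's equipotent dose is
# Dx_i(fa) = Dm_i * (fa/(1-fa))^(1/m_i) from its single-agent fit, and
#   CI = d1 / Dx_1(fa) + d2 / Dx_2(fa)
# CI < 1 indicates synergy, 1 additivity, > 1 antagonism. Screens report
# log10(CI); the synergy call threshold applies on that scale. The mutually
# nonexclusive variant (third product term) is not computed.

#' Combination index for one measurement
#'
#' @param dose_a,dose_b Doses (uM) of the two drugs; at least one positive.
#' @param fa Observed combined fraction affected; clipped to the interior
#'   band before inversion.
#' @param fit_a,fit_b `medfit` objects for the two drugs in this cell line.
#' @param eps Interior clip half-width.
#' @param log_base Base of the reported log CI (default 10).
#' @return List with `ci`, `log_ci` and the clipped `fa`. If `fa` sits at
#'   the clip boundary the score is unreliable and `NA` is returned in both
#'   fields with `skipped = TRUE`.
#' @examples
#' fit <- structure(list(m = 1, Dm = 1), class = "medfit")
#' combination_index(0.5, 0.5, 0.5, fit, fit)$ci  # self-combination: CI = 1
#' @export
combination_index <- function(dose_a, dose_b, fa, fit_a, fit_b,
                              eps = 1e-3, log_base = 10) {
  if (dose_a < 0 || dose_b < 0) stop("doses must be non-negative", call. = FALSE)
  if (dose_a == 0 && dose_b == 0) {
    stop("both doses zero: no combination to score", call. = FALSE)
  }
  assert_fraction(fa, "fa")
  if (!is_interior(fa, eps)) {
    return(list(ci = NA_real_, log_ci = NA_real_, fa = clip_fraction(fa, eps),
                skipped = TRUE))
  }
  ci <- 0
  if (dose_a > 0) ci <- ci + dose_a / dose_for_effect(fit_a, fa)
  if (dose_b > 0) ci <- ci + dose_b / dose_for_effect(fit_b, fa)
  list(ci = ci, log_ci = log(ci, base = log_base), fa = fa, skipped = FALSE)
}

#' Score a whole combination screen
#'
#' Joins each combination measurement with the median-effect fits of its two
#' drugs in the same cell line and computes the combination index at every
#' (pair, cell line, dose pair). Replicate rows are averaged before scoring.
#' Rows whose drugs lack a fittable curve, or whose observed effect sits at
#' the interior-band boundary, are skipped and enumerated in a message.
#'
#' The combination index inherits its reliability from the single-agent
#' curves, so fits are quality-gated before use: a curve contributes only
#' when it has at least `min_points` interior dose points and a linear-fit
#' correlation of at least `min_r`. Rows backed by an unreliable curve are
#' skipped (and counted in the message) rather than scored.
#'
#' @param combination Data.frame with columns
#'   `drug_a, drug_b, cell_line, dose_a_uM, dose_b_uM, response`.
#' @param curves Output of [fit_screen_curves()].
#' @param eps Interior clip half-width.
#' @param log_base Base of the reported log CI.
#' @param min_points,min_r Fit-quality gate: minimum interior points and
#'   minimum absolute linear-fit correlation a curve needs to back a score.
#' @return Data.frame with one row per scorable (pair, cell line, dose pair):
#'   `pair, drug_a, drug_b, cell_line, dose_a_uM, dose_b_uM, fa, ci, log_ci`.
#' @export
score_combination_screen <- function(combination, curves, eps = 1e-3,
                                     log_base = 10, min_points = 3L,
                                     min_r = 0.9) {
  if (nrow(combination) == 0) {
    return(data.frame(pair = character(), drug_a = character(),
                      drug_b = character(), cell_line = character(),
                      dose_a_uM = numeric(), dose_b_uM = numeric(),
                      fa = numeric(), ci = numeric(), log_ci = numeric()))
  }
  combination <- canonicalize_pairs(combination)
  # average replicates at the same (pair, line, dose pair)
  key <- paste(combination$drug_a, combination$drug_b, combination$cell_line,
               combination$dose_a_uM, combination$dose_b_uM, sep = "\r")
  fa <- tapply(combination$response, key, mean)
  first <- combination[!duplicated(key), , drop = FALSE]
  first$response <- as.numeric(fa[paste(first$drug_a, first$drug_b,
                                        first$cell_line, first$dose_a_uM,
                                        first$dose_b_uM, sep = "\r")])
  ck <- paste(curves$drug, curves$cell_line, sep = "\r")
  ia <- match(paste(first$drug_a, first$cell_line, sep = "\r"), ck)
  ib <- match(paste(first$drug_b, first$cell_line, sep = "\r"), ck)
  reliable <- curves$fittable & curves$n_used >= min_points &
    !is.na(curves$r) & abs(curves$r) >= min_r
  fittable <- !is.na(ia) & !is.na(ib) & reliable[ia] & reliable[ib]
  interior <- is_interior(first$response, eps)
  ok <- fittable & interior
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    message(sprintf("score_combination_screen: skipped %d row(s) (%d unfittable curve, %d boundary effect)",
                    n_skip, sum(!fittable), sum(fittable & !interior)))
  }
  s <- first[ok, , drop = FALSE]
  ia <- ia[ok]; ib <- ib[ok]
  z <- s$response / (1 - s$response)
  dx_a <- curves$Dm[ia] * z^(1 / curves$m[ia])
  dx_b <- curves$Dm[ib] * z^(1 / curves$m[ib])
  ci <- ifelse(s$dose_a_uM > 0, s$dose_a_uM / dx_a, 0) +
    ifelse(s$dose_b_uM > 0, s$dose_b_uM / dx_b, 0)
  data.frame(pair = pair_id(s$drug_a, s$drug_b),
             drug_a = s$drug_a, drug_b = s$drug_b, cell_line = s$cell_line,
             dose_a_uM = s$dose_a_uM, dose_b_uM = s$dose_b_uM,
             fa = s$response, ci = ci, log_ci = log(ci, base = log_base),
             row.names = NULL)
}

#' Bliss excess over probabilistic independence
#'
#' Expected combined effect of independently acting drugs is
#' `e_a + e_b - e_a * e_b`; the excess of the observed combination effect
#' over it indicates synergy (positive) or antagonism (negative).
#'
#' @param e_a,e_b Single-agent effects in `[0,1]`.
#' @param e_ab Observed combination effect in `[0,1]`.
#' @return `e_ab - (e_a + e_b - e_a * e_b)`, vectorized.
#' @export
bliss_excess <- function(e_a, e_b, e_ab) {
  assert_fraction(e_a, "e_a")
  assert_fraction(e_b, "e_b")
  assert_fraction(e_ab, "e_ab")
  e_ab - (e_a + e_b - e_a * e_b)
}
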