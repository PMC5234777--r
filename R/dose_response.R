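# Median-effect (mass-action) dose-response model.
#
# fa / fu = (D / Dm)^m  with fu = 1 - fa, i.e.
# log(fa / (1 - fa)) = m * log(D) - m * log(Dm):
# linear in log-log coordinates, fitted by ordinary least squares.

#' Fit the median-effect model to one dose-response series
#'
#' Replicates at the same dose are averaged first. Averaged responses at or
#' beyond the interior band `(eps, 1 - eps)` carry no information after the
#' log-odds transform and are dropped from the fit; at least two interior
#' points are required.
#'
#' @param doses Positive dose vector (uM).
#' @param responses Fraction of growth inhibited in `[0,1]`, one per dose.
#' @param eps Interior clip half-width (default `1e-3`).
#' @return An object of class `medfit`: list with slope `m`, median-effect
#'   dose `Dm` (uM), linear-fit correlation `r`, `n_used` interior points and
#'   `max_dose`, the largest tested dose.
#' @examples
#' d <- c(0.5, 1, 2, 4)
#' fit <- fit_median_effect(d, d / (d + 1))
#' c(fit$m, fit$Dm)  # recovers m = 1, Dm = 1
#' @export
fit_median_effect <- function(doses, responses, eps = 1e-3) {
  if (length(doses) != length(responses)) {
    stop("doses and responses must have equal length", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be strictly positive", call. = FALSE)
  assert_fraction(responses, "response")
  # average replicates at identical doses
  fa <- tapply(responses, doses, mean)
  d <- as.numeric(names(fa))
  fa <- as.numeric(fa)
  keep <- is_interior(fa, eps)
  if (sum(keep) < 2) {
    stop(sprintf("unfittable series: %d interior point(s) after clipping, need >= 2",
                 sum(keep)), call. = FALSE)
  }
  x <- log10(d[keep])
  y <- log10(fa[keep] / (1 - fa[keep]))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || m == 0) {
    stop("degenerate fit: zero or undefined slope", call. = FALSE)
  }
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  structure(
    list(m = m, Dm = 10^(-b / m), r = r, n_used = sum(keep),
         max_dose = max(d)),
    class = "medfit")
}

#' @export
print.medfit <- function(x, ...) {
  cat(sprintf("median-effect fit: m = %.4g, Dm = %.4g uM (r = %.3f, n = %d)\n",
              x$m, x$Dm, x$r, x$n_used))
  invisible(x)
}

#' Dose producing a target inhibited fraction
#'
#' Inverts the fitted median-effect curve:
#' `D_x = Dm * (x / (1 - x))^(1/m)`. The GI50 is `dose_for_effect(fit, 0.5)`
#' which equals `Dm` by definition.
#'
#' @param fit A `medfit` object (or any list with `m` and `Dm`).
#' @param level Target inhibited fraction, strictly inside (0,1). Vectorized.
#' @return Dose(s) in uM.
#' @export
dose_for_effect <- function(fit, level) {
  if (any(level <= 0 | level >= 1)) {
    stop("effect level must lie strictly inside (0,1)", call. = FALSE)
  }
  if (fit$m == 0) stop("degenerate curve: m = 0 cannot be inverted", call. = FALSE)
  fit$Dm * (level / (1 - level))^(1 / fit$m)
}

#' Fit median-effect curves for a whole single-agent screen
#'
#' @param single_agent Long data.frame with columns
#'   `drug, cell_line, dose_uM, response`.
#' @param eps Interior clip (see [fit_median_effect()]).
#' @param levels Inhibited fractions reported as GI doses (default 10/25/50%).
#' @return Data.frame with one row per (drug, cell line): `m`, `Dm`, `r`,
#'   `n_used`, `max_dose`, GI columns (`gi10`, `gi25`, `gi50`, ...) and a
#'   `fittable` flag; unfittable series keep NA estimates.
#' @export
fit_screen_curves <- function(single_agent, eps = 1e-3,
                              levels = c(0.10, 0.25, 0.50)) {
  stopifnot(all(c("drug", "cell_line", "dose_uM", "response") %in%
                  names(single_agent)))
  keys <- unique(single_agent[c("drug", "cell_line")])
  keys <- keys[order(keys$drug, keys$cell_line), , drop = FALSE]
  idx <- split(seq_len(nrow(single_agent)),
               paste(single_agent$drug, single_agent$cell_line, sep = "\r"))
  gi_names <- sprintf("gi%d", round(levels * 100))
  out <- lapply(seq_len(nrow(keys)), function(i) {
    rows <- idx[[paste(keys$drug[i], keys$cell_line[i], sep = "\r")]]
    res <- tryCatch(
      fit_median_effect(single_agent$dose_uM[rows],
                        single_agent$response[rows], eps = eps),
      error = function(e) NULL)
    if (is.null(res)) {
      gi <- rep(NA_real_, length(levels))
      row <- data.frame(drug = keys$drug[i], cell_line = keys$cell_line[i],
                        m = NA_real_, Dm = NA_real_, r = NA_real_,
                        n_used = 0L,
                        max_dose = max(single_agent$dose_uM[rows]),
                        fittable = FALSE)
    } else {
      gi <- dose_for_effect(res, levels)
      row <- data.frame(drug = keys$drug[i], cell_line = keys$cell_line[i],
                        m = res$m, Dm = res$Dm, r = res$r,
                        n_used = res$n_used, max_dose = res$max_dose,
                        fittable = TRUE)
    }
    row[gi_names] <- as.list(gi)
    row
  })
  do.call(rbind, out)
}

#' GI50 matrix for a drug panel
#'
#' Collapses fitted curves to a drug-by-cell-line matrix of GI50 doses (uM).
#' Entries that are unfittable, or whose GI50 falls beyond
#' `cap_factor * max tested dose` (the drug never reaches 50% inhibition in
#' range), are imputed at `cap_factor * max_dose` and flagged. The imputation
#' preserves "weak drug" ordering in downstream features instead of
#' discarding the drug.
#'
#' @param curves Output of [fit_screen_curves()].
#' @param panel Optional panel data.frame (`cell_line`, `genotype`); when
#'   given, columns are ordered by genotype block (BRAF, RAS, WT) then id.
#' @param cap_factor Imputation cap as a multiple of the maximum tested dose.
#' @return Numeric matrix (drugs x cell lines) with an `"imputed"` logical
#'   matrix attribute.
#' @export
gi50_matrix <- function(curves, panel = NULL, cap_factor = 10) {
  stopifnot(all(c("drug", "cell_line", "gi50", "max_dose") %in% names(curves)))
  drugs <- sort(unique(curves$drug))
  lines <- if (is.null(panel)) sort(unique(curves$cell_line)) else
    order_cell_lines(panel)
  mat <- matrix(NA_real_, length(drugs), length(lines),
                dimnames = list(drugs, lines))
  imputed <- matrix(FALSE, length(drugs), length(lines),
                    dimnames = list(drugs, lines))
  ij <- cbind(match(curves$drug, drugs), match(curves$cell_line, lines))
  ok <- !is.na(ij[, 2])
  cap <- cap_factor * curves$max_dose
  gi <- curves$gi50
  flag <- is.na(gi) | gi > cap
  gi[flag] <- cap[flag]
  mat[ij[ok, , drop = FALSE]] <- gi[ok]
  imputed[ij[ok, , drop = FALSE]] <- flag[ok]
  if (anyNA(mat)) {
    # (drug, line) combinations never measured: impute at the drug's cap
    for (i in seq_along(drugs)) {
      miss <- is.na(mat[i, ])
      if (any(miss)) {
        drug_cap <- max(cap[curves$drug == drugs[i]])
        mat[i, miss] <- drug_cap
        imputed[i, miss] <- TRUE
      }
    }
  }
  attr(mat, "imputed") <- imputed
  mat
}

# Cell lines ordered by genotype block (BRAF, RAS, WT) then id; this fixed
# ordering is recorded with feature matrices so prediction-time data align
# by name, not position.
order_cell_lines <- function(panel) {
  g <- factor(panel$genotype, levels = GENOTYPES)
  panel$cell_line[order(g, panel$cell_line)]
}
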