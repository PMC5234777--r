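# Rule-based per-pair outcomes.
#
# Three boolean outcomes per drug pair:
#   synergy            — log10(CI) strictly below the cutoff at any tested
#                        dose pair (training rule; the validation variant is
#                        inclusive at the cutoff)
#   effective          — aggregate percent growth inhibition reaches the
#                        cutoff (boundary inclusive)
#   genotype-selective — the target genotype group's mean growth inhibition
#                        beats every other group by at least the margin AND
#                        reaches the floor

#' Synergy label from a collection of combination-index scores
#'
#' @param log_ci Vector of log-scale combination indices for one pair
#'   (all cell lines and dose pairs); NAs are dropped.
#' @param cutoff Synergy cutoff on the log CI scale (default -1); the
#'   comparison is strict (`<`).
#' @return TRUE when any score falls strictly below the cutoff.
#' @export
label_synergy <- function(log_ci, cutoff = -1) {
  log_ci <- log_ci[!is.na(log_ci)]
  if (length(log_ci) == 0) {
    stop("undefined synergy label: no scores for this pair", call. = FALSE)
  }
  any(log_ci < cutoff)
}

#' Validation-rule synergy label (inclusive at the cutoff)
#'
#' The training rule is strict; the validation rule counts a pair as
#' synergistic when it achieves a score of the cutoff in at least one
#' dose-level pair (`<=`). The asymmetry is deliberate and configurable.
#'
#' @inheritParams label_synergy
#' @return TRUE when any score is at or below the cutoff.
#' @export
label_synergy_validation <- function(log_ci, cutoff = -1) {
  log_ci <- log_ci[!is.na(log_ci)]
  if (length(log_ci) == 0) {
    stop("undefined synergy label: no scores for this pair", call. = FALSE)
  }
  any(log_ci <= cutoff)
}

#' Effectiveness label over a cell-line group
#'
#' @param gi_values Named vector of per-cell-line percent growth inhibition.
#' @param group Cell-line ids forming the group (default: all).
#' @param cutoff Percent growth inhibition required (boundary inclusive).
#' @return TRUE when the group mean reaches the cutoff.
#' @export
label_effective <- function(gi_values, group = names(gi_values), cutoff = 70) {
  if (is.null(group)) group <- seq_along(gi_values)
  vals <- if (is.character(group)) gi_values[group] else gi_values[group]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("empty cell-line group", call. = FALSE)
  mean(vals) >= cutoff
}

#' Effectiveness by the third quantile of observed inhibition
#'
#' Validation-screen rule: a combination is effective when the 0.75 quantile
#' of all its observed growth-inhibition values reaches the cutoff. The
#' quantile uses linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param gi_values Percent growth inhibition over all tested dose pairs.
#' @param cutoff Percent cutoff (boundary inclusive).
#' @return TRUE when Q3 >= cutoff.
#' @export
label_effective_q3 <- function(gi_values, cutoff = 70) {
  gi_values <- gi_values[!is.na(gi_values)]
  if (length(gi_values) == 0) stop("no growth-inhibition values", call. = FALSE)
  unname(stats::quantile(gi_values, 0.75, type = 7)) >= cutoff
}

#' Genotype-selectivity label
#'
#' @param gi_values Named vector of per-cell-line percent growth inhibition.
#' @param panel Data.frame with `cell_line` and `genotype`.
#' @param target Target genotype (`"BRAF"`, `"RAS"` or `"WT"`).
#' @param margin Minimum advantage (percentage points) of the target group's
#'   mean over every other genotype group's mean.
#' @param floor Minimum mean percent growth inhibition within the target
#'   group.
#' @return TRUE when both conditions hold.
#' @export
label_genotype_selective <- function(gi_values, panel, target,
                                     margin = 15, floor = 50) {
  stopifnot(target %in% GENOTYPES)
  geno <- panel$genotype[match(names(gi_values), panel$cell_line)]
  means <- tapply(gi_values, geno, mean, na.rm = TRUE)
  others <- setdiff(names(means), target)
  if (!(target %in% names(means)) || length(others) == 0) {
    stop("target group and at least one other genotype group must be non-empty",
         call. = FALSE)
  }
  all(means[target] - means[others] >= margin) && means[target] >= floor
}

#' Label every pair in a combination screen
#'
#' Combines the synergy rule (from combination-index scores) with the
#' effectiveness and genotype-selectivity rules (from combination
#' growth-inhibition values). Growth inhibition is first collapsed to one
#' value per (pair, cell line) over the tested dose pairs — by mean or by
#' the best achieved value, per `dose_agg` — then averaged within genotype
#' groups.
#'
#' @param scores Output of [score_combination_screen()].
#' @param combination Combination measurement table (fractions).
#' @param panel Panel data.frame (`cell_line`, `genotype`).
#' @param synergy_cutoff Log-CI cutoff (strict).
#' @param effective_cutoff Percent growth inhibition for effectiveness.
#' @param margin,floor Genotype-selectivity parameters.
#' @param dose_agg `"mean"` or `"max"`: per-cell-line collapse over dose pairs.
#' @return Data.frame with one row per pair: `pair`, `drug_a`, `drug_b`,
#'   `synergy`, `effective`, and `selective_<genotype>` /
#'   `effective_<genotype>` columns for every genotype present.
#' @export
label_screen <- function(scores, combination, panel,
                         synergy_cutoff = -1, effective_cutoff = 70,
                         margin = 15, floor = 50, dose_agg = c("mean", "max")) {
  dose_agg <- match.arg(dose_agg)
  combination <- canonicalize_pairs(combination)
  combination$pair <- pair_id(combination$drug_a, combination$drug_b)
  pairs <- unique(combination[c("pair", "drug_a", "drug_b")])
  pairs <- pairs[order(pairs$pair), , drop = FALSE]

  agg_fun <- if (dose_agg == "mean") mean else max
  # percent growth inhibition per (pair, cell line)
  key <- paste(combination$pair, combination$cell_line, sep = "\r")
  gi_cell <- tapply(100 * combination$response, key, agg_fun)

  genos <- intersect(GENOTYPES, unique(panel$genotype))
  lab <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs$pair[i]
    sc <- scores$log_ci[scores$pair == p]
    syn <- if (length(sc[!is.na(sc)])) label_synergy(sc, synergy_cutoff) else NA
    lines <- combination$cell_line[combination$pair == p]
    lines <- unique(lines)
    gi <- gi_cell[paste(p, lines, sep = "\r")]
    names(gi) <- lines
    row <- data.frame(pair = p, drug_a = pairs$drug_a[i],
                      drug_b = pairs$drug_b[i],
                      synergy = syn,
                      effective = label_effective(gi, cutoff = effective_cutoff))
    geno_here <- panel$genotype[match(lines, panel$cell_line)]
    for (g in genos) {
      grp <- lines[geno_here == g]
      row[[paste0("effective_", g)]] <-
        if (length(grp)) label_effective(gi, grp, effective_cutoff) else NA
      row[[paste0("selective_", g)]] <-
        if (length(grp) && length(setdiff(geno_here, g)))
          label_genotype_selective(gi, panel, g, margin, floor) else NA
    }
    row
  })
  out <- do.call(rbind, lab)
  rownames(out) <- NULL
  out
}
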