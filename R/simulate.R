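# Synthetic combinatorial screen generator with known ground truth.
#
# Single-agent curves follow the median-effect model
#   fa = D^m / (D^m + Dm^m)
# with per-(drug, cell line) parameters. The combination response at a dose
# pair (d1, d2) is the fa solving
#   d1 / Dx_a(fa) + d2 / Dx_b(fa) = 1 / gamma
# so the true Chou-Talalay combination index at every dose pair equals
# 1/gamma by construction: gamma = 1 is exact Loewe additivity, gamma > 1 a
# planted synergist with log10(CI) = -log10(gamma). Measurement noise is
# Gaussian on the response scale; replicates are simulated and averaged,
# then clipped into [0,1].
#
# Synergy is made learnable from single-agent features: drug potency
# profiles share a latent cell-line factor, and pairs whose profiles are
# weakly correlated across the mutant-BRAF lines get an elevated synergy
# probability (the rule's quantile and probabilities live in the config).

#' Simulator configuration
#'
#' Defaults mirror a melanoma combination screen: a 27-line panel
#' (15 BRAF / 6 RAS / 6 WT) with combinations measured in a 19-line subset
#' (8 / 6 / 5), 40 drugs (780 tested pairs), four-point 1:10 single-agent
#' dilution series measured in triplicate, and a 3x3 combination dose grid
#' anchored at each drug's GI10 / GI25 / GI50 in each cell line.
#'
#' @param n_braf,n_ras,n_wt Cell lines per genotype in the single-agent
#'   panel.
#' @param combo_braf,combo_ras,combo_wt Cell lines per genotype measured in
#'   the combination screen (subsets of the panel).
#' @param n_drugs Number of drugs; all pairs are tested.
#' @param m_range Uniform range of the median-effect slope m.
#' @param dm_log10_range Uniform range of the drug-level log10 median-effect
#'   dose (decades of uM).
#' @param latent_sd Scale of the latent cell-line factor shaping potency
#'   profiles (log10 units).
#' @param profile_noise Residual per-(drug, line) profile spread (log10
#'   units).
#' @param selective_fraction Fraction of drugs given genotype-selective
#'   potency.
#' @param selective_genotype Genotype in which selective drugs are more
#'   potent.
#' @param selective_divisor Factor dividing Dm in the target genotype.
#' @param n_doses,dilution Single-agent dose grid: `n_doses`-point serial
#'   dilution with this factor, anchored at the drug's base potency.
#' @param combo_levels Inhibited fractions anchoring each drug's combination
#'   doses (low / medium / high).
#' @param corr_quantile Pairs whose BRAF-profile correlation falls below
#'   this quantile get the elevated synergy probability.
#' @param p_high,p_low Synergy probabilities for weakly- vs
#'   strongly-correlated pairs.
#' @param gamma_log10_range log10 range of the planted interaction potency
#'   gamma for synergistic pairs (others get gamma = 1).
#' @param fixed_gamma When non-NULL, every pair gets exactly this gamma
#'   (used for calibration checks).
#' @param noise_sd Gaussian noise standard deviation on the response scale.
#' @param replicates Technical replicates simulated and averaged.
#' @param seed Integer seed; the whole screen is a deterministic function of
#'   the configuration.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_braf = 15L, n_ras = 6L, n_wt = 6L,
                       combo_braf = 8L, combo_ras = 6L, combo_wt = 5L,
                       n_drugs = 40L,
                       m_range = c(0.8, 2.5),
                       dm_log10_range = c(-1, 1),
                       latent_sd = 0.5, profile_noise = 0.15,
                       selective_fraction = 0.2,
                       selective_genotype = "BRAF",
                       selective_divisor = 8,
                       n_doses = 4L, dilution = 10,
                       combo_levels = c(0.10, 0.25, 0.50),
                       corr_quantile = 0.25, p_high = 1.0, p_low = 0.02,
                       gamma_log10_range = c(1.1, 1.5),
                       fixed_gamma = NULL,
                       noise_sd = 0.05, replicates = 3L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_braf > 0, n_ras > 0, n_wt > 0, n_drugs >= 2,
            combo_braf <= n_braf, combo_ras <= n_ras, combo_wt <= n_wt,
            noise_sd >= 0, replicates >= 1,
            is.null(fixed_gamma) || fixed_gamma >= 1,
            all(gamma_log10_range >= 0))
  class(cfg) <- c("sim_config", "list")
  cfg
}

# Vectorized bisection for the combination response: solves
# d1 / Dx_a(fa) + d2 / Dx_b(fa) = 1 / gamma for fa, on the log-odds scale
# t = log10(fa / (1 - fa)). The left side is strictly decreasing in t, so
# the bracket [-12, 12] always contains the unique root.
solve_combo_fa <- function(d1, d2, m_a, dm_a, m_b, dm_b, gamma,
                           iterations = 70L) {
  lhs <- function(t) {
    d1 / (dm_a * 10^(t / m_a)) + d2 / (dm_b * 10^(t / m_b)) - 1 / gamma
  }
  lo <- rep(-12, length(d1))
  hi <- rep(12, length(d1))
  if (any(lhs(lo) < 0) || any(lhs(hi) > 0)) {
    stop("combination response bracket unsatisfiable; check doses and gamma",
         call. = FALSE)
  }
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    pos <- lhs(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  t <- (lo + hi) / 2
  1 / (1 + 10^(-t))
}

# Noisy measurement: mean of `reps` Gaussian replicates, clipped to [0,1].
measure <- function(fa_true, noise_sd, reps) {
  if (noise_sd == 0) return(fa_true)
  n <- length(fa_true)
  noise <- rowMeans(matrix(stats::rnorm(n * reps, 0, noise_sd), n, reps))
  pmin(pmax(fa_true + noise, 0), 1)
}

#' Simulate a full combinatorial screen
#'
#' Generates the three standard tables (single-agent, combination, panel)
#' plus a ground-truth record. Deterministic given the configuration,
#' including its seed.
#'
#' @param config A [sim_config()] list.
#' @return An object of class `sim_screen`: list with `single_agent`,
#'   `combination` (both carrying a noiseless `response_true` column),
#'   `panel`, and `truth` — per-pair gamma / true log10 CI / BRAF-profile
#'   correlation / planted synergy flag, per-drug curve parameters and
#'   selectivity, the true log10 Dm matrix, and the config.
#' @export
simulate_screen <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)

  panel <- data.frame(
    cell_line = c(sprintf("BRAF%02d", seq_len(cfg$n_braf)),
                  sprintf("RAS%02d", seq_len(cfg$n_ras)),
                  sprintf("WT%02d", seq_len(cfg$n_wt))),
    genotype = rep(GENOTYPES, c(cfg$n_braf, cfg$n_ras, cfg$n_wt)))
  combo_lines <- c(sprintf("BRAF%02d", seq_len(cfg$combo_braf)),
                   sprintf("RAS%02d", seq_len(cfg$combo_ras)),
                   sprintf("WT%02d", seq_len(cfg$combo_wt)))
  n_lines <- nrow(panel)
  drugs <- sprintf("D%03d", seq_len(cfg$n_drugs))

  # per-drug curve parameters and latent profile structure
  m_drug <- stats::setNames(stats::runif(cfg$n_drugs, cfg$m_range[1],
                                         cfg$m_range[2]), drugs)
  b_drug <- stats::setNames(stats::runif(cfg$n_drugs, cfg$dm_log10_range[1],
                                         cfg$dm_log10_range[2]), drugs)
  # bimodal loadings: every drug engages the latent axis with a clear sign,
  # so profile correlations separate into similar vs opposing mechanisms and
  # the near-zero-delta region (similar drugs, shams) is unambiguous
  u_drug <- stats::setNames(sample(c(-1, 1), cfg$n_drugs, replace = TRUE) *
                              stats::runif(cfg$n_drugs, 0.5, 1), drugs)
  v_line <- stats::setNames(stats::rnorm(n_lines), panel$cell_line)
  eps_profile <- matrix(stats::rnorm(cfg$n_drugs * n_lines, 0,
                                     cfg$profile_noise),
                        cfg$n_drugs, n_lines,
                        dimnames = list(drugs, panel$cell_line))
  dm_log10 <- outer(b_drug, rep(1, n_lines)) +
    cfg$latent_sd * outer(u_drug, v_line) + eps_profile
  colnames(dm_log10) <- panel$cell_line

  # genotype-selective drugs: more potent (smaller Dm) in the target group
  n_sel <- round(cfg$selective_fraction * cfg$n_drugs)
  selective <- stats::setNames(rep(FALSE, cfg$n_drugs), drugs)
  if (n_sel > 0) {
    selective[sample(drugs, n_sel)] <- TRUE
    target_lines <- panel$cell_line[panel$genotype == cfg$selective_genotype]
    dm_log10[selective, target_lines] <-
      dm_log10[selective, target_lines] - log10(cfg$selective_divisor)
  }

  # single-agent screen: fixed per-drug serial dilution across all lines
  exps <- seq_len(cfg$n_doses) - (cfg$n_doses - 1L)
  sa <- expand.grid(dose_idx = seq_len(cfg$n_doses),
                    cell_line = panel$cell_line, drug = drugs,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sa$dose_uM <- 10^(b_drug[sa$drug]) * cfg$dilution^(exps[sa$dose_idx])
  dm <- 10^dm_log10[cbind(sa$drug, sa$cell_line)]
  mm <- m_drug[sa$drug]
  sa$response_true <- sa$dose_uM^mm / (sa$dose_uM^mm + dm^mm)
  sa$response <- measure(sa$response_true, cfg$noise_sd, cfg$replicates)
  single_agent <- sa[c("drug", "cell_line", "dose_uM", "response",
                       "response_true")]

  # tested pairs and planted interactions
  cmb <- utils::combn(drugs, 2)
  pairs <- data.frame(drug_a = cmb[1, ], drug_b = cmb[2, ])
  braf_lines <- panel$cell_line[panel$genotype == "BRAF"]
  prof <- dm_log10[, braf_lines, drop = FALSE]
  rho <- stats::cor(t(prof))
  pairs$rho_braf <- rho[cbind(pairs$drug_a, pairs$drug_b)]
  if (is.null(cfg$fixed_gamma)) {
    thr <- stats::quantile(pairs$rho_braf, cfg$corr_quantile, type = 7)
    p_syn <- ifelse(pairs$rho_braf <= thr, cfg$p_high, cfg$p_low)
    syn <- stats::runif(nrow(pairs)) < p_syn
    gamma <- ifelse(syn, 10^stats::runif(nrow(pairs),
                                         cfg$gamma_log10_range[1],
                                         cfg$gamma_log10_range[2]), 1)
  } else {
    gamma <- rep(cfg$fixed_gamma, nrow(pairs))
  }
  pairs$gamma <- gamma
  pairs$log_ci_true <- -log10(gamma)
  pairs$planted_synergy <- log10(gamma) > 1  # strict -1 cutoff on log10 CI
  pairs$pair <- pair_id(pairs$drug_a, pairs$drug_b)

  # combination screen: 3x3 grid at each drug's GI levels in each line
  grid <- expand.grid(lev_b = cfg$combo_levels, lev_a = cfg$combo_levels,
                      cell_line = combo_lines, pair_idx = seq_len(nrow(pairs)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  da <- pairs$drug_a[grid$pair_idx]
  db <- pairs$drug_b[grid$pair_idx]
  dm_a <- 10^dm_log10[cbind(da, grid$cell_line)]
  dm_b <- 10^dm_log10[cbind(db, grid$cell_line)]
  m_a <- m_drug[da]
  m_b <- m_drug[db]
  d1 <- dm_a * (grid$lev_a / (1 - grid$lev_a))^(1 / m_a)
  d2 <- dm_b * (grid$lev_b / (1 - grid$lev_b))^(1 / m_b)
  fa_true <- solve_combo_fa(d1, d2, m_a, dm_a, m_b, dm_b,
                            pairs$gamma[grid$pair_idx])
  combination <- data.frame(
    drug_a = da, drug_b = db, cell_line = grid$cell_line,
    dose_a_uM = d1, dose_b_uM = d2,
    response = measure(fa_true, cfg$noise_sd, cfg$replicates),
    response_true = fa_true)

  structure(list(
    single_agent = single_agent,
    combination = combination,
    panel = panel,
    truth = list(
      pairs = pairs[c("pair", "drug_a", "drug_b", "gamma", "log_ci_true",
                      "rho_braf", "planted_synergy")],
      drugs = data.frame(drug = drugs, m = unname(m_drug),
                         dm_log10_base = unname(b_drug),
                         loading = unname(u_drug),
                         selective = unname(selective)),
      dm_log10 = dm_log10,
      combo_lines = combo_lines,
      config = cfg)),
    class = "sim_screen")
}

#' @export
print.sim_screen <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("simulated screen: %d drugs, %d cell lines (%d in combinations), %d pairs, seed %d\n",
              cfg$n_drugs, nrow(x$panel), length(x$truth$combo_lines),
              nrow(x$truth$pairs), cfg$seed))
  invisible(x)
}

#' Ground-truth labels implied by the simulator
#'
#' Applies the labelling rules to the simulator's noiseless responses and
#' analytic combination indices (log10 CI = -log10 gamma at every dose
#' pair), giving the recovery target the pipeline should reproduce.
#'
#' @param sim A `sim_screen` object.
#' @param synergy_cutoff,effective_cutoff,margin,floor,dose_agg Labelling
#'   thresholds, as in [label_screen()].
#' @return PairLabels data.frame as produced by [label_screen()].
#' @export
truth_labels <- function(sim, synergy_cutoff = -1, effective_cutoff = 70,
                         margin = 15, floor = 50, dose_agg = "mean") {
  stopifnot(inherits(sim, "sim_screen"))
  combo <- sim$combination
  combo$response <- combo$response_true
  scores <- data.frame(
    pair = pair_id(combo$drug_a, combo$drug_b),
    log_ci = sim$truth$pairs$log_ci_true[
      match(pair_id(combo$drug_a, combo$drug_b), sim$truth$pairs$pair)])
  label_screen(scores, combo, sim$panel,
               synergy_cutoff = synergy_cutoff,
               effective_cutoff = effective_cutoff,
               margin = margin, floor = floor, dose_agg = dose_agg)
}
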