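# Independent oracles used to check the main implementation paths, plus a
# small simulator configuration for fast tests.

# Closed-form ordinary-least-squares fit of the median-effect line,
# written from the normal equations (independent of the lm-based path).
ols_median_effect_oracle <- function(doses, fa) {
  x <- log10(doses)
  y <- log10(fa / (1 - fa))
  mx <- mean(x); my <- mean(y)
  m <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  b <- my - m * mx
  list(m = m, Dm = 10^(-b / m))
}

# Two-term closed-form combination index.
ci_oracle <- function(d1, d2, fa, m1, dm1, m2, dm2) {
  dx1 <- dm1 * (fa / (1 - fa))^(1 / m1)
  dx2 <- dm2 * (fa / (1 - fa))^(1 / m2)
  d1 / dx1 + d2 / dx2
}

# Brute-force all-pairs concordance count (Mann-Whitney AUC), ties = 1/2.
auc_oracle <- function(probs, labels) {
  pos <- probs[as.logical(labels)]
  neg <- probs[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Brute-force two-sample KS statistic by sweeping the pooled ECDFs.
ks_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}

# Small screen for fast tests: 8 lines (4 BRAF / 2 RAS / 2 WT), 6 drugs,
# 15 pairs.
tiny_sim_config <- function(...) {
  sim_config(n_braf = 4L, n_ras = 2L, n_wt = 2L,
             combo_braf = 3L, combo_ras = 2L, combo_wt = 2L,
             n_drugs = 6L, ...)
}

# Write a data.frame to a temporary csv and return the path.
tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
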