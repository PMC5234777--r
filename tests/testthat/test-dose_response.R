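test_that("median-effect fit recovers exact model parameters", {
  d <- c(0.5, 1, 2, 4)
  fit <- fit_median_effect(d, d / (d + 1))  # m = 1, Dm = 1
  expect_equal(fit$m, 1, tolerance = 1e-9)
  expect_equal(fit$Dm, 1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$n_used, 4L)

  # general (m, Dm): fa = D^m / (D^m + Dm^m)
  m <- 1.7; dm <- 3.2
  fa <- d^m / (d^m + dm^m)
  fit <- fit_median_effect(d, fa)
  expect_equal(fit$m, m, tolerance = 1e-9)
  expect_equal(fit$Dm, dm, tolerance = 1e-9)
})

test_that("boundary responses are clipped out and degenerate series refused", {
  expect_error(fit_median_effect(c(1, 2), c(0, 1)), "unfittable")
  expect_error(fit_median_effect(c(1, 2, 4), c(0, 0.5, 1)), "unfittable")
  expect_error(fit_median_effect(c(-1, 2), c(0.3, 0.6)), "positive")
  # replicates at the same dose are averaged before fitting
  fit <- fit_median_effect(c(1, 1, 2, 2), c(0.45, 0.55, 2 / 3, 2 / 3))
  expect_equal(fit$n_used, 2L)
  expect_equal(fit$Dm, 1, tolerance = 1e-9)
})

test_that("noisy fits agree with an independent least-squares oracle", {
  set.seed(401)
  for (i in 1:10) {
    d <- 10^seq(-1.5, 1, length.out = 6)
    m <- runif(1, 0.8, 2.5); dm <- 10^runif(1, -0.5, 0.5)
    fa <- d^m / (d^m + dm^m)
    fa <- pmin(pmax(fa + rnorm(6, 0, 0.02), 0.005), 0.995)
    fit <- fit_median_effect(d, fa)
    oracle <- ols_median_effect_oracle(d, fa)
    expect_equal(fit$m, oracle$m, tolerance = 1e-10)
    expect_equal(fit$Dm, oracle$Dm, tolerance = 1e-10)
  }
})

test_that("dose_for_effect inverts the curve and is monotone", {
  fit <- structure(list(m = 1, Dm = 2), class = "medfit")
  expect_equal(dose_for_effect(fit, 0.5), 2)    # GI50 = Dm by definition
  expect_equal(dose_for_effect(fit, 0.75), 6)   # 2 * 3
  fit2 <- structure(list(m = 2, Dm = 1), class = "medfit")
  expect_equal(dose_for_effect(fit2, 0.9), 3)   # sqrt(9)
  expect_error(dose_for_effect(fit, 1.2), "inside")
  expect_error(dose_for_effect(structure(list(m = 0, Dm = 1), class = "medfit"),
                               0.5), "degenerate")
  # GI10 < GI25 < GI50 whenever m > 0
  gi <- dose_for_effect(fit2, c(0.10, 0.25, 0.50))
  expect_true(all(diff(gi) > 0))
})

test_that("fit and inversion are scale-equivariant and round-trip", {
  set.seed(402)
  for (i in 1:20) {
    m <- runif(1, 0.5, 3); dm <- 10^runif(1, -1, 1); c0 <- 10^runif(1, -2, 2)
    d <- dm * 10^seq(-1, 1, length.out = 5)
    fa <- d^m / (d^m + dm^m)
    fit <- fit_median_effect(d, fa)
    fit_scaled <- fit_median_effect(c0 * d, fa)
    expect_equal(fit_scaled$m, fit$m, tolerance = 1e-8)
    expect_equal(fit_scaled$Dm, c0 * fit$Dm, tolerance = 1e-8)
    # round-trip: the fitted curve reproduces the generating curve
    x <- runif(3, 0.05, 0.95)
    expect_equal(dose_for_effect(fit, x), dm * (x / (1 - x))^(1 / m),
                 tolerance = 1e-8)
  }
})

test_that("screen-level fitting flags unfittable series", {
  sa <- rbind(
    data.frame(drug = "d1", cell_line = "c1", dose_uM = c(0.5, 1, 2, 4),
               response = c(0.5, 1, 2, 4) / c(1.5, 2, 3, 5)),
    data.frame(drug = "d1", cell_line = "c2", dose_uM = c(1, 2),
               response = c(0, 1)))
  curves <- fit_screen_curves(sa)
  expect_equal(nrow(curves), 2)
  expect_true(curves$fittable[curves$cell_line == "c1"])
  expect_false(curves$fittable[curves$cell_line == "c2"])
  expect_equal(curves$gi50[curves$cell_line == "c1"], 1, tolerance = 1e-9)
})

test_that("gi50 matrix imputes unreachable entries at the cap and flags them", {
  doses <- c(0.5, 1, 2, 4)
  mk <- function(drug, line, m, dm) {
    data.frame(drug = drug, cell_line = line, dose_uM = doses,
               response = doses^m / (doses^m + dm^m))
  }
  sa <- rbind(mk("d1", "c1", 1, 1), mk("d1", "c2", 1, 2), mk("d1", "c3", 1, 4),
              mk("d2", "c1", 2, 1), mk("d2", "c2", 2, 2),
              # unfittable in c3: flat boundary responses
              data.frame(drug = "d2", cell_line = "c3", dose_uM = doses,
                         response = c(0, 0, 1, 1)))
  curves <- fit_screen_curves(sa)
  mat <- gi50_matrix(curves)
  expect_equal(dim(mat), c(2, 3))
  expect_equal(mat["d1", "c2"], 2, tolerance = 1e-8)
  # unfittable entry imputed at 10 * max tested dose and flagged
  expect_equal(mat["d2", "c3"], 40)
  expect_true(attr(mat, "imputed")["d2", "c3"])
  expect_false(any(attr(mat, "imputed")[1, ]))
})

test_that("gi50 matrix matches the simulator's analytic values on noiseless data", {
  cfg <- tiny_sim_config(noise_sd = 0, seed = 5L)
  sim <- simulate_screen(cfg)
  curves <- fit_screen_curves(sim$single_agent)
  mat <- gi50_matrix(curves, sim$panel)
  truth <- 10^sim$truth$dm_log10  # analytic GI50 = Dm
  imputed <- attr(mat, "imputed")
  for (d in rownames(mat)) for (l in colnames(mat)) {
    if (!imputed[d, l]) {
      expect_equal(mat[d, l], truth[d, l], tolerance = 1e-4)
    }
  }
  # genotype-block column ordering: BRAF lines first
  expect_match(colnames(mat)[1], "^BRAF")
})
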