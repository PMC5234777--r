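test_that("single-agent reader parses, validates and normalizes", {
  df <- data.frame(drug = "d1", cell_line = "c1",
                   dose_uM = c(0.1, 1, 10, 100),
                   response = c(0.05, 0.3, 0.7, 0.95))
  got <- read_single_agent_table(tmp_csv(df))
  expect_equal(nrow(got), 4)
  expect_equal(got$response, df$response)

  # malformed header names the missing column
  bad <- df; names(bad)[3] <- "dose"
  expect_error(read_single_agent_table(tmp_csv(bad)), "dose_uM")

  # out-of-range response cites the row
  bad <- df; bad$response[2] <- 1.2
  expect_error(read_single_agent_table(tmp_csv(bad)), "row 2")

  # empty file with valid header: empty collection plus a warning
  empty <- df[0, ]
  expect_warning(got <- read_single_agent_table(tmp_csv(empty)), "no data rows")
  expect_equal(nrow(got), 0)

  # percent-scale input is auto-detected and rescaled
  pct <- df; pct$response <- c(5, 30, 70, 95)
  expect_message(got <- read_single_agent_table(tmp_csv(pct)), "percent")
  expect_equal(got$response, df$response)

  # rows with missing values are dropped with a count
  holey <- df; holey$response[1] <- NA
  expect_message(got <- read_single_agent_table(tmp_csv(holey)), "1 row")
  expect_equal(nrow(got), 3)
})

test_that("combination reader canonicalizes pairs and keeps replicates", {
  df <- data.frame(drug_a = c("b", "a", "a"), drug_b = c("a", "b", "b"),
                   cell_line = "c1",
                   dose_a_uM = c(1, 2, 2), dose_b_uM = c(4, 3, 3),
                   response = c(0.5, 0.6, 0.62))
  got <- read_combination_table(tmp_csv(df))
  expect_true(all(got$drug_a == "a" & got$drug_b == "b"))
  # doses travel with their drug on swap: (b@1, a@4) becomes (a@4, b@1)
  expect_true(any(got$dose_a_uM == 4 & got$dose_b_uM == 1))
  # duplicate (pair, line, dose pair) rows kept as replicates
  expect_equal(sum(got$dose_a_uM == 2 & got$dose_b_uM == 3), 2)

  bad <- df; bad$dose_a_uM[1] <- 0; bad$dose_b_uM[1] <- 0
  expect_error(read_combination_table(tmp_csv(bad)), "both doses zero")

  sham <- df; sham$drug_b <- sham$drug_a
  expect_error(read_combination_table(tmp_csv(sham)), "itself")
  expect_silent(got <- read_combination_table(tmp_csv(sham), allow_sham = TRUE))
  expect_equal(nrow(got), 3)
})

test_that("pair canonicalization is idempotent and order-insensitive", {
  df1 <- data.frame(drug_a = c("x", "b"), drug_b = c("a", "y"))
  once <- canonicalize_pairs(df1)
  expect_identical(canonicalize_pairs(once), once)
  expect_identical(pair_id("b", "a"), pair_id("a", "b"))
})

test_that("screen tables round-trip through write and read", {
  cfg <- tiny_sim_config(seed = 3L)
  sim <- simulate_screen(cfg)
  sa_path <- tempfile(fileext = ".csv")
  write_screen_table(sim$single_agent, sa_path)
  back <- read_single_agent_table(sa_path)
  expect_equal(back$response, sim$single_agent$response, tolerance = 1e-12)

  co_path <- tempfile(fileext = ".csv")
  write_screen_table(sim$combination, co_path)
  back <- read_combination_table(co_path)
  expect_equal(nrow(back), nrow(sim$combination))

  pn_path <- tempfile(fileext = ".csv")
  write_screen_table(sim$panel, pn_path)
  expect_identical(read_panel_table(pn_path), sim$panel)
})

test_that("panel reader enforces the genotype vocabulary and unique ids", {
  ok <- data.frame(cell_line = c("c1", "c2"), genotype = c("BRAF", "WT"))
  expect_equal(nrow(read_panel_table(tmp_csv(ok))), 2)
  dup <- data.frame(cell_line = c("c1", "c1"), genotype = c("BRAF", "WT"))
  expect_error(read_panel_table(tmp_csv(dup)), "duplicated")
  bad <- data.frame(cell_line = c("c1", "c2"), genotype = c("BRAF", "NRAS"))
  expect_error(read_panel_table(tmp_csv(bad)), "genotype")
})

test_that("prediction writer validates probabilities and round-trips", {
  preds <- data.frame(pair = c("a|b", "a|c", "b|c"),
                      p_synergy = c(0.9, 0.2, 0.5),
                      p_effective = c(0.8, 0.1, 0.4),
                      p_selective = c(0.7, 0.3, 0.6),
                      call_synergy = c(TRUE, FALSE, TRUE),
                      call_effective = c(TRUE, FALSE, FALSE),
                      call_selective = c(TRUE, FALSE, TRUE))
  path <- tempfile(fileext = ".csv")
  write_predictions(preds, path, seed = 42)
  back <- read_predictions(path)
  expect_equal(back$call_synergy, preds$call_synergy)
  expect_equal(back$p_synergy, preds$p_synergy, tolerance = 1e-12)
  expect_match(readLines(path, n = 1), "seed: 42")

  bad <- preds; bad$p_synergy[1] <- 1.2
  expect_error(write_predictions(bad, path), "outside")
  expect_error(write_predictions(preds[-2], path), "missing column")
})
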