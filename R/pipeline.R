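# End-to-end orchestration: simulate -> fit-curves -> score-synergy ->
# label -> featurize -> cross-validate -> predict -> sham-check.
# Every stage's output can be persisted as delimited text; the whole run is
# a deterministic function of (config, seed).

#' Train the per-outcome models and predict every pair
#'
#' Trains one independent random forest per outcome (synergy, general
#' effectiveness, genotype-selectivity) on the labelled pairs and returns
#' per-pair probabilities and hard calls. Outcomes with a single observed
#' class cannot be modelled and yield NA columns with a message.
#'
#' @param X Feature matrix (pairs x features) for the labelled pairs.
#' @param labels PairLabels data.frame from [label_screen()], aligned with
#'   the rows of `X` by pair id.
#' @param newX Feature matrix of pairs to predict (default: `X`).
#' @param selective_genotype Which `selective_<genotype>` column backs the
#'   `p_selective` output.
#' @param threshold Vote threshold for hard calls.
#' @param ntree,mtry Forest hyperparameters.
#' @param seed Integer seed.
#' @return List with `predictions` (data.frame ready for
#'   [write_predictions()]) and `models` (named list of `rf_bundle`s).
#' @export
predict_pairs <- function(X, labels, newX = X, selective_genotype = "BRAF",
                          threshold = 0.5, ntree = 500L, mtry = NULL,
                          seed = 1L) {
  stopifnot(all(rownames(X) == labels$pair))
  sel_col <- paste0("selective_", selective_genotype)
  outcomes <- c(synergy = "synergy", effective = "effective",
                selective = sel_col)
  models <- list()
  preds <- data.frame(pair = rownames(newX))
  for (nm in names(outcomes)) {
    y <- labels[[outcomes[[nm]]]]
    p <- rep(NA_real_, nrow(newX))
    ok <- !is.na(y)
    if (sum(ok) >= 2 && length(unique(y[ok])) == 2) {
      bundle <- train_model(X[ok, , drop = FALSE], y[ok],
                            outcome = outcomes[[nm]], ntree = ntree,
                            mtry = mtry, seed = seed)
      models[[nm]] <- bundle
      p <- predict(bundle, newX)
    } else {
      message(sprintf("predict_pairs: outcome '%s' has a single class; emitting NA",
                      outcomes[[nm]]))
    }
    preds[[paste0("p_", nm)]] <- p
    preds[[paste0("call_", nm)]] <- p >= threshold
  }
  list(predictions = preds, models = models)
}

#' Run the whole pipeline end to end on a simulated screen
#'
#' Executes simulate, fit-curves, score-synergy, label, featurize,
#' cross-validate, predict and sham-check in order. When `out_dir` is given
#' every stage's output is persisted as a delimited text table; rerunning
#' with the same configuration and seed reproduces each file byte for byte.
#'
#' @param config Pipeline configuration from [default_config()]; the
#'   simulator draws its seed from `config$seed`.
#' @param out_dir Optional output directory (created if needed).
#' @return List of class `screen_run` with all stage objects: `sim`,
#'   `curves`, `scores`, `labels`, `gi50`, `features`, `cv` (eval reports
#'   per modelled outcome), `predicted` and `sham`.
#' @export
run_end_to_end <- function(config = default_config(), out_dir = NULL) {
  cfg <- config
  cfg$sim$seed <- cfg$seed

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sim <- stage("simulate", simulate_screen(cfg$sim))
  curves <- stage("fit-curves",
                  fit_screen_curves(sim$single_agent,
                                    eps = cfg$dose_response$eps))
  scores <- stage("score-synergy",
                  score_combination_screen(sim$combination, curves,
                                           eps = cfg$dose_response$eps,
                                           log_base = cfg$log_base,
                                           min_points = cfg$dose_response$min_points,
                                           min_r = cfg$dose_response$min_r))
  labels <- stage("label",
                  label_screen(scores, sim$combination, sim$panel,
                               synergy_cutoff = cfg$labels$synergy_cutoff,
                               effective_cutoff = cfg$labels$effective_cutoff,
                               margin = cfg$labels$selective_margin,
                               floor = cfg$labels$selective_floor,
                               dose_agg = cfg$labels$dose_agg))
  gi50 <- stage("featurize",
                gi50_matrix(curves, sim$panel,
                            cap_factor = cfg$dose_response$gi50_cap_factor))
  X <- stage("featurize",
             featurize_pairs(gi50, labels[c("drug_a", "drug_b")],
                             transform = cfg$features$transform,
                             signed_delta = cfg$features$signed_delta))
  X <- X[labels$pair, , drop = FALSE]

  cv <- list()
  for (oc in c("synergy", "effective")) {
    y <- labels[[oc]]
    if (length(unique(y[!is.na(y)])) == 2) {
      cv[[oc]] <- stage("cross-validate",
                        cross_validate(X[!is.na(y), , drop = FALSE],
                                       y[!is.na(y)],
                                       k = cfg$model$k,
                                       threshold = cfg$model$threshold,
                                       seed = cfg$seed, outcome = oc,
                                       ntree = cfg$model$ntree,
                                       mtry = cfg$model$mtry,
                                       stratified = cfg$model$stratified))
    }
  }

  predicted <- stage("predict",
                     predict_pairs(X, labels,
                                   threshold = cfg$model$threshold,
                                   ntree = cfg$model$ntree,
                                   mtry = cfg$model$mtry, seed = cfg$seed))
  sham <- if (!is.null(predicted$models$synergy)) {
    stage("sham-check",
          sham_control(predicted$models$synergy, gi50,
                       threshold = cfg$model$threshold,
                       transform = cfg$features$transform))
  } else NULL

  run <- structure(list(sim = sim, curves = curves, scores = scores,
                        labels = labels, gi50 = gi50, features = X, cv = cv,
                        predicted = predicted, sham = sham, config = cfg),
                   class = "screen_run")
  if (!is.null(out_dir)) persist_run(run, out_dir)
  run
}

# Write all eight stage outputs as delimited text under out_dir.
persist_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_screen_table(run$sim$single_agent, p("01_single_agent.csv"))
  write_screen_table(run$sim$combination, p("01_combination.csv"))
  write_screen_table(run$sim$panel, p("01_panel.csv"))
  write_screen_table(run$sim$truth$pairs, p("01_truth_pairs.csv"))
  write_screen_table(run$curves, p("02_curves.csv"))
  write_screen_table(run$scores, p("03_scores.csv"))
  write_screen_table(run$labels, p("04_labels.csv"))
  feat <- data.frame(pair = rownames(run$features), run$features,
                     check.names = FALSE)
  write_screen_table(feat, p("05_features.csv"))
  cv_rows <- do.call(rbind, lapply(names(run$cv), function(oc) {
    r <- run$cv[[oc]]
    data.frame(outcome = oc, auc = r$auc, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               fdr = r$fdr, k = r$k, seed = r$seed)
  }))
  if (!is.null(cv_rows)) write_screen_table(cv_rows, p("06_cross_validation.csv"))
  write_predictions(run$predicted$predictions, p("07_predictions.csv"),
                    seed = run$config$seed)
  if (!is.null(run$sham)) {
    write_screen_table(
      data.frame(drug = names(run$sham$probs),
                 p_synergy = unname(run$sham$probs),
                 called_negative = unname(run$sham$probs) <
                   run$config$model$threshold),
      p("08_sham_check.csv"))
  }
  invisible(out_dir)
}

#' @export
print.screen_run <- function(x, ...) {
  cat("end-to-end screen run\n")
  print(x$sim)
  if (length(x$cv)) for (r in x$cv) print(r)
  if (!is.null(x$sham)) {
    cat(sprintf("  sham negative rate: %.3f (%d shams)\n", x$sham$rate,
                x$sham$n))
  }
  invisible(x)
}
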