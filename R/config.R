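# Configuration surface: one nested list holds every threshold, model
# hyperparameter and simulator setting. A YAML file can override any subset.

#' Default pipeline configuration
#'
#' Returns the nested list of settings used by every stage of the pipeline:
#' labelling thresholds, feature transform, random-forest hyperparameters,
#' cross-validation settings and simulator parameters. All randomized
#' operations draw from `config$seed`.
#'
#' @section Thresholds:
#' * `labels$synergy_cutoff` (-1): a pair is synergistic when `log10(CI)`
#'   falls strictly below this at any tested dose pair (training rule).
#'   The companion validation rule (`label_synergy_validation()`) is
#'   inclusive at the same cutoff.
#' * `labels$effective_cutoff` (70): percent growth inhibition an effective
#'   combination must reach (boundary inclusive).
#' * `labels$selective_margin` (15) and `labels$selective_floor` (50):
#'   a genotype-selective pair beats every other genotype group's mean
#'   growth inhibition by at least the margin and reaches the floor within
#'   its target group.
#' * `labels$dose_agg` ("mean"): how growth-inhibition values over the
#'   tested dose pairs collapse to one value per cell line ("mean" or "max").
#'
#' @param ... Named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return A named list of class `screen_config`.
#' @examples
#' cfg <- default_config(seed = 7)
#' cfg$model$ntree
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    log_base = 10,
    labels = list(
      synergy_cutoff = -1,
      effective_cutoff = 70,
      selective_margin = 15,
      selective_floor = 50,
      dose_agg = "mean",
      q3_cutoff = 70
    ),
    features = list(
      transform = "log10",   # transform of the GI50 dose before mu/delta
      signed_delta = FALSE   # absolute difference keeps pairs order-invariant
    ),
    dose_response = list(
      eps = 1e-3,            # interior clip for the log-odds transform
      gi50_cap_factor = 10,  # unreached GI50 imputed at cap * max tested dose
      min_points = 3L,       # fit-quality gate for CI scoring
      min_r = 0.9
    ),
    model = list(
      ntree = 500L,
      mtry = NULL,           # NULL = floor(sqrt(n_features))
      threshold = 0.5,
      k = 10L,
      stratified = FALSE
    ),
    sim = sim_config()
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  class(cfg) <- c("screen_config", "list")
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a configuration file
#'
#' Loads a YAML file and merges it over [default_config()]; only the keys
#' present in the file are overridden.
#'
#' @param path Path to a YAML configuration file.
#' @return A `screen_config` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg <- merge_config(cfg, user)
  class(cfg) <- c("screen_config", "list")
  cfg
}
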