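#' Read a run configuration
#'
#' A single YAML file drives the command-level entry points: an `inputs`
#' block (either `manifest: <path>` pointing at [write_bundles()] output or
#' `synthetic: true` with optional [fixture_config()] overrides under
#' `fixture`), a `scenario` block of [scenario_params()] overrides, a
#' `sensitivity` block ([sensitivity_spec()] overrides), and a `validation`
#' block (`survey: <csv path>` with columns gender, year, prevalence and an
#' optional `period: [y0, y1]`).  Every scenario default (relative risk 0.05,
#' multipliers 0.88/0.25/1/1, decay 0.9) lives in [scenario_params()], never
#' in the engine.
#'
#' @param path path to the YAML file.
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$inputs)) stop("config needs an 'inputs' block")
  cfg$dir <- dirname(normalizePath(path))
  structure(cfg, class = "run_config")
}

resolve_path <- function(cfg, p) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) return(p)
  file.path(cfg$dir, p)
}

config_bundles <- function(cfg, seed = NULL) {
  inp <- cfg$inputs
  if (isTRUE(inp$synthetic)) {
    args <- inp$fixture
    if (is.null(args)) args <- list()
    if (!is.null(seed)) args$seed <- as.integer(seed)
    do.call(fixture_config, args) |> generate_bundles()
  } else if (!is.null(inp$manifest)) {
    read_bundles(resolve_path(cfg, inp$manifest))
  } else {
    stop("inputs block needs either 'manifest' or 'synthetic: true'")
  }
}

config_params <- function(cfg) {
  args <- cfg$scenario
  if (is.null(args)) args <- list()
  if (!is.null(args$switch_rates) && is.character(args$switch_rates)) {
    args$switch_rates <- read_grouped_csv(resolve_path(cfg, args$switch_rates))
  }
  do.call(scenario_params, args)
}

#' Run both scenarios and write reports
#'
#' Executes the counterfactual and NVP scenarios on the configured inputs
#' and writes trajectory, outcome, net-impact and prevalence tables as CSV,
#' plus a small YAML run manifest recording the seed and the scaling ratios
#' applied.
#'
#' @param config path to a YAML run configuration ([read_run_config()]) or a
#'   `run_config` object.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest and forwarded to the
#'   synthetic generator when inputs are synthetic.
#' @return (invisibly) list with both trajectories, outcome tables and the
#'   net impact.
#' @export
savm_run <- function(config, out_dir = "savm_out", seed = 1L) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  b <- config_bundles(cfg, seed)
  params <- config_params(cfg)
  rates <- localize_inputs(b$country, b$reference)
  traj0 <- run_scenario(b$country, rates, params, scenario = "no_nvp")
  traj1 <- run_scenario(b$country, rates, params, scenario = "nvp")
  out0 <- outcome_table(traj0, rates, rr_nvp = 0)
  out1 <- outcome_table(traj1, rates)
  ni <- net_impact(out0, out1)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE, quote = FALSE)
  w(trajectory_to_df(traj0), "trajectory_no_nvp.csv")
  w(trajectory_to_df(traj1), "trajectory_nvp.csv")
  w(out0$by_year, "outcomes_no_nvp.csv")
  w(out1$by_year, "outcomes_nvp.csv")
  w(out0$prevalence, "prevalence_no_nvp.csv")
  w(out1$prevalence, "prevalence_nvp.csv")
  w(ni$by_year, "net_impact_by_year.csv")
  w(ni$cumulative, "net_impact_cumulative.csv")
  yaml::write_yaml(list(seed = as.integer(seed),
                        scaling_ratios = as.list(as.data.frame(rates$ratios)),
                        percent_averted = as.list(ni$percent)),
                   file.path(out_dir, "run_manifest.yaml"))
  invisible(list(no_nvp = list(trajectory = traj0, outcomes = out0),
                 nvp = list(trajectory = traj1, outcomes = out1),
                 net_impact = ni, rates = rates))
}

#' Run the sensitivity grid from a configuration
#'
#' @inheritParams savm_run
#' @return (invisibly) the sensitivity grid data frame (also written as
#'   `sensitivity.csv`).
#' @export
savm_sensitivity <- function(config, out_dir = "savm_out", seed = 1L) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  b <- config_bundles(cfg, seed)
  params <- config_params(cfg)
  rates <- localize_inputs(b$country, b$reference)
  args <- cfg$sensitivity
  if (is.null(args)) args <- list()
  spec <- do.call(sensitivity_spec, args)
  grid <- run_sensitivity(b$country, rates, params, spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(grid, file.path(out_dir, "sensitivity.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(grid)
}

#' Validate configured inputs against a survey series
#'
#' @inheritParams savm_run
#' @return (invisibly) the validation list from [validate_against_survey()]
#'   (also written as `validation_endpoints.csv` / `validation_by_year.csv`).
#' @export
savm_validate <- function(config, out_dir = "savm_out", seed = 1L) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (is.null(cfg$validation$survey)) {
    stop("config needs validation$survey: a CSV with gender, year, prevalence")
  }
  b <- config_bundles(cfg, seed)
  params <- config_params(cfg)
  rates <- localize_inputs(b$country, b$reference)
  traj1 <- run_scenario(b$country, rates, params, scenario = "nvp")
  prev <- traj_prevalence(traj1)
  model <- data.frame(gender = prev$gender, year = prev$year,
                      prevalence = prev$smoking)
  survey <- utils::read.csv(resolve_path(cfg, cfg$validation$survey),
                            stringsAsFactors = FALSE)
  cmp <- validate_against_survey(model, survey,
                                 period = unlist(cfg$validation$period))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cmp$endpoints, file.path(out_dir, "validation_endpoints.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cmp$by_year, file.path(out_dir, "validation_by_year.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(cmp)
}

#' Generate synthetic inputs to disk
#'
#' @inheritParams savm_run
#' @return (invisibly) the manifest path from [write_bundles()].
#' @export
savm_synth <- function(config, out_dir = "savm_out", seed = 1L) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  args <- cfg$inputs$fixture
  if (is.null(args)) args <- list()
  args$seed <- as.integer(seed)
  b <- generate_bundles(do.call(fixture_config, args))
  invisible(write_bundles(b, out_dir))
}
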