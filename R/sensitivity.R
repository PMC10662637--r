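#' Specification of a one-at-a-time sensitivity analysis
#'
#' A grid of NVP relative-risk values crossed with single-parameter
#' perturbations of the NVP-scenario multipliers.  Defaults follow the usual
#' reporting layout: relative risks 5/15/25/40/50% and each of the switching
#' scale and the four multipliers at 50% and 150% of its base value.
#'
#' @param rr_values numeric vector of relative-risk multipliers.
#' @param parameters character vector of perturbed parameter names (fields of
#'   [scenario_params()]).
#' @param factors numeric multipliers applied one at a time to each
#'   parameter.
#' @return object of class `sensitivity_spec`.
#' @export
sensitivity_spec <- function(rr_values = c(0.05, 0.15, 0.25, 0.40, 0.50),
                             parameters = c("switch_scale", "m_smk_init",
                                            "m_nvp_init", "m_smk_cess",
                                            "m_nvp_cess"),
                             factors = c(0.5, 1.5)) {
  allowed <- c("switch_scale", "m_smk_init", "m_nvp_init", "m_smk_cess",
               "m_nvp_cess")
  bad <- setdiff(parameters, allowed)
  if (length(bad)) {
    stop("config error: unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  if (any(factors <= 0)) stop("perturbation factors must be > 0")
  structure(list(rr_values = rr_values, parameters = parameters,
                 factors = factors),
            class = "sensitivity_spec")
}

#' Run the one-at-a-time sensitivity grid
#'
#' For every relative-risk value, reruns the NVP scenario at the base
#' parameters and with each single parameter multiplied by each perturbation
#' factor (the counterfactual scenario is unchanged throughout), and
#' tabulates cumulative averted deaths and life-years, the relative
#' difference versus the base estimate at the same relative risk, and the
#' relative change across relative-risk values versus the first one.
#' Negative averted values (an NVP scenario worse than the counterfactual)
#' are reported as-is.
#'
#' @param bundle a [country_bundle()].
#' @param rates a `country_rates` from [localize_inputs()].
#' @param params base [scenario_params()].
#' @param spec a [sensitivity_spec()].
#' @return data frame with one row per (rr, scenario) cell: columns
#'   `rr`, `parameter` (`"base"` for the unperturbed row), `factor`,
#'   `averted_deaths`, `averted_lyls`, `rel_diff_deaths_pct`,
#'   `rel_diff_lyls_pct`, `cross_rr_deaths_pct`, `cross_rr_lyls_pct`, and
#'   the counterfactual totals `total_deaths_no_nvp`, `total_lyls_no_nvp`.
#' @export
run_sensitivity <- function(bundle, rates, params,
                            spec = sensitivity_spec()) {
  traj0 <- run_scenario(bundle, rates, params, scenario = "no_nvp")
  out0 <- outcome_table(traj0, rates, rr_nvp = 0)
  tot0 <- out0$cumulative[out0$cumulative$gender == "both", ]

  cells <- data.frame(parameter = "base", factor = 1)
  for (p in spec$parameters) {
    cells <- rbind(cells, data.frame(parameter = p, factor = spec$factors))
  }
  rows <- list()
  for (rr in spec$rr_values) {
    for (i in seq_len(nrow(cells))) {
      pr <- params
      pr$rr_nvp <- rr
      if (cells$parameter[i] != "base") {
        pr[[cells$parameter[i]]] <- pr[[cells$parameter[i]]] * cells$factor[i]
      }
      traj1 <- run_scenario(bundle, rates, pr, scenario = "nvp")
      out1 <- outcome_table(traj1, rates)
      ni <- net_impact(out0, out1)
      cum <- ni$cumulative[ni$cumulative$gender == "both", ]
      rows[[length(rows) + 1L]] <- data.frame(
        rr = rr, parameter = cells$parameter[i], factor = cells$factor[i],
        averted_deaths = cum$deaths_averted, averted_lyls = cum$lyls_averted)
    }
  }
  grid <- do.call(rbind, rows)
  grid$rel_diff_deaths_pct <- NA_real_
  grid$rel_diff_lyls_pct <- NA_real_
  for (rr in unique(grid$rr)) {
    sel <- grid$rr == rr
    base <- grid[sel & grid$parameter == "base", ]
    grid$rel_diff_deaths_pct[sel] <-
      100 * relative_change(base$averted_deaths, grid$averted_deaths[sel])
    grid$rel_diff_lyls_pct[sel] <-
      100 * relative_change(base$averted_lyls, grid$averted_lyls[sel])
  }
  rr1 <- spec$rr_values[1L]
  grid$cross_rr_deaths_pct <- NA_real_
  grid$cross_rr_lyls_pct <- NA_real_
  for (i in seq_len(nrow(grid))) {
    ref <- grid[grid$rr == rr1 & grid$parameter == grid$parameter[i] &
                  grid$factor == grid$factor[i], ]
    grid$cross_rr_deaths_pct[i] <-
      100 * relative_change(ref$averted_deaths, grid$averted_deaths[i])
    grid$cross_rr_lyls_pct[i] <-
      100 * relative_change(ref$averted_lyls, grid$averted_lyls[i])
  }
  grid$total_deaths_no_nvp <- tot0$deaths
  grid$total_lyls_no_nvp <- tot0$lyls
  grid
}

#' Compare model prevalence against a survey series
#'
#' Surveys disagree on levels, so validation compares relative changes: over
#' the first and last overlapping years (or a supplied period) the model and
#' survey endpoint prevalences and their relative changes are reported per
#' gender, together with per-year relative differences
#' `(model - survey) / survey`.
#'
#' @param model data frame with columns `gender`, `year`, `prevalence` (the
#'   `prevalence` summary of an [outcome_table()] works after renaming its
#'   value column).
#' @param survey data frame with columns `gender`, `year`, `prevalence`;
#'   years must be strictly increasing within each gender.
#' @param period optional length-2 integer vector of endpoint years.
#' @return list with `endpoints` (gender, year0, year1, model/survey values
#'   and relative changes) and `by_year` (gender, year, model, survey,
#'   rel_diff).
#' @export
validate_against_survey <- function(model, survey, period = NULL) {
  for (df in list(model, survey)) {
    if (!all(c("gender", "year", "prevalence") %in% names(df))) {
      stop("need columns gender, year, prevalence")
    }
  }
  for (g in unique(survey$gender)) {
    ys <- survey$year[survey$gender == g]
    if (any(diff(ys) <= 0)) stop("survey years must be strictly increasing")
  }
  merged <- merge(model, survey, by = c("gender", "year"),
                  suffixes = c("_model", "_survey"))
  if (nrow(merged) == 0L) stop("coverage error: no overlapping years")
  if (!is.null(period)) {
    merged <- merged[merged$year >= period[1L] & merged$year <= period[2L], ]
    if (nrow(merged) == 0L) {
      stop("coverage error: no overlapping years in the requested period")
    }
  }
  merged <- merged[order(merged$gender, merged$year), ]
  merged$rel_diff <- relative_change(merged$prevalence_survey,
                                     merged$prevalence_model)
  endpoints <- do.call(rbind, lapply(split(merged, merged$gender), function(d) {
    d0 <- d[1L, ]; d1 <- d[nrow(d), ]
    data.frame(gender = d0$gender, year0 = d0$year, year1 = d1$year,
               model0 = d0$prevalence_model, model1 = d1$prevalence_model,
               survey0 = d0$prevalence_survey, survey1 = d1$prevalence_survey,
               model_rel_change = relative_change(d0$prevalence_model,
                                                  d1$prevalence_model),
               survey_rel_change = relative_change(d0$prevalence_survey,
                                                   d1$prevalence_survey))
  }))
  rownames(endpoints) <- NULL
  list(endpoints = endpoints,
       by_year = merged[c("gender", "year", "prevalence_model",
                          "prevalence_survey", "rel_diff")])
}
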