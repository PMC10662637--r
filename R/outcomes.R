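#' Excess-mortality map over states
#'
#' The per-state excess death probability used both for survival inside the
#' engine and for attributing deaths: zero for never smokers and low-risk
#' quitters, the full smoking excess for current/former smokers, `rr` times
#' the corresponding smoking excess for vaping states, and (by default) the
#' former-smoker excess plus the NVP add-on for former smokers who vape.
#'
#' @param rates a `country_rates` object from [localize_inputs()].
#' @param rr_nvp NVP relative-risk multiplier.
#' @param fsnvp_excess_mode see [scenario_params()].
#' @return 9 x age x gender x year array of excess death probabilities.
#' @export
excess_map <- function(rates, rr_nvp = 0, fsnvp_excess_mode = "additive") {
  mu <- rates$mu
  dn <- dimnames(mu$never)
  ex <- array(0, dim = c(9L, dim(mu$never)),
              dimnames = c(list(state = use_states()), dn))
  for (g in dn$gender) {
    lst <- state_excess_list(mu$never[, g, ], mu$current[, g, ],
                             mu$former[, g, ], rr_nvp, fsnvp_excess_mode)
    for (s in seq_len(9L)) ex[s, , g, ] <- lst[[s]]
  }
  ex
}

#' Attributable deaths from a trajectory
#'
#' Deaths attributable to smoking and vaping: the excess mortality of each
#' use state multiplied by the number of individuals in that state, summed
#' over states, using start-of-year counts.
#'
#' @param traj a `state_trajectory` from [run_scenario()].
#' @param excess a 9 x age x gender x year array from [excess_map()].
#' @return age x gender x year array of attributable deaths.
#' @export
attributable_deaths <- function(traj, excess) {
  if (any(excess < 0)) stop("data error: negative excess mortality")
  if (!identical(dim(excess), dim(traj$count))) {
    stop("index mismatch between trajectory and excess map")
  }
  apply(excess * traj$count, c(2, 3, 4), sum)
}

#' Life-years lost from attributable deaths
#'
#' Each attributable death is weighted by the remaining life expectancy of a
#' never smoker of that age, gender and year.
#'
#' @param deaths age x gender x year array from [attributable_deaths()].
#' @param le_never age x gender x year never-smoker life expectancy.
#' @return age x gender x year array of life-years lost.
#' @export
life_years_lost <- function(deaths, le_never) {
  if (!identical(dim(deaths), dim(le_never))) {
    stop("coverage error: life-expectancy table does not match deaths index")
  }
  deaths * le_never
}

#' Summarise a trajectory into an outcome table
#'
#' Computes attributable deaths and life-years lost by gender and year, their
#' cumulative totals, and population-weighted prevalence summaries (current
#' smoking, exclusive NVP use, former smokers who vape) over the modeled
#' adult ages.
#'
#' @param traj a `state_trajectory`.
#' @param rates a `country_rates` (for status mortality and never-smoker life
#'   expectancy).
#' @param rr_nvp NVP relative-risk multiplier used in the excess map; use 0
#'   for the counterfactual scenario so only smoker states contribute.
#' @param fsnvp_excess_mode see [scenario_params()].
#' @return object of class `outcome_table`: list with `by_year` (gender,
#'   year, deaths, lyls), `cumulative` (per gender and `"both"`), and
#'   `prevalence` (gender, year, smoking, nvp, fs_nvp shares).
#' @export
outcome_table <- function(traj, rates, rr_nvp = NULL,
                          fsnvp_excess_mode = NULL) {
  p <- traj$params
  if (is.null(rr_nvp)) {
    rr_nvp <- if (traj$scenario == "nvp") p$rr_nvp else 0
  }
  if (is.null(fsnvp_excess_mode)) {
    fsnvp_excess_mode <- if (!is.null(p)) p$fsnvp_excess_mode else "additive"
  }
  ex <- excess_map(rates, rr_nvp, fsnvp_excess_mode)
  deaths <- attributable_deaths(traj, ex)
  lyls <- life_years_lost(deaths, rates$le_never)
  genders <- dimnames(deaths)$gender
  years <- as.integer(dimnames(deaths)$year)

  by_year <- expand.grid(gender = genders, year = years,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  by_year$deaths <- as.vector(apply(deaths, c(2, 3), sum))
  by_year$lyls <- as.vector(apply(lyls, c(2, 3), sum))

  cum <- stats::aggregate(cbind(deaths, lyls) ~ gender, data = by_year, sum)
  cum <- rbind(cum, data.frame(gender = "both",
                               deaths = sum(by_year$deaths),
                               lyls = sum(by_year$lyls)))

  prev <- traj_prevalence(traj)
  structure(list(by_year = by_year, cumulative = cum, prevalence = prev,
                 deaths_by_age = deaths, lyls_by_age = lyls,
                 scenario = traj$scenario),
            class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("<outcome_table> scenario ", x$scenario, "\n", sep = "")
  print(x$cumulative)
  invisible(x)
}

#' Population-weighted prevalence summaries by year
#'
#' @param traj a `state_trajectory`.
#' @return data frame with per gender/year population-weighted shares:
#'   `smoking` (current smokers, incl. dual users), `nvp` (exclusive NVP
#'   users), `fs_nvp` (former smokers who vape).
#' @export
traj_prevalence <- function(traj) {
  dn <- dimnames(traj$share)
  genders <- dn$gender
  years <- as.integer(dn$year)
  out <- expand.grid(gender = genders, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  wshare <- function(states, g, ti) {
    w <- traj$population[, g, ti]
    sh <- matrix(traj$share[states, , g, ti], nrow = length(states))
    sum(colSums(sh) * w) / sum(w)
  }
  for (i in seq_len(nrow(out))) {
    g <- out$gender[i]
    ti <- match(out$year[i], years)
    out$smoking[i] <- wshare("current_smoker", g, ti)
    out$nvp[i] <- wshare(c("nvp_user", "nvp_user_exsmoker_lowrisk"), g, ti)
    out$fs_nvp[i] <- wshare("fs_nvp_user", g, ti)
  }
  out
}

#' Net impact of the NVP scenario versus the counterfactual
#'
#' Deaths and life-years averted, per gender and year and cumulatively,
#' as counterfactual minus NVP-scenario values; percentages are the
#' cumulative averted totals relative to the counterfactual cumulative
#' totals.
#'
#' @param no_nvp,nvp `outcome_table` objects on identical indices.
#' @return object of class `net_impact`: list with `by_year` (gender, year,
#'   deaths_averted, lyls_averted), `cumulative`, and `percent`
#'   (both-gender cumulative percentages averted).
#' @export
net_impact <- function(no_nvp, nvp) {
  a <- no_nvp$by_year; b <- nvp$by_year
  if (!identical(a[c("gender", "year")], b[c("gender", "year")])) {
    stop("schema error: outcome tables are not on identical indices")
  }
  by_year <- a[c("gender", "year")]
  by_year$deaths_averted <- a$deaths - b$deaths
  by_year$lyls_averted <- a$lyls - b$lyls
  cum <- stats::aggregate(cbind(deaths_averted, lyls_averted) ~ gender,
                          data = by_year, sum)
  cum <- rbind(cum, data.frame(gender = "both",
                               deaths_averted = sum(by_year$deaths_averted),
                               lyls_averted = sum(by_year$lyls_averted)))
  tot0 <- no_nvp$cumulative[no_nvp$cumulative$gender == "both", ]
  percent <- c(deaths_averted_pct =
                 100 * cum$deaths_averted[cum$gender == "both"] / tot0$deaths,
               lyls_averted_pct =
                 100 * cum$lyls_averted[cum$gender == "both"] / tot0$lyls)
  structure(list(by_year = by_year, cumulative = cum, percent = percent),
            class = "net_impact")
}

#' @export
print.net_impact <- function(x, ...) {
  cat("<net_impact>\n")
  print(x$cumulative)
  cat(sprintf("deaths averted: %.1f%%, LYLs averted: %.1f%%\n",
              x$percent[["deaths_averted_pct"]],
              x$percent[["lyls_averted_pct"]]))
  invisible(x)
}

#' Relative change between two values
#'
#' `(v1 - v0) / v0` — the quantity used both for endpoint prevalence
#' comparisons (e.g. a decline from 20.6% to 16.6% is a 19% relative
#' reduction) and for sensitivity-table relative differences.
#'
#' @param v0 baseline value (nonzero).
#' @param v1 comparison value.
#' @return the relative change as a proportion.
#' @export
relative_change <- function(v0, v1) {
  if (any(v0 == 0)) stop("division error: baseline value is zero")
  (v1 - v0) / v0
}
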