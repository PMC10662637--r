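#' Default smoking-to-vaping switching schedule
#'
#' Annual probabilities that a current smoker switches to exclusive NVP use,
#' by age group and gender, as estimated from the US PATH cohort: males
#' (females) 4% (2.5%) through age 24, 2.5% (2.0%) at 25-34, 2.5% (1.6%) at
#' 35-44, 1.3% (1.4%) at 45-54, 1.2% (1.4%) at 55-64 and 0.6% (1.0%) at 65+.
#'
#' @return grouped data frame (`age_lo`, `age_hi`, `gender`, `value`).
#' @export
default_switch_rates <- function() {
  lo <- c(0, 25, 35, 45, 55, 65)
  hi <- c(24, 34, 44, 54, 64, 99)
  data.frame(
    age_lo = rep(lo, 2), age_hi = rep(hi, 2),
    gender = rep(c("male", "female"), each = 6),
    value = c(0.040, 0.025, 0.025, 0.013, 0.012, 0.006,
              0.025, 0.020, 0.016, 0.014, 0.014, 0.010))
}

#' Parameters of the NVP scenario
#'
#' All knobs of the vaping scenario.  Defaults are the German configuration:
#' NVP excess mortality at 5% of the smoking excess, the built-in switching
#' schedule halved (`switch_scale = 0.5`) with a 10% annual decay
#' (`decay_factor = 0.9`) from 2018, smoking initiation at 88% and NVP
#' initiation at 25% of the counterfactual smoking initiation rate, both
#' cessation rates at 100% of the counterfactual smoking cessation rate, and
#' vaping introduced in 2012.
#'
#' @param rr_nvp NVP excess-mortality relative-risk multiplier in \[0, 1\]:
#'   NVP users' excess mortality as a fraction of smokers' excess mortality.
#' @param switch_scale proportion applied to the switching schedule.
#' @param decay_factor annual multiplicative decay of the switching rate
#'   (0.9 means a 10% reduction per year), in (0, 1\].
#' @param decay_start_year first year the decay applies.
#' @param m_smk_init,m_nvp_init multipliers on the counterfactual smoking
#'   initiation rate giving smoking and NVP initiation in the NVP scenario.
#' @param m_smk_cess,m_nvp_cess multipliers on the counterfactual smoking
#'   cessation rate giving smoking and NVP cessation in the NVP scenario.
#' @param age35_threshold quit-before-35 rule: smokers who quit (or switch)
#'   with attained age below this carry never-smoker mortality afterwards.
#' @param nvp_intro_year first year NVP flows are active; earlier years
#'   follow the counterfactual dynamics exactly.
#' @param switch_rates grouped data frame of switching probabilities by age
#'   group and gender ([default_switch_rates()]).
#' @param annual_change optional named list of per-parameter annual change
#'   factors (names among `m_smk_init`, `m_nvp_init`, `m_smk_cess`,
#'   `m_nvp_cess`), each applied as `factor^(year - nvp_intro_year)`.
#' @param fsnvp_excess_mode excess-mortality composition for former smokers
#'   who vape (switched at >= 35): `"additive"` adds the NVP excess on top of
#'   the former-smoker excess; `"nvp_only"` keeps only the NVP term.
#' @return object of class `scenario_params`.
#' @export
scenario_params <- function(rr_nvp = 0.05,
                            switch_scale = 0.5,
                            decay_factor = 0.9,
                            decay_start_year = 2018,
                            m_smk_init = 0.88,
                            m_nvp_init = 0.25,
                            m_smk_cess = 1.0,
                            m_nvp_cess = 1.0,
                            age35_threshold = 35,
                            nvp_intro_year = 2012,
                            switch_rates = default_switch_rates(),
                            annual_change = list(),
                            fsnvp_excess_mode = c("additive", "nvp_only")) {
  fsnvp_excess_mode <- match.arg(fsnvp_excess_mode)
  if (rr_nvp < 0 || rr_nvp > 1) stop("rr_nvp must lie in [0, 1]")
  if (decay_factor <= 0 || decay_factor > 1) {
    stop("parameter error: decay_factor must lie in (0, 1]")
  }
  for (m in c(switch_scale, m_smk_init, m_nvp_init, m_smk_cess, m_nvp_cess)) {
    if (m < 0) stop("multipliers must be >= 0")
  }
  check_grouped(switch_rates)
  bad <- setdiff(names(annual_change),
                 c("m_smk_init", "m_nvp_init", "m_smk_cess", "m_nvp_cess"))
  if (length(bad)) stop("unknown annual_change entries: ",
                        paste(bad, collapse = ", "))
  structure(list(rr_nvp = rr_nvp, switch_scale = switch_scale,
                 decay_factor = decay_factor,
                 decay_start_year = as.integer(decay_start_year),
                 m_smk_init = m_smk_init, m_nvp_init = m_nvp_init,
                 m_smk_cess = m_smk_cess, m_nvp_cess = m_nvp_cess,
                 age35_threshold = as.integer(age35_threshold),
                 nvp_intro_year = as.integer(nvp_intro_year),
                 switch_rates = switch_rates, annual_change = annual_change,
                 fsnvp_excess_mode = fsnvp_excess_mode),
            class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("<scenario_params> rr_nvp=", x$rr_nvp,
      " switch_scale=", x$switch_scale,
      " decay=", x$decay_factor, "@", x$decay_start_year,
      " m=(", x$m_smk_init, ",", x$m_nvp_init, ",",
      x$m_smk_cess, ",", x$m_nvp_cess, ")\n", sep = "")
  invisible(x)
}

#' Exponential decay of a transition parameter
#'
#' `base * decay_factor^max(0, year - decay_start_year)`: no change before
#' the start year, constant relative change each year after.
#'
#' @param base annual probability in \[0, 1\].
#' @param decay_factor multiplicative annual factor, > 0.
#' @param year calendar year evaluated.
#' @param decay_start_year year the decay begins.
#' @return the decayed probability.
#' @export
#' @examples
#' apply_decay(0.04, 0.9, 2020, 2018)  # 0.0324
apply_decay <- function(base, decay_factor, year, decay_start_year) {
  if (any(decay_factor <= 0)) stop("parameter error: decay_factor must be > 0")
  base * decay_factor^pmax(0, year - decay_start_year)
}

#' Build the NVP-scenario transition schedule
#'
#' Applies the scenario multipliers to the counterfactual (No-NVP) initiation
#' and cessation rates and lays out the switching schedule over time:
#' `smk_init = m_smk_init * init`, `nvp_init = m_nvp_init * init`,
#' `smk_cess = m_smk_cess * cess`, `nvp_cess = m_nvp_cess * cess`, and
#' `switch(a,g,t) = switch_scale * switch_rate(group(a),g) *
#' decay_factor^max(0, t - decay_start_year)`.  Before `nvp_intro_year` the
#' schedule reproduces the counterfactual exactly (multipliers not applied,
#' NVP flows zero).  Competing-flow feasibility (`smk_init + nvp_init <= 1`,
#' `smk_cess + switch <= 1`) is enforced.
#'
#' @param no_nvp_init,no_nvp_cess age x gender x year counterfactual rates on
#'   a common index.
#' @param params a [scenario_params()].
#' @return object of class `transition_schedule`: list of five age x gender
#'   x year arrays `smk_init`, `nvp_init`, `smk_cess`, `nvp_cess`, `switch`.
#' @export
build_schedule <- function(no_nvp_init, no_nvp_cess, params) {
  check_same_index(no_nvp_init, no_nvp_cess, "init", "cess")
  ages <- agy_ages(no_nvp_init)
  years <- agy_years(no_nvp_init)
  sw_age <- expand_groups_uniform(params$switch_rates, ages)

  ac <- function(nm) {
    f <- params$annual_change[[nm]]
    if (is.null(f)) return(rep(1, length(years)))
    apply_decay(1, f, years, params$nvp_intro_year)
  }
  pre <- years < params$nvp_intro_year

  sched <- list(
    smk_init = no_nvp_init, nvp_init = no_nvp_init,
    smk_cess = no_nvp_cess, nvp_cess = no_nvp_cess,
    switch = agy_table(0, ages, years))
  for (i in seq_along(years)) {
    y <- as.character(years[i])
    if (pre[i]) {
      sched$nvp_init[, , y] <- 0
      # smk_init / smk_cess keep the counterfactual values; switch stays 0
      next
    }
    sched$smk_init[, , y] <- no_nvp_init[, , y] * params$m_smk_init * ac("m_smk_init")[i]
    sched$nvp_init[, , y] <- no_nvp_init[, , y] * params$m_nvp_init * ac("m_nvp_init")[i]
    sched$smk_cess[, , y] <- no_nvp_cess[, , y] * params$m_smk_cess * ac("m_smk_cess")[i]
    sched$nvp_cess[, , y] <- no_nvp_cess[, , y] * params$m_nvp_cess * ac("m_nvp_cess")[i]
    sched$switch[, , y] <- params$switch_scale * sw_age *
      apply_decay(1, params$decay_factor, years[i], params$decay_start_year)
  }
  for (nm in names(sched)) {
    if (any(sched[[nm]] < 0 | sched[[nm]] > 1)) {
      stop("feasibility error: ", nm, " outside [0, 1]")
    }
  }
  if (any(sched$smk_init + sched$nvp_init > 1 + 1e-12)) {
    stop("feasibility error: smk_init + nvp_init > 1")
  }
  if (any(sched$smk_cess + sched$switch > 1 + 1e-12)) {
    stop("feasibility error: smk_cess + switch > 1")
  }
  structure(sched, class = "transition_schedule")
}

#' NVP excess mortality from smoking excess risk
#'
#' The mortality add-on for vaping states: the relative-risk multiplier times
#' the smoker (or former-smoker) excess over never-smoker mortality.
#'
#' @param mu_never,mu_current,mu_former mortality by smoking status on a
#'   common index.
#' @param rr_nvp relative-risk multiplier in \[0, 1\].
#' @return list with `current` (`rr * (mu_current - mu_never)`) and `former`
#'   (`rr * (mu_former - mu_never)`), both >= 0.
#' @export
nvp_excess_mortality <- function(mu_never, mu_current, mu_former, rr_nvp) {
  ec <- mu_current - mu_never
  ef <- mu_former - mu_never
  if (any(ec < -1e-12) || any(ef < -1e-12)) {
    stop("data error: negative excess mortality input")
  }
  list(current = rr_nvp * pmax(ec, 0), former = rr_nvp * pmax(ef, 0))
}
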