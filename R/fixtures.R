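#' Configuration of the synthetic input generator
#'
#' Describes a complete synthetic country + reference input pair: a
#' Gompertz-type never-smoker mortality curve with status relative risks
#' ordered current > former > never, an initiation profile concentrated at
#' young adult ages, a cessation rate rising with age, age-group prevalence
#' anchors smoothed into single-age curves, and a population projection
#' evolved under overall mortality.  Defaults emulate the German adult
#' application: ages 18-99, years 2012-2060, the published GEDA age-group
#' smoking prevalences as country anchors and US-style anchors for the
#' reference population, with the country's overall mortality offset
#' multiplicatively from the reference so every rescaling step is exercised
#' nontrivially.
#'
#' @param seed integer; recorded in the config and used for the optional
#'   jitter (the generator is otherwise deterministic).
#' @param min_age,max_age,base_year,end_year modeled window.
#' @param pop_scale persons in the youngest age class in the base year.
#' @param entrant_growth annual multiplicative change of the entrant cohort
#'   size.
#' @param gompertz_b0 named baseline hazard at age 0 per gender.
#' @param gompertz_beta log-hazard increase per year of age (doubling time
#'   `log(2)/beta` years).
#' @param mort_trend annual multiplicative mortality trend.
#' @param rr_current,rr_former mortality of current/former smokers relative
#'   to never smokers.
#' @param init_peak named peak initiation probability per gender at the
#'   youngest age.
#' @param init_width Gaussian width (years) of the initiation age profile.
#' @param cess_base,cess_slope,cess_max cessation at the youngest age, its
#'   rise per year of age, and its cap.
#' @param country_prev_groups,ref_prev_groups age-group anchors (proportions)
#'   for current-smoking prevalence, as grouped data frames
#'   (`age_lo`, `age_hi`, `gender`, `value`).
#' @param former_base,former_slope former/current ratio at the youngest age
#'   and its rise per year of age.
#' @param country_mort_offset country overall mortality as a multiple of the
#'   reference overall mortality.
#' @param jitter_sd lognormal age-wise jitter applied to initiation and
#'   cessation rates (0 disables; then the generator is fully
#'   deterministic).
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           min_age = 18L, max_age = 99L,
                           base_year = 2012L, end_year = 2060L,
                           pop_scale = 5e5, entrant_growth = 0.998,
                           gompertz_b0 = c(male = 4e-5, female = 2.5e-5),
                           gompertz_beta = 0.085,
                           mort_trend = 0.995,
                           rr_current = 2.5, rr_former = 1.5,
                           init_peak = c(male = 0.055, female = 0.045),
                           init_width = 6,
                           cess_base = 0.03, cess_slope = 8e-4,
                           cess_max = 0.12,
                           country_prev_groups = germany_prevalence_groups(),
                           ref_prev_groups = us_prevalence_groups(),
                           former_base = 0.30, former_slope = 0.013,
                           country_mort_offset = 1.08,
                           jitter_sd = 0) {
  if (end_year - base_year > 88) stop("config error: horizon exceeds 88 years")
  if (!(min_age >= 0 && min_age <= max_age && max_age <= 99)) {
    stop("config error: need 0 <= min_age <= max_age <= 99")
  }
  if (rr_current < rr_former || rr_former < 1) {
    stop("config error: need rr_current >= rr_former >= 1")
  }
  check_grouped(country_prev_groups)
  check_grouped(ref_prev_groups)
  structure(as.list(environment()), class = "fixture_config")
}

#' Germany-like and reference age-group prevalence anchors
#'
#' `germany_prevalence_groups()` carries the published German age-group
#' current-smoking prevalences (18-29: 34.7%, 30-44: 34.5%, 45-64: 30.4%,
#' 65+: 12.0%), split by gender with male/female factors chosen so the
#' population-weighted adult prevalences resemble the published
#' male/female levels; `us_prevalence_groups()` carries the corresponding
#' US-style anchors (21.3/27.0/22.1/9.4%).  These are resemblance presets
#' for synthetic runs, not reproductions of any survey microdata.
#'
#' @param male_factor,female_factor multipliers applied to the combined
#'   anchors to split them by gender.
#' @return grouped data frame (`age_lo`, `age_hi`, `gender`, `value`).
#' @export
germany_prevalence_groups <- function(male_factor = 1.17,
                                      female_factor = 0.88) {
  both <- c(0.347, 0.345, 0.304, 0.120)
  data.frame(age_lo = rep(c(18, 30, 45, 65), 2),
             age_hi = rep(c(29, 44, 64, 99), 2),
             gender = rep(c("male", "female"), each = 4),
             value = c(both * male_factor, both * female_factor))
}

#' @rdname germany_prevalence_groups
#' @export
us_prevalence_groups <- function(male_factor = 1.10, female_factor = 0.90) {
  both <- c(0.213, 0.270, 0.221, 0.094)
  data.frame(age_lo = rep(c(18, 30, 45, 65), 2),
             age_hi = rep(c(29, 44, 64, 99), 2),
             gender = rep(c("male", "female"), each = 4),
             value = c(both * male_factor, both * female_factor))
}

#' Period life expectancy from a mortality table
#'
#' Builds remaining life expectancy at every age from annual death
#' probabilities by summing survivorship, extrapolating the hazard beyond
#' the table's last age by a constant multiplicative growth so old-age
#' values are not truncated.
#'
#' @param mu age x gender x year array of annual death probabilities.
#' @param extend_to age to which the hazard is extrapolated.
#' @param growth multiplicative hazard growth per extrapolated year.
#' @return age x gender x year array of life expectancy (years).
#' @export
le_from_mu <- function(mu, extend_to = 120L, growth = 1.09) {
  ages <- agy_ages(mu)
  out <- mu
  n_ext <- max(extend_to - max(ages), 0L)
  for (g in agy_genders(mu)) {
    for (y in dimnames(mu)[["year"]]) {
      m <- mu[, g, y]
      m_ext <- pmin(m[length(m)] * growth^seq_len(n_ext), 1)
      mm <- c(m, m_ext)
      for (i in seq_along(ages)) {
        surv <- cumprod(1 - mm[i:length(mm)])
        out[i, g, y] <- sum(surv) + 0.5
      }
    }
  }
  out
}

#' Generate a synthetic country + reference input pair
#'
#' Deterministic given its configuration (the seed drives only the optional
#' jitter).  The generated tables satisfy every bundle invariant, including
#' the status mortality ordering, and the country tables differ from the
#' reference tables by the configured multiplicative offsets so the
#' rescaling operations have nontrivial effect.
#'
#' @param cfg a [fixture_config()].
#' @return list with elements `country` (a [country_bundle()]), `reference`
#'   (a [reference_bundle()]) and `cfg`.
#' @export
generate_bundles <- function(cfg = fixture_config()) {
  if (!inherits(cfg, "fixture_config")) stop("cfg must be a fixture_config")
  ages <- cfg$min_age:cfg$max_age
  years <- cfg$base_year:cfg$end_year
  nA <- length(ages); nY <- length(years)
  genders <- c("male", "female")

  jit <- function(n) rep(1, n)
  if (cfg$jitter_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(cfg$seed)
    jit <- function(n) exp(stats::rnorm(n, 0, cfg$jitter_sd))
  }

  # --- reference mortality by status (Gompertz x relative risks) ---
  mu_never <- agy_table(0, ages, years)
  for (g in genders) {
    base_curve <- cfg$gompertz_b0[[g]] * exp(cfg$gompertz_beta * ages)
    for (i in seq_len(nY)) {
      mu_never[, g, i] <- pmin(base_curve * cfg$mort_trend^(i - 1), 0.9)
    }
  }
  mu_current <- pmin(cfg$rr_current * mu_never, 0.95)
  mu_former <- pmin(cfg$rr_former * mu_never, 0.93)

  # --- base-year smoking-status prevalence curves ---
  status_prev <- function(groups) {
    cur <- smooth_group_prevalence(groups, ages)
    frac <- pmin(cfg$former_base + cfg$former_slope * (ages - cfg$min_age), 1.6)
    prev <- array(0, dim = c(nA, 2L, 3L),
                  dimnames = list(age = as.character(ages), gender = genders,
                                  status = c("never", "current", "former")))
    for (g in genders) {
      former <- pmin(cur[, g] * frac, 1 - cur[, g] - 0.02)
      prev[, g, "current"] <- cur[, g]
      prev[, g, "former"] <- former
      prev[, g, "never"] <- 1 - cur[, g] - former
    }
    prev
  }
  prev_ref <- status_prev(cfg$ref_prev_groups)
  prev_country <- status_prev(cfg$country_prev_groups)

  # --- reference overall mortality as the status mixture ---
  mu_overall_ref <- mu_never
  for (g in genders) {
    for (i in seq_len(nY)) {
      mu_overall_ref[, g, i] <-
        prev_ref[, g, "never"] * mu_never[, g, i] +
        prev_ref[, g, "current"] * mu_current[, g, i] +
        prev_ref[, g, "former"] * mu_former[, g, i]
    }
  }
  mort_country <- pmin(mu_overall_ref * cfg$country_mort_offset, 1)

  # --- initiation / cessation ---
  init <- agy_table(0, ages, years)
  cess <- agy_table(0, ages, years)
  for (g in genders) {
    prof_i <- cfg$init_peak[[g]] *
      exp(-((ages - cfg$min_age) / cfg$init_width)^2) * jit(nA)
    prof_c <- pmin(cfg$cess_base + cfg$cess_slope * (ages - cfg$min_age),
                   cfg$cess_max) * jit(nA)
    for (i in seq_len(nY)) {
      init[, g, i] <- pmin(prof_i, 1)
      cess[, g, i] <- pmin(prof_c, 1)
    }
  }

  # --- life expectancy ---
  le_never_ref <- le_from_mu(mu_never)
  le_overall_ref <- le_from_mu(mu_overall_ref)
  le_country <- le_from_mu(mort_country)

  # --- population projection evolved under country overall mortality ---
  pop <- agy_table(0, ages, years)
  for (g in genders) {
    p0 <- numeric(nA)
    p0[1] <- cfg$pop_scale
    for (i in seq_len(nA - 1L)) {
      p0[i + 1L] <- p0[i] * (1 - mort_country[i, g, 1L])
    }
    pop[, g, 1L] <- p0
    for (t in seq_len(nY - 1L)) {
      pop[1L, g, t + 1L] <- pop[1L, g, t] * cfg$entrant_growth
      pop[-1L, g, t + 1L] <- pop[-nA, g, t] * (1 - mort_country[-nA, g, t])
    }
  }

  country <- country_bundle(
    population = pop, mortality = mort_country,
    le_base = le_country[, , 1L], prevalence_base = prev_country,
    base_year = cfg$base_year, end_year = cfg$end_year,
    min_age = cfg$min_age, max_age = cfg$max_age)
  reference <- reference_bundle(
    init = init, cess = cess, mu_never = mu_never, mu_current = mu_current,
    mu_former = mu_former, le_never = le_never_ref,
    prev_base = prev_ref[, , "current"],
    le_overall_base = le_overall_ref[, , 1L],
    mu_overall = mu_overall_ref)
  list(country = country, reference = reference, cfg = cfg)
}

#' Germany-like preset
#'
#' The default configuration ([fixture_config()]) plus the matching default
#' scenario parameters ([scenario_params()]): the 2012-2060, ages 18-99
#' setting with the published German multipliers and switching schedule.
#'
#' @param seed passed to [fixture_config()].
#' @return list with `bundles` (from [generate_bundles()]), `params`
#'   (a [scenario_params()]) and `rates` (from [localize_inputs()]).
#' @export
germany_preset <- function(seed = 1L) {
  b <- generate_bundles(fixture_config(seed = seed))
  rates <- localize_inputs(b$country, b$reference)
  list(bundles = b, params = scenario_params(), rates = rates)
}
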