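#' Bundle of country-specific model inputs
#'
#' Collects the compulsory country inputs: population projections, overall
#' mortality, base-year overall life expectancy, and base-year smoking-status
#' prevalence (never/current/former shares summing to 1 at every age/gender).
#' The modeling horizon is capped at 88 years and ages lie in \[0, 99\].
#'
#' @param population age x gender x year array of persons ([agy_table()]).
#' @param mortality age x gender x year array of overall annual death
#'   probabilities.
#' @param le_base age x gender matrix of overall life expectancy (years) in
#'   the base year.
#' @param prevalence_base age x gender x status array with statuses
#'   `never`, `current`, `former`; shares sum to 1 within 1e-9.
#' @param base_year,end_year first and last calendar year of the projection.
#' @param min_age,max_age modeled age range (integers in \[0, 99\]).
#' @return an object of class `country_bundle`.
#' @export
country_bundle <- function(population, mortality, le_base, prevalence_base,
                           base_year, end_year, min_age, max_age) {
  if (!(min_age >= 0 && min_age <= max_age && max_age <= 99)) {
    stop("need 0 <= min_age <= max_age <= 99")
  }
  if (end_year - base_year > 88) {
    stop("modeling period exceeds the 88-year maximum")
  }
  if (end_year < base_year) stop("end_year must be >= base_year")
  validate_agy(population, "count", "population")
  validate_agy(mortality, "rate", "mortality")
  validate_agy(le_base, "le", "le_base")
  ages <- min_age:max_age
  years <- base_year:end_year
  for (nm in c("population", "mortality")) {
    x <- get(nm)
    if (!identical(agy_ages(x), ages) || !identical(agy_years(x), years)) {
      stop(nm, " must cover exactly ages ", min_age, "-", max_age,
           " and years ", base_year, "-", end_year)
    }
  }
  if (!identical(agy_ages(le_base), ages)) {
    stop("le_base must cover exactly ages ", min_age, "-", max_age)
  }
  st <- dimnames(prevalence_base)[["status"]]
  if (!identical(st, c("never", "current", "former"))) {
    stop("prevalence_base needs a status dimension: never, current, former")
  }
  sums <- apply(prevalence_base, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("never+current+former shares must sum to 1 at every age/gender")
  }
  structure(list(population = population, mortality = mortality,
                 le_base = le_base, prevalence_base = prevalence_base,
                 base_year = as.integer(base_year),
                 end_year = as.integer(end_year),
                 min_age = as.integer(min_age), max_age = as.integer(max_age)),
            class = "country_bundle")
}

#' @export
print.country_bundle <- function(x, ...) {
  cat("<country_bundle> ages ", x$min_age, "-", x$max_age,
      ", years ", x$base_year, "-", x$end_year, "\n", sep = "")
  invisible(x)
}

#' Bundle of reference (US-style) rates
#'
#' The built-in rates every country adaptation is rescaled from: smoking
#' initiation and cessation, mortality by smoking status, never-smoker life
#' expectancy, plus the base-year current-smoking prevalence, overall life
#' expectancy and overall mortality of the reference population needed to
#' form the scaling ratios.
#'
#' @param init,cess age x gender x year arrays of annual initiation/cessation
#'   probabilities.
#' @param mu_never,mu_current,mu_former mortality by smoking status; the
#'   ordering `mu_current >= mu_former >= mu_never` is expected (a warning is
#'   emitted where user data violate it).
#' @param le_never age x gender x year never-smoker life expectancy (years).
#' @param prev_base age x gender matrix of base-year current-smoking
#'   prevalence.
#' @param le_overall_base age x gender matrix of base-year overall life
#'   expectancy.
#' @param mu_overall age x gender x year overall mortality of the reference
#'   population.
#' @return an object of class `reference_bundle`.
#' @export
reference_bundle <- function(init, cess, mu_never, mu_current, mu_former,
                             le_never, prev_base, le_overall_base,
                             mu_overall) {
  validate_agy(init, "rate", "init")
  validate_agy(cess, "rate", "cess")
  validate_agy(mu_never, "rate", "mu_never")
  validate_agy(mu_current, "rate", "mu_current")
  validate_agy(mu_former, "rate", "mu_former")
  validate_agy(le_never, "le", "le_never")
  validate_agy(prev_base, "rate", "prev_base")
  validate_agy(le_overall_base, "le", "le_overall_base")
  validate_agy(mu_overall, "rate", "mu_overall")
  for (nm in c("cess", "mu_never", "mu_current", "mu_former", "le_never",
               "mu_overall")) {
    check_same_index(init, get(nm), "init", nm)
  }
  if (any(mu_current < mu_former - 1e-12) || any(mu_former < mu_never - 1e-12)) {
    warning("mortality ordering mu_current >= mu_former >= mu_never violated")
  }
  structure(list(init = init, cess = cess, mu_never = mu_never,
                 mu_current = mu_current, mu_former = mu_former,
                 le_never = le_never, prev_base = prev_base,
                 le_overall_base = le_overall_base, mu_overall = mu_overall),
            class = "reference_bundle")
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("<reference_bundle> ages ", min(agy_ages(x$init)), "-",
      max(agy_ages(x$init)), ", years ", min(agy_years(x$init)), "-",
      max(agy_years(x$init)), "\n", sep = "")
  invisible(x)
}

#' Rescale never-smoker life expectancy to a country
#'
#' Never-smoker life expectancy for the country is obtained by multiplying
#' the reference never-smoker life expectancy by the age- and gender-specific
#' ratio of country to reference overall life expectancy in the base year;
#' each ratio is held constant over the whole modeling period.
#'
#' @param le_never_ref age x gender x year reference never-smoker life
#'   expectancy.
#' @param le_overall_country_base,le_overall_ref_base age x gender matrices
#'   of base-year overall life expectancy.
#' @return age x gender x year country never-smoker life expectancy.
#' @export
scale_life_expectancy <- function(le_never_ref, le_overall_country_base,
                                  le_overall_ref_base) {
  check_same_index(le_overall_country_base, le_overall_ref_base,
                   "country LE", "reference LE")
  if (any(le_overall_ref_base <= 0)) {
    stop("division error: reference overall life expectancy must be > 0")
  }
  ratio <- le_overall_country_base / le_overall_ref_base
  out <- le_never_ref
  for (y in dimnames(le_never_ref)[["year"]]) {
    out[, , y] <- le_never_ref[, , y] * ratio
  }
  out
}

#' Rescale initiation and cessation rates to a country
#'
#' Country initiation rates are the reference initiation rates scaled by the
#' ratio of country to reference current-smoking prevalence among young
#' adults (ages 18-24 by default); cessation rates are scaled by the same
#' ratio formed over ages 25-64.  Band prevalences are population-weighted
#' means (weights: the country's base-year population) unless
#' `weighted = FALSE`.  Scaled rates exceeding 1 are clipped to 1 with a
#' warning.
#'
#' @param ref a [reference_bundle()].
#' @param country_prev_base age x gender matrix of country base-year
#'   current-smoking prevalence.
#' @param pop_base age x gender matrix of country base-year population, used
#'   as band weights; required when `weighted = TRUE`.
#' @param init_band,cess_band integer age vectors defining the two bands.
#' @param weighted use population weights for the band means?
#' @return list with elements `init` and `cess` (age x gender x year arrays)
#'   and `ratios` (the per-gender scaling factors applied).
#' @export
scale_transition_rates <- function(ref, country_prev_base, pop_base = NULL,
                                   init_band = 18:24, cess_band = 25:64,
                                   weighted = TRUE) {
  if (weighted && is.null(pop_base)) {
    stop("pop_base is required for population-weighted band means")
  }
  band_mean <- function(prev, band, g) {
    a <- intersect(agy_ages(prev), band)
    if (length(a) == 0L) stop("age band outside the table's age range")
    idx <- as.character(a)
    if (weighted) {
      w <- pop_base[idx, g]
      sum(prev[idx, g] * w) / sum(w)
    } else {
      mean(prev[idx, g])
    }
  }
  init <- ref$init
  cess <- ref$cess
  ratios <- matrix(NA_real_, nrow = 2, ncol = 2,
                   dimnames = list(c("init", "cess"), c("male", "female")))
  for (g in c("male", "female")) {
    p_ref_i <- band_mean(ref$prev_base, init_band, g)
    p_ref_c <- band_mean(ref$prev_base, cess_band, g)
    if (p_ref_i <= 0 || p_ref_c <= 0) {
      stop("division error: reference band prevalence must be > 0")
    }
    ratios["init", g] <- band_mean(country_prev_base, init_band, g) / p_ref_i
    ratios["cess", g] <- band_mean(country_prev_base, cess_band, g) / p_ref_c
    init[, g, ] <- init[, g, ] * ratios["init", g]
    cess[, g, ] <- cess[, g, ] * ratios["cess", g]
  }
  clipped <- sum(init > 1) + sum(cess > 1)
  if (clipped > 0) {
    warning("clipped ", clipped, " scaled rate(s) above 1 down to 1")
    init[init > 1] <- 1
    cess[cess > 1] <- 1
  }
  list(init = init, cess = cess, ratios = ratios)
}

#' Rescale mortality by smoking status to a country
#'
#' Reference death rates by smoking status are multiplied by the ratio of
#' country to reference overall mortality, cell by cell.  A common ratio
#' preserves the ordering current >= former >= never; it is nevertheless
#' re-checked after scaling.
#'
#' @param ref a [reference_bundle()].
#' @param overall_country,overall_ref age x gender x year overall mortality.
#' @return list with elements `never`, `current`, `former` (scaled arrays).
#' @export
scale_mortality_by_status <- function(ref, overall_country, overall_ref) {
  check_same_index(overall_country, overall_ref, "country", "reference")
  if (any(overall_ref <= 0 & overall_country > 0)) {
    stop("division error: zero reference mortality where country mortality > 0")
  }
  ratio <- overall_country
  pos <- overall_ref > 0
  ratio[pos] <- overall_country[pos] / overall_ref[pos]
  ratio[!pos] <- 0
  out <- list(never = ref$mu_never * ratio,
              current = ref$mu_current * ratio,
              former = ref$mu_former * ratio)
  out <- lapply(out, function(m) {
    if (any(m > 1)) {
      warning("scaled status mortality above 1 clipped to 1")
      m[m > 1] <- 1
    }
    m
  })
  if (any(out$current < out$former - 1e-12) ||
      any(out$former < out$never - 1e-12)) {
    warning("scaled mortality ordering current >= former >= never violated")
  }
  out
}

#' Derive the full country rate set from a bundle pair
#'
#' Convenience wrapper applying [scale_transition_rates()],
#' [scale_mortality_by_status()] and [scale_life_expectancy()] in one call,
#' restricted to the country's age/year window.
#'
#' @param country a [country_bundle()].
#' @param ref a [reference_bundle()] covering at least the country's window.
#' @inheritParams scale_transition_rates
#' @return object of class `country_rates`: list with `init`, `cess`,
#'   `mu` (list never/current/former), `le_never`, and the scaling `ratios`.
#' @export
localize_inputs <- function(country, ref, init_band = 18:24,
                            cess_band = 25:64, weighted = TRUE) {
  ages <- as.character(country$min_age:country$max_age)
  years <- as.character(country$base_year:country$end_year)
  win <- function(x) x[ages, , years, drop = FALSE]
  ref_w <- ref
  for (nm in c("init", "cess", "mu_never", "mu_current", "mu_former",
               "le_never", "mu_overall")) {
    if (!all(ages %in% dimnames(ref[[nm]])[["age"]]) ||
        !all(years %in% dimnames(ref[[nm]])[["year"]])) {
      stop("coverage error: reference ", nm,
           " does not cover the country's age/year window")
    }
    ref_w[[nm]] <- win(ref[[nm]])
  }
  ref_w$prev_base <- ref$prev_base[ages, , drop = FALSE]
  ref_w$le_overall_base <- ref$le_overall_base[ages, , drop = FALSE]
  pop_base <- country$population[, , 1]
  tr <- scale_transition_rates(ref_w, country$prevalence_base[, , "current"],
                               pop_base = pop_base, init_band = init_band,
                               cess_band = cess_band, weighted = weighted)
  mu <- scale_mortality_by_status(ref_w, country$mortality, ref_w$mu_overall)
  le_never <- scale_life_expectancy(ref_w$le_never, country$le_base,
                                    ref_w$le_overall_base)
  structure(list(init = tr$init, cess = tr$cess, mu = mu,
                 le_never = le_never, ratios = tr$ratios),
            class = "country_rates")
}
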