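# Shared fixtures, all built in code at test time.

# A small fast setting: ages 18-50, 2012-2022.
small_cfg <- function(seed = 1L) {
  fixture_config(seed = seed, min_age = 18L, max_age = 50L,
                 base_year = 2012L, end_year = 2022L, pop_scale = 1e4)
}

small_setup <- function(seed = 1L) {
  b <- generate_bundles(small_cfg(seed))
  list(bundles = b,
       rates = localize_inputs(b$country, b$reference),
       params = scenario_params())
}

# Randomised country_rates over a compact window, for oracle comparisons.
# Ordering mu_current >= mu_former >= mu_never is maintained by construction.
random_rates <- function(seed, ages = 40:60, years = 2012:2023) {
  set.seed(seed)
  n <- length(ages) * 2 * length(years)
  mu_n <- agy_table(runif(n, 0.002, 0.02), ages, years)
  mu_c <- mu_n * agy_table(runif(n, 1.5, 3.0), ages, years)
  mu_f <- mu_n * agy_table(runif(n, 1.1, 1.5), ages, years)
  structure(list(
    init = agy_table(runif(n, 0, 0.10), ages, years),
    cess = agy_table(runif(n, 0, 0.12), ages, years),
    mu = list(never = mu_n, current = mu_c, former = mu_f),
    le_never = agy_table(runif(n, 10, 40), ages, years),
    ratios = NULL), class = "country_rates")
}

random_params <- function(seed) {
  set.seed(seed + 1000L)
  scenario_params(
    rr_nvp = runif(1, 0, 0.5),
    switch_scale = runif(1, 0.3, 1),
    decay_factor = runif(1, 0.85, 1),
    decay_start_year = 2015L,
    m_smk_init = runif(1, 0.5, 1.2),
    m_nvp_init = runif(1, 0.1, 0.6),
    m_smk_cess = runif(1, 0.6, 1.4),
    m_nvp_cess = runif(1, 0.6, 1.4),
    nvp_intro_year = 2012L,
    switch_rates = data.frame(
      age_lo = rep(c(0, 50), 2), age_hi = rep(c(49, 99), 2),
      gender = rep(c("male", "female"), each = 2),
      value = runif(4, 0.005, 0.04)))
}

random_shares0 <- function(seed) {
  set.seed(seed + 2000L)
  x <- c(runif(4, 0.05, 1), runif(3, 0, 0.3), 0, 0)
  names(x) <- use_states()
  x / sum(x)
}
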