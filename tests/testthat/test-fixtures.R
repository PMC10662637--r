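test_that("the generator is deterministic and satisfies all bundle invariants", {
  b1 <- generate_bundles(small_cfg())
  b2 <- generate_bundles(small_cfg())
  expect_identical(b1$country, b2$country)
  expect_identical(b1$reference, b2$reference)

  r <- b1$reference
  expect_true(all(r$mu_current >= r$mu_former))
  expect_true(all(r$mu_former >= r$mu_never))
  sums <- apply(b1$country$prevalence_base, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(b1$country$population >= 0))
  expect_true(all(b1$country$mortality >= 0 & b1$country$mortality <= 1))
  # constructing the bundles re-runs every validator without warnings
  expect_silent(generate_bundles(small_cfg()))
})

test_that("offset factors of one make country and reference rates coincide", {
  cfg <- fixture_config(min_age = 18, max_age = 50, base_year = 2012,
                        end_year = 2022, pop_scale = 1e4,
                        country_mort_offset = 1,
                        country_prev_groups = us_prevalence_groups())
  b <- generate_bundles(cfg)
  rates <- localize_inputs(b$country, b$reference)
  expect_equal(unname(rates$ratios), matrix(1, 2, 2))
  expect_equal(rates$init, b$reference$init)
  expect_equal(rates$cess, b$reference$cess)
  expect_equal(rates$mu$never, b$reference$mu_never)
  expect_equal(rates$le_never, b$reference$le_never)
})

test_that("generated prevalence aggregates match a direct weighted mean", {
  b <- generate_bundles(small_cfg())
  co <- b$country
  for (g in c("male", "female")) {
    w <- co$population[, g, 1]
    direct <- sum(co$prevalence_base[, g, "current"] * w) / sum(w)
    traj <- run_scenario(co, localize_inputs(co, b$reference),
                         scenario = "no_nvp")
    prev <- traj_prevalence(traj)
    got <- prev$smoking[prev$gender == g & prev$year == co$base_year]
    expect_equal(got, direct, tolerance = 1e-12)
  }
})

test_that("bundles survive a round trip through delimited files", {
  dir <- withr::local_tempdir()
  b <- generate_bundles(small_cfg())
  manifest <- write_bundles(b, dir)
  back <- read_bundles(manifest)
  expect_equal(back$country$population, b$country$population)
  expect_equal(back$country$prevalence_base, b$country$prevalence_base)
  expect_equal(back$reference$init, b$reference$init)
  expect_equal(back$reference$mu_overall, b$reference$mu_overall)
  expect_equal(back$country$base_year, b$country$base_year)
})

test_that("life-table construction behaves sensibly", {
  ages <- 18:99; years <- 2012
  mu <- agy_table(rep(pmin(4e-5 * exp(0.09 * (18:99)), 0.9), 2), ages, years)
  le <- le_from_mu(mu)
  # life expectancy declines with age and stays positive
  expect_true(all(diff(le[, "male", 1]) < 0))
  expect_true(all(le > 0))
  # halving mortality increases life expectancy everywhere
  le2 <- le_from_mu(mu / 2)
  expect_true(all(le2 > le))
})

test_that("the microsimulation refuses settings too noisy to be an oracle", {
  rates <- random_rates(1)
  expect_error(microsim_oracle(rates, scenario = "no_nvp",
                               shares0 = c(never = 1), age0 = 45,
                               gender = "male", n_steps = 5,
                               n_agents = 500), "noisy")
  expect_error(microsim_oracle(rates, scenario = "no_nvp",
                               shares0 = c(never = 1), age0 = 45,
                               gender = "male", n_steps = 20,
                               n_agents = 1e4), "horizon")
})

test_that("with all rates zero every agent stays in its initial state", {
  ages <- 40:55; years <- 2012:2020
  rates <- structure(list(
    init = agy_table(0, ages, years), cess = agy_table(0, ages, years),
    mu = list(never = agy_table(0, ages, years),
              current = agy_table(0, ages, years),
              former = agy_table(0, ages, years)),
    le_never = agy_table(20, ages, years), ratios = NULL),
    class = "country_rates")
  x0 <- c(never = 0.5, current_smoker = 0.3, former_smoker = 0.2)
  ms <- microsim_oracle(rates, scenario = "no_nvp", shares0 = x0, age0 = 42,
                        gender = "female", n_steps = 6, n_agents = 5000,
                        seed = 7)
  for (k in 2:7) expect_identical(ms$share[, k], ms$share[, 1])
  expect_equal(ms$n_alive, rep(5000L, 7))
})

test_that("with degenerate probabilities the oracle equals the engine exactly", {
  ages <- 40:55; years <- 2012:2020
  rates <- structure(list(
    init = agy_table(1, ages, years), cess = agy_table(0, ages, years),
    mu = list(never = agy_table(0, ages, years),
              current = agy_table(0, ages, years),
              former = agy_table(0, ages, years)),
    le_never = agy_table(20, ages, years), ratios = NULL),
    class = "country_rates")
  x0 <- c(never = 1)
  ms <- microsim_oracle(rates, scenario = "no_nvp", shares0 = x0, age0 = 42,
                        gender = "male", n_steps = 4, n_agents = 2000)
  eng <- evolve_cohort(x0, 42, "male", 4, rates, scenario = "no_nvp")
  expect_equal(unname(ms$share), unname(eng))
  expect_true(all(eng["current_smoker", -1] == 1))
})

test_that("more agents bring the oracle closer to the engine on average", {
  seeds <- 1:5
  err <- sapply(seeds, function(sd) {
    rates <- random_rates(sd)
    x0 <- random_shares0(sd)
    eng <- evolve_cohort(x0, 42, "male", 6, rates, scenario = "no_nvp")
    sapply(c(2e3, 3.2e4), function(n) {
      ms <- microsim_oracle(rates, scenario = "no_nvp", shares0 = x0,
                            age0 = 42, gender = "male", n_steps = 6,
                            n_agents = n, seed = sd + 100)
      max(abs(ms$share - eng))
    })
  })
  expect_lt(mean(err[2, ]), mean(err[1, ]))
})
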