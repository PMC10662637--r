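test_that("initial occupancy splits former smokers by the age-35 rule", {
  s <- small_setup()
  b <- s$bundles$country
  S0 <- init_no_nvp(b)
  prev <- b$prevalence_base
  # under 35 the entire former pool is low-risk (quit before 35 by necessity)
  expect_equal(unname(S0["former_smoker_lowrisk", "25", "male"]),
               unname(prev["25", "male", "former"]))
  expect_equal(unname(S0["former_smoker", "25", "male"]), 0)
  # at 35+ it carries the full former-smoker excess
  expect_equal(unname(S0["former_smoker", "40", "female"]),
               unname(prev["40", "female", "former"]))
  expect_equal(unname(S0["former_smoker_lowrisk", "40", "female"]), 0)
  expect_equal(unname(colSums(S0[, , "male"])), rep(1, ncol(S0)),
               tolerance = 1e-12)
  # an all-never population is a single-state occupancy
  prev2 <- prev; prev2[] <- 0; prev2[, , "never"] <- 1
  b2 <- country_bundle(b$population, b$mortality, b$le_base, prev2,
                       b$base_year, b$end_year, b$min_age, b$max_age)
  S02 <- init_no_nvp(b2)
  expect_true(all(S02["never", , ] == 1))
})

test_that("the counterfactual step matches a hand-computed year", {
  # survivors then transitions then renormalisation, computed by hand:
  occ <- c(never = 0.6, current_smoker = 0.3, former_smoker = 0.1)
  mu <- c(never = 0.01, current = 0.03, former = 0.02)
  sv <- c(0.6 * 0.99, 0.3 * 0.97, 0.1 * 0.98)      # 0.594 0.291 0.098
  nv <- c(sv[1] * 0.95,                            # never minus initiators
          sv[2] * 0.9 + sv[1] * 0.05,              # current + initiators
          sv[3] + sv[2] * 0.1)                     # former + quitters
  expected <- nv / sum(nv)
  out <- step_no_nvp(occ, init = 0.05, cess = 0.1, mu = mu, age = 60)
  expect_equal(unname(out[c("never", "current_smoker", "former_smoker")]),
               expected, tolerance = 1e-12)
  expect_equal(sum(out), 1)

  # identity: no flows and equal mortality leave occupancy unchanged
  id <- step_no_nvp(occ, 0, 0, c(never = 0.02, current = 0.02, former = 0.02),
                    age = 60)
  expect_equal(unname(id[names(occ)]), unname(occ))

  # forced single-flow case
  f <- step_no_nvp(c(never = 1), init = 0.1, cess = 0,
                   mu = c(never = 0.05, current = 0.05, former = 0.05),
                   age = 30)
  expect_equal(unname(f["never"]), 0.9)
  expect_equal(unname(f["current_smoker"]), 0.1)
})

test_that("cessation routes to the low-risk substate before age 35", {
  occ <- c(never = 0.5, current_smoker = 0.5)
  mu <- c(never = 0, current = 0, former = 0)
  young <- step_no_nvp(occ, 0, 0.2, mu, age = 30)   # attained age 31
  old <- step_no_nvp(occ, 0, 0.2, mu, age = 40)
  expect_equal(unname(young["former_smoker_lowrisk"]), 0.1)
  expect_equal(unname(young["former_smoker"]), 0)
  expect_equal(unname(old["former_smoker"]), 0.1)
  # boundary: quitting with attained age 34 is low-risk, 35 is not
  at34 <- step_no_nvp(occ, 0, 0.2, mu, age = 33)
  at35 <- step_no_nvp(occ, 0, 0.2, mu, age = 34)
  expect_equal(unname(at34["former_smoker_lowrisk"]), 0.1)
  expect_equal(unname(at35["former_smoker"]), 0.1)
})

test_that("the NVP step routes switching by age and reduces to the counterfactual", {
  mu <- c(never = 0.01, current = 0.01, former = 0.01)
  r <- list(smk_init = 0, nvp_init = 0, smk_cess = 0.1, nvp_cess = 0,
            switch = 0.02)
  out <- step_nvp(c(current_smoker = 1), r, mu, age = 40, rr_nvp = 0)
  expect_equal(unname(out["current_smoker"]), 0.88)
  expect_equal(unname(out["former_smoker"]), 0.10)
  expect_equal(unname(out["fs_nvp_user"]), 0.02)
  young <- step_nvp(c(current_smoker = 1), r, mu, age = 25, rr_nvp = 0)
  expect_equal(unname(young["nvp_user_exsmoker_lowrisk"]), 0.02)
  expect_equal(unname(young["former_smoker_lowrisk"]), 0.10)

  # with all NVP flows zero the step equals the counterfactual step
  occ <- c(never = 0.6, current_smoker = 0.3, former_smoker = 0.1)
  r0 <- list(smk_init = 0.05, nvp_init = 0, smk_cess = 0.1, nvp_cess = 0,
             switch = 0)
  expect_identical(step_nvp(occ, r0, mu, age = 50, rr_nvp = 0.4),
                   step_no_nvp(occ, 0.05, 0.1, mu, age = 50))
})

test_that("a one-year run returns only the initial occupancy", {
  s <- small_setup()
  b <- s$bundles$country
  b1 <- country_bundle(
    b$population[, , 1, drop = FALSE], b$mortality[, , 1, drop = FALSE],
    b$le_base, b$prevalence_base, b$base_year, b$base_year,
    b$min_age, b$max_age)
  r1 <- s$rates
  for (nm in c("init", "cess")) r1[[nm]] <- r1[[nm]][, , 1, drop = FALSE]
  r1$mu <- lapply(r1$mu, function(m) m[, , 1, drop = FALSE])
  r1$le_never <- r1$le_never[, , 1, drop = FALSE]
  traj <- run_scenario(b1, r1, scenario = "no_nvp")
  expect_equal(dim(traj$share)[4], 1L)
  expect_equal(traj$share[, , , 1], init_no_nvp(b1))
})

test_that("a closed cohort under constant rates follows the matrix power", {
  ages <- 40:60; years <- 2012:2020
  rates <- structure(list(
    init = agy_table(0.03, ages, years),
    cess = agy_table(0.08, ages, years),
    mu = list(never = agy_table(0.010, ages, years),
              current = agy_table(0.025, ages, years),
              former = agy_table(0.016, ages, years)),
    le_never = agy_table(20, ages, years), ratios = NULL),
    class = "country_rates")
  x0 <- c(never = 0.5, current_smoker = 0.4, former_smoker = 0.1)
  sh <- evolve_cohort(x0, 45, "male", 8, rates, scenario = "no_nvp")

  # independent construction: one-step operator as an explicit matrix
  M <- matrix(0, 9, 9)
  sv <- c(0.990, 0.975, 0.984, 0.990, rep(0.99, 5))  # survival by state (rr 0)
  M[1, 1] <- sv[1] * (1 - 0.03)
  M[2, 1] <- sv[1] * 0.03
  M[2, 2] <- sv[2] * (1 - 0.08)
  M[3, 2] <- sv[2] * 0.08        # age 45+: routed to full-excess former
  M[3, 3] <- sv[3]
  M[4, 4] <- sv[4]
  x <- c(0.5, 0.4, 0.1, rep(0, 6))
  pw <- x
  for (k in 1:8) pw <- M %*% pw
  expect_equal(unname(sh[, 9]), unname(drop(pw) / sum(pw)), tolerance = 1e-12)
})

test_that("state shares always sum to one along full runs", {
  s <- small_setup()
  b <- s$bundles$country
  for (sc in c("no_nvp", "nvp")) {
    traj <- run_scenario(b, s$rates, s$params, scenario = sc)
    sums <- apply(traj$share, c(2, 3, 4), sum)
    expect_lt(max(abs(sums - 1)), 1e-9)
    # counts rescale shares to the projected population
    csum <- apply(traj$count, c(2, 3, 4), sum)
    expect_lt(max(abs(csum / b$population - 1)), 1e-6)
  }
})

test_that("evolving absolute counts conserves people through survival", {
  s <- small_setup()
  b <- s$bundles$country
  traj <- run_scenario(b, s$rates, s$params, scenario = "no_nvp",
                       count_mode = "evolve")
  # a cohort's headcount shrinks as it ages (mortality only, no migration)
  cnt <- apply(traj$count, c(2, 3, 4), sum)
  cohort <- sapply(0:10, function(k) cnt[as.character(30 + k), "male", k + 1])
  expect_true(all(diff(cohort) < 0))
  # shares agree with the projection-mode run exactly
  traj2 <- run_scenario(b, s$rates, s$params, scenario = "no_nvp")
  expect_identical(traj$share, traj2$share)
})

test_that("raising the switch rate moves smokers into vaping states monotonely", {
  s <- small_setup()
  b <- s$bundles$country
  p_lo <- s$params; p_lo$switch_scale <- 0.5
  p_hi <- s$params; p_hi$switch_scale <- 1.0
  t_lo <- run_scenario(b, s$rates, p_lo, scenario = "nvp")
  t_hi <- run_scenario(b, s$rates, p_hi, scenario = "nvp")
  cs_lo <- t_lo$share["current_smoker", , , ]
  cs_hi <- t_hi$share["current_smoker", , , ]
  expect_true(all(cs_hi <= cs_lo + 1e-12))
  nvp_states <- c("nvp_user", "nvp_user_exsmoker_lowrisk", "fs_nvp_user")
  v_lo <- apply(t_lo$share[nvp_states, , , ], c(2, 3, 4), sum)
  v_hi <- apply(t_hi$share[nvp_states, , , ], c(2, 3, 4), sum)
  expect_true(all(v_hi >= v_lo - 1e-12))
})

test_that("trajectory export is a tidy long table", {
  s <- small_setup()
  traj <- run_scenario(s$bundles$country, s$rates, scenario = "no_nvp")
  df <- trajectory_to_df(traj)
  expect_named(df, c("year", "age", "gender", "state", "share", "count"))
  expect_equal(nrow(df), prod(dim(traj$share)))
  cell <- df[df$year == 2012 & df$age == 30 & df$gender == "male" &
               df$state == "current_smoker", ]
  expect_equal(cell$share,
               unname(traj$share["current_smoker", "30", "male", "2012"]))
})
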