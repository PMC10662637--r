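test_that("uniform group expansion assigns each age its covering group's value", {
  g <- data.frame(age_lo = rep(c(18, 30), 2), age_hi = rep(c(29, 44), 2),
                  gender = rep(c("male", "female"), each = 2),
                  value = c(0.1, 0.2, 0.3, 0.4))
  m <- expand_groups_uniform(g, 18:44)
  expect_equal(unname(m["29", "male"]), 0.1)   # closed-interval boundary
  expect_equal(unname(m["30", "male"]), 0.2)
  expect_true(all(m[as.character(18:29), "female"] == 0.3))

  # single group covering everything gives a constant table
  one <- data.frame(age_lo = rep(0, 2), age_hi = rep(99, 2),
                    gender = c("male", "female"), value = c(0.012, 0.01))
  expect_true(all(expand_groups_uniform(one, 0:99)[, "male"] == 0.012))

  # group-averaging with equal weights recovers the grouped input exactly
  for (gg in c("male", "female")) {
    for (i in which(g$gender == gg)) {
      ages <- as.character(g$age_lo[i]:g$age_hi[i])
      expect_equal(mean(m[ages, gg]), g$value[i])
    }
  }
})

test_that("group expansion rejects gaps and overlaps", {
  gap <- data.frame(age_lo = rep(c(18, 40), 2), age_hi = rep(c(29, 50), 2),
                    gender = rep(c("male", "female"), each = 2),
                    value = 0.1)
  expect_error(expand_groups_uniform(gap, 18:50), "coverage")
  ovl <- data.frame(age_lo = rep(c(18, 25), 2), age_hi = rep(c(29, 50), 2),
                    gender = rep(c("male", "female"), each = 2),
                    value = 0.1)
  expect_error(expand_groups_uniform(ovl, 18:50), "overlap")
  expect_error(expand_groups_uniform(gap[0, ], 18:50), "empty")
})

german_groups <- function() {
  data.frame(age_lo = rep(c(18, 30, 45, 65), 2),
             age_hi = rep(c(29, 44, 64, 99), 2),
             gender = rep(c("male", "female"), each = 4),
             value = rep(c(0.347, 0.345, 0.304, 0.120), 2))
}

test_that("prevalence smoothing hits midpoints exactly and extends flat", {
  m <- smooth_group_prevalence(german_groups(), 18:99)
  # group values recovered at midpoints 23, 37, 54, 82
  expect_identical(unname(m["23", "male"]), 0.347)
  expect_identical(unname(m["37", "male"]), 0.345)
  expect_identical(unname(m["54", "male"]), 0.304)
  expect_identical(unname(m["82", "male"]), 0.120)
  # ages 18-22 carry the value at the first midpoint (23)
  expect_true(all(m[as.character(18:22), "male"] == 0.347))
  # ages 83-99 carry the value at the last midpoint (82)
  expect_true(all(m[as.character(83:99), "female"] == 0.120))
  # output bounded by the group values everywhere
  expect_true(all(m >= 0.120 & m <= 0.347))
})

test_that("prevalence smoothing interpolates linearly between midpoints", {
  g <- data.frame(age_lo = rep(c(18, 30), 2), age_hi = rep(c(29, 44), 2),
                  gender = rep(c("male", "female"), each = 2),
                  value = rep(c(0.347, 0.345), 2))
  m <- smooth_group_prevalence(g, 18:44)
  # midpoints 23 and 37: age 30 lies 7/14 of the way
  expect_equal(unname(m["30", "male"]),
               0.347 + (30 - 23) / (37 - 23) * (0.345 - 0.347))
  expect_equal(unname(m["30", "male"]), 0.346)
  # one group -> constant table
  one <- data.frame(age_lo = c(18, 18), age_hi = c(99, 99),
                    gender = c("male", "female"), value = c(0.3, 0.25))
  expect_true(all(smooth_group_prevalence(one, 18:99)[, "male"] == 0.3))
})

test_that("life-expectancy scaling applies the constant base-year ratio", {
  ages <- 18:20; years <- 2012:2014
  le_ref <- agy_table(20, ages, years)
  le_c <- ag_matrix(81, ages)
  le_r <- ag_matrix(79, ages)
  out <- scale_life_expectancy(le_ref, le_c, le_r)
  expect_equal(unname(out["18", "male", "2014"]), 20 * 81 / 79)
  # ratio 1 is the identity
  expect_identical(scale_life_expectancy(le_ref, le_r, le_r), le_ref)
  # genders scale independently
  le_c2 <- le_c; le_c2[, "female"] <- 79 * 1.5
  out2 <- scale_life_expectancy(le_ref, le_c2, le_r)
  expect_equal(unname(out2["19", "female", "2012"]), 30)
  expect_equal(unname(out2["19", "male", "2012"]), 20 * 81 / 79)
  expect_error(scale_life_expectancy(le_ref, le_c, ag_matrix(0, ages)),
               "division")
})

test_that("initiation/cessation scaling uses the band prevalence ratios", {
  s <- small_setup()
  ref <- s$bundles$reference
  ages <- agy_ages(ref$init)
  # constant prevalences make the weighted band means exact
  prev_country <- ag_matrix(0.347, ages)
  ref2 <- ref
  ref2$prev_base <- ag_matrix(0.213, ages)
  ref2$init <- agy_table(0.02, ages, agy_years(ref$init))
  ref2$cess <- agy_table(0.05, ages, agy_years(ref$cess))
  pop <- s$bundles$country$population[, , 1]
  out <- scale_transition_rates(ref2, prev_country, pop)
  expect_equal(unname(out$init["20", "male", "2013"]), 0.02 * 0.347 / 0.213)
  expect_equal(unname(out$cess["40", "female", "2015"]), 0.05 * 0.347 / 0.213)
  # equal prevalence leaves rates unchanged
  same <- scale_transition_rates(ref2, ref2$prev_base, pop)
  expect_equal(same$init, ref2$init)
  expect_equal(same$cess, ref2$cess)
  # overshoot clips at 1 with a warning
  ref3 <- ref2
  ref3$init <- agy_table(0.9, ages, agy_years(ref$init))
  expect_warning(big <- scale_transition_rates(ref3, prev_country, pop),
                 "clip")
  expect_true(all(big$init <= 1))
  # zero reference band prevalence is an error
  ref4 <- ref2; ref4$prev_base[] <- 0
  expect_error(scale_transition_rates(ref4, prev_country, pop), "division")
})

test_that("status mortality scaling multiplies by the overall ratio per cell", {
  ages <- 30:32; years <- 2012:2013
  ref <- list(mu_never = agy_table(0.010, ages, years),
              mu_current = agy_table(0.020, ages, years),
              mu_former = agy_table(0.014, ages, years))
  us <- agy_table(0.013, ages, years)
  country <- us * 1.1
  out <- scale_mortality_by_status(ref, country, us)
  expect_equal(unname(out$current["30", "male", "2012"]), 0.022)
  # the excess over never scales by the same ratio
  expect_equal(out$current - out$never, 1.1 * (ref$mu_current - ref$mu_never))
  # ratio 1 is the identity
  idn <- scale_mortality_by_status(ref, us, us)
  expect_equal(idn$never, ref$mu_never)
  # year-varying ratios apply per year
  country2 <- us; country2[, , "2013"] <- us[, , "2013"] * 2
  out2 <- scale_mortality_by_status(ref, country2, us)
  expect_equal(unname(out2$former["31", "male", "2012"]), 0.014)
  expect_equal(unname(out2$former["31", "male", "2013"]), 0.028)
  # zero reference mortality with nonzero country mortality errors
  us0 <- us; us0["30", "male", "2012"] <- 0
  expect_error(scale_mortality_by_status(ref, country, us0), "division")
})

test_that("scaling commutes with gender slicing", {
  s <- small_setup()
  b <- s$bundles
  rates <- localize_inputs(b$country, b$reference)
  # scale-then-slice equals what the per-gender ratio gives directly
  for (g in c("male", "female")) {
    expect_equal(rates$init[, g, ],
                 b$reference$init[, g, ] * rates$ratios["init", g])
    expect_equal(rates$cess[, g, ],
                 b$reference$cess[, g, ] * rates$ratios["cess", g])
  }
})

test_that("bundle validators enforce the stated invariants", {
  s <- small_setup()
  b <- s$bundles$country
  # prevalence shares must sum to one
  bad_prev <- b$prevalence_base
  bad_prev[1, 1, "never"] <- bad_prev[1, 1, "never"] + 0.01
  expect_error(country_bundle(b$population, b$mortality, b$le_base, bad_prev,
                              b$base_year, b$end_year, b$min_age, b$max_age),
               "sum to 1")
  # horizon cap
  expect_error(country_bundle(b$population, b$mortality, b$le_base,
                              b$prevalence_base, 2012, 2101, 18, 50),
               "88")
  # mortality ordering violation on reference data warns
  r <- s$bundles$reference
  mu_bad <- r$mu_former
  mu_bad[1, 1, 1] <- r$mu_current[1, 1, 1] * 2
  expect_warning(reference_bundle(r$init, r$cess, r$mu_never, r$mu_current,
                                  mu_bad, r$le_never, r$prev_base,
                                  r$le_overall_base, r$mu_overall),
                 "ordering")
})
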