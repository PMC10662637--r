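#' Use states of the model
#'
#' Nine mutually exclusive tobacco/NVP use states.  The counterfactual
#' (No-NVP) scenario occupies only the first four.  Dual users of cigarettes
#' and NVPs are counted as current smokers.  The `_lowrisk` substates carry
#' never-smoker baseline mortality under the quit-before-35 rule; `fs_nvp_user`
#' is a former smoker (quit at 35+) who currently vapes.
#'
#' @return character vector of state names, in canonical order.
#' @export
use_states <- function() {
  c("never", "current_smoker", "former_smoker", "former_smoker_lowrisk",
    "nvp_user", "nvp_user_exsmoker_lowrisk", "fs_nvp_user",
    "former_nvp_user", "former_nvp_user_exsmoker")
}

# Excess mortality (over never smokers) for each state, given the smoking
# excesses ec = mu_current - mu_never, ef = mu_former - mu_never and the NVP
# relative-risk multiplier.  Shapes broadcast (scalars or equal-dim arrays).
# mode governs the former-smoker-who-vapes composition.
state_excess_list <- function(mu_never, mu_current, mu_former, rr,
                              mode = "additive") {
  ec <- pmax(mu_current - mu_never, 0)
  ef <- pmax(mu_former - mu_never, 0)
  fs_nvp <- if (mode == "additive") ef + rr * ec else rr * ec
  fnvp_ex <- if (mode == "additive") ef + rr * ef else rr * ef
  list(never = 0 * ec, current_smoker = ec, former_smoker = ef,
       former_smoker_lowrisk = 0 * ec,
       nvp_user = rr * ec, nvp_user_exsmoker_lowrisk = rr * ec,
       fs_nvp_user = fs_nvp, former_nvp_user = rr * ef,
       former_nvp_user_exsmoker = fnvp_ex)
}

# 9-vector of state mortality from scalar status rates.
state_mu <- function(mu_never, mu_current, mu_former, rr, mode = "additive") {
  ex <- state_excess_list(mu_never, mu_current, mu_former, rr, mode)
  mu_never + unlist(ex, use.names = TRUE)
}

# One model year for k cohorts at once.  X: 9 x k occupancy, MU: 9 x k state
# mortality, rates: length-k vectors, lowrisk: logical k — TRUE when the
# attained age at year end is below the age-35 threshold.  Order within the
# year: survival, then transitions among survivors.  Returns the
# unnormalised 9 x k next-year occupancy.
.step_core <- function(X, MU, smk_init, nvp_init, smk_cess, nvp_cess,
                       sw, lowrisk) {
  if (any(MU > 1)) stop("data error: state mortality above 1")
  if (any(smk_init + nvp_init > 1 + 1e-12)) {
    stop("feasibility error: smk_init + nvp_init > 1")
  }
  if (any(smk_cess + sw > 1 + 1e-12)) {
    stop("feasibility error: smk_cess + switch > 1")
  }
  S <- X * (1 - MU)
  quit <- S[2L, ] * smk_cess
  swch <- S[2L, ] * sw
  vcess <- nvp_cess
  out <- S
  out[1L, ] <- S[1L, ] * (1 - smk_init - nvp_init)
  out[2L, ] <- S[2L, ] * (1 - smk_cess - sw) + S[1L, ] * smk_init
  out[3L, ] <- S[3L, ] + quit * !lowrisk
  out[4L, ] <- S[4L, ] + quit * lowrisk
  out[5L, ] <- S[5L, ] * (1 - vcess) + S[1L, ] * nvp_init
  out[6L, ] <- S[6L, ] * (1 - vcess) + swch * lowrisk
  out[7L, ] <- S[7L, ] * (1 - vcess) + swch * !lowrisk
  out[8L, ] <- S[8L, ] + (S[5L, ] + S[6L, ]) * vcess
  out[9L, ] <- S[9L, ] + S[7L, ] * vcess
  out
}

as_state_vector <- function(occupancy) {
  states <- use_states()
  x <- stats::setNames(numeric(9L), states)
  if (is.null(names(occupancy))) {
    if (length(occupancy) != 9L) {
      stop("unnamed occupancy must have length 9")
    }
    x[] <- occupancy
  } else {
    bad <- setdiff(names(occupancy), states)
    if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "))
    x[names(occupancy)] <- occupancy
  }
  if (any(x < 0)) stop("data error: negative occupancy share")
  x
}

#' Advance one cohort one year (counterfactual dynamics)
#'
#' Applies status-specific survival, then smoking initiation
#' (never to current) and net cessation (current to former) among survivors,
#' then renormalises the shares to sum to 1.  Cessation routes to the
#' low-risk former-smoker substate when the attained age at year end is below
#' the age-35 threshold.  Former states are absorbing (cessation is net of
#' relapse).
#'
#' @param occupancy named vector of state shares (subset of [use_states()]),
#'   summing to 1.
#' @param init,cess annual initiation/cessation probabilities.
#' @param mu named vector `c(never=, current=, former=)` of annual death
#'   probabilities by smoking status.
#' @param age current age of the cohort (attained age is `age + 1`).
#' @param age35_threshold the quit-before-35 rule threshold.
#' @return named length-9 vector of next-year shares, summing to 1.
#' @export
step_no_nvp <- function(occupancy, init, cess, mu, age, age35_threshold = 35) {
  x <- as_state_vector(occupancy)
  MU <- matrix(state_mu(mu[["never"]], mu[["current"]], mu[["former"]],
                        rr = 0), ncol = 1)
  lowrisk <- (age + 1) <= (age35_threshold - 1)
  nxt <- .step_core(matrix(x, ncol = 1), MU, init, 0, cess, 0, 0, lowrisk)
  stats::setNames(drop(nxt) / sum(nxt), use_states())
}

#' Advance one cohort one year (NVP dynamics)
#'
#' As [step_no_nvp()] with the vaping flows active: never smokers may
#' initiate NVP use, current smokers may switch to exclusive NVP use (routed
#' to a low-risk substate below the age-35 threshold, else to the
#' former-smoker-who-vapes state), and vapers may quit vaping.  State
#' mortality is never-smoker mortality plus the state's excess, with NVP
#' excess at `rr_nvp` times the corresponding smoking excess.
#'
#' @inheritParams step_no_nvp
#' @param rates named list of annual probabilities: `smk_init`, `nvp_init`,
#'   `smk_cess`, `nvp_cess`, `switch`.
#' @param rr_nvp NVP relative-risk multiplier.
#' @param fsnvp_excess_mode see [scenario_params()].
#' @return named length-9 vector of next-year shares, summing to 1.
#' @export
step_nvp <- function(occupancy, rates, mu, age, rr_nvp = 0.05,
                     age35_threshold = 35,
                     fsnvp_excess_mode = "additive") {
  x <- as_state_vector(occupancy)
  MU <- matrix(state_mu(mu[["never"]], mu[["current"]], mu[["former"]],
                        rr = rr_nvp, mode = fsnvp_excess_mode), ncol = 1)
  lowrisk <- (age + 1) <= (age35_threshold - 1)
  nxt <- .step_core(matrix(x, ncol = 1), MU,
                    rates$smk_init, rates$nvp_init,
                    rates$smk_cess, rates$nvp_cess, rates$switch, lowrisk)
  stats::setNames(drop(nxt) / sum(nxt), use_states())
}

#' Base-year occupancy from smoking prevalence
#'
#' Distributes the base-year never/current/former prevalence over the model
#' states.  Former smokers below the age-35 threshold start in the low-risk
#' substate (they necessarily quit before 35); at or above it the initial
#' former pool carries the full former-smoker excess.
#'
#' @param bundle a [country_bundle()].
#' @param age35_threshold the quit-before-35 rule threshold.
#' @return 9 x age x gender array of base-year shares.
#' @export
init_no_nvp <- function(bundle, age35_threshold = 35) {
  ages <- bundle$min_age:bundle$max_age
  prev <- bundle$prevalence_base
  S0 <- array(0, dim = c(9L, length(ages), 2L),
              dimnames = list(state = use_states(),
                              age = as.character(ages),
                              gender = c("male", "female")))
  young <- ages < age35_threshold
  for (g in c("male", "female")) {
    S0["never", , g] <- prev[, g, "never"]
    S0["current_smoker", , g] <- prev[, g, "current"]
    S0["former_smoker_lowrisk", young, g] <- prev[young, g, "former"]
    S0["former_smoker", !young, g] <- prev[!young, g, "former"]
  }
  S0
}

# Entrant state distribution at min_age.  NVP scenario (from the intro year):
# the entering current-smoker share is multiplied by m_smk_init, an NVP-user
# share of m_nvp_init x (base current share) is added, remainder to never.
entrant_shares <- function(base_col, params = NULL, year = NULL) {
  x <- base_col
  if (!is.null(params) && !is.null(year) && year >= params$nvp_intro_year) {
    c0 <- base_col["current_smoker"]
    x["current_smoker"] <- params$m_smk_init * c0
    x["nvp_user"] <- params$m_nvp_init * c0
    # multipliers summing above 1 draw the extra entrants from the never pool
    x["never"] <- base_col["never"] + (1 - params$m_smk_init - params$m_nvp_init) * c0
    if (x["never"] < 0) {
      stop("entrant multipliers allocate more than the never-smoker share")
    }
  }
  x / sum(x)
}

#' Run a full scenario over all cohorts
#'
#' Evolves the whole population year by year from the base year to the end
#' year.  Each cohort ages one year per step; new entrants appear at the
#' minimum age with the base-year entry distribution (multiplier-adjusted in
#' the NVP scenario); the oldest age class exits after its year.  Shares
#' evolve and are renormalised each year; person counts are obtained by
#' rescaling shares to the projected population (`count_mode = "projection"`,
#' the default, which avoids double-counting deaths already embodied in the
#' projection) or by evolving absolute counts under the model's own survival
#' (`count_mode = "evolve"`).
#'
#' @param bundle a [country_bundle()].
#' @param rates a `country_rates` object from [localize_inputs()].
#' @param params a [scenario_params()]; required for `scenario = "nvp"`
#'   (used only for the age-35 threshold in the counterfactual, where it
#'   defaults to 35).
#' @param scenario `"no_nvp"` or `"nvp"`.
#' @param schedule optional pre-built [build_schedule()] result; built from
#'   `rates` and `params` when missing.
#' @param count_mode `"projection"` or `"evolve"` (see Details).
#' @return object of class `state_trajectory`: list with `share` and `count`
#'   (9 x age x gender x year arrays), `population`, `scenario`, `params`.
#' @export
run_scenario <- function(bundle, rates, params = NULL,
                         scenario = c("no_nvp", "nvp"), schedule = NULL,
                         count_mode = c("projection", "evolve")) {
  scenario <- match.arg(scenario)
  count_mode <- match.arg(count_mode)
  if (scenario == "nvp") {
    if (is.null(params)) stop("params is required for the NVP scenario")
    if (is.null(schedule)) schedule <- build_schedule(rates$init, rates$cess, params)
  }
  thr <- if (is.null(params)) 35L else params$age35_threshold
  rr <- if (scenario == "nvp") params$rr_nvp else 0
  mode <- if (is.null(params)) "additive" else params$fsnvp_excess_mode

  ages <- bundle$min_age:bundle$max_age
  years <- bundle$base_year:bundle$end_year
  nA <- length(ages); nY <- length(years)
  genders <- c("male", "female")

  share <- array(0, dim = c(9L, nA, 2L, nY),
                 dimnames = list(state = use_states(),
                                 age = as.character(ages), gender = genders,
                                 year = as.character(years)))
  count <- share
  share[, , , 1L] <- init_no_nvp(bundle, thr)
  if (count_mode == "evolve") {
    for (g in genders) {
      count[, , g, 1L] <- sweep(share[, , g, 1L], 2L,
                                bundle$population[, g, 1L], `*`)
    }
  }

  # per-gender state-mortality array [9, age, year]
  MU <- vector("list", 2L); names(MU) <- genders
  for (g in genders) {
    ex <- state_excess_list(rates$mu$never[, g, ], rates$mu$current[, g, ],
                            rates$mu$former[, g, ], rr, mode)
    MU[[g]] <- array(0, dim = c(9L, nA, nY))
    for (s in seq_len(9L)) {
      MU[[g]][s, , ] <- rates$mu$never[, g, ] + ex[[s]]
    }
  }

  zero <- rep(0, nA - 1L)
  lowrisk <- (ages[-nA] + 1L) <= (thr - 1L)
  base_entry <- share[, 1L, , 1L]  # state x gender at min_age, base year

  for (ti in seq_len(nY - 1L)) {
    y <- as.character(years[ti])
    for (g in genders) {
      X <- matrix(share[, -nA, g, ti], nrow = 9L)
      MUg <- matrix(MU[[g]][, -nA, ti], nrow = 9L)
      if (scenario == "nvp") {
        r <- list(smk_init = schedule$smk_init[-nA, g, y],
                  nvp_init = schedule$nvp_init[-nA, g, y],
                  smk_cess = schedule$smk_cess[-nA, g, y],
                  nvp_cess = schedule$nvp_cess[-nA, g, y],
                  sw = schedule$switch[-nA, g, y])
      } else {
        r <- list(smk_init = rates$init[-nA, g, y], nvp_init = zero,
                  smk_cess = rates$cess[-nA, g, y], nvp_cess = zero,
                  sw = zero)
      }
      nxt <- .step_core(X, MUg, r$smk_init, r$nvp_init,
                        r$smk_cess, r$nvp_cess, r$sw, lowrisk)
      tot <- colSums(nxt)
      share[, -1L, g, ti + 1L] <- sweep(nxt, 2L, tot, `/`)
      ent <- entrant_shares(base_entry[, g],
                            if (scenario == "nvp") params else NULL,
                            years[ti + 1L])
      share[, 1L, g, ti + 1L] <- ent
      if (count_mode == "evolve") {
        C <- matrix(count[, -nA, g, ti], nrow = 9L)
        cn <- .step_core(C, MUg, r$smk_init, r$nvp_init,
                         r$smk_cess, r$nvp_cess, r$sw, lowrisk)
        count[, -1L, g, ti + 1L] <- cn
        count[, 1L, g, ti + 1L] <- ent * bundle$population[1L, g, ti + 1L]
      }
    }
  }
  if (count_mode == "projection") {
    for (g in genders) {
      for (ti in seq_len(nY)) {
        count[, , g, ti] <- sweep(share[, , g, ti], 2L,
                                  bundle$population[, g, ti], `*`)
      }
    }
  }
  structure(list(share = share, count = count,
                 population = bundle$population,
                 scenario = scenario, params = params,
                 count_mode = count_mode),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  d <- dim(x$share)
  cat("<state_trajectory> ", x$scenario, ": ", d[2], " ages x ", d[4],
      " years\n", sep = "")
  invisible(x)
}

#' Export a trajectory as a long data frame
#'
#' @param traj a `state_trajectory` from [run_scenario()].
#' @return data frame with columns `year`, `age`, `gender`, `state`, `share`,
#'   `count`.
#' @export
trajectory_to_df <- function(traj) {
  dn <- dimnames(traj$share)
  df <- expand.grid(state = dn$state, age = as.integer(dn$age),
                    gender = dn$gender, year = as.integer(dn$year),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$share <- as.vector(traj$share)
  df$count <- as.vector(traj$count)
  df[, c("year", "age", "gender", "state", "share", "count")]
}

#' Evolve a single closed cohort
#'
#' Follows one cohort (one starting age and gender, no new entrants) for a
#' number of years under either scenario's dynamics.  Used by the tests to
#' compare the deterministic engine with the individual-level
#' microsimulation oracle.
#'
#' @param shares0 named initial state shares.
#' @param age0 starting age.
#' @param gender `"male"` or `"female"`.
#' @param n_steps number of annual steps (cohort must stay within the rate
#'   tables' age range).
#' @param rates a `country_rates` object.
#' @param params optional [scenario_params()].
#' @param scenario `"no_nvp"` or `"nvp"`.
#' @param start_year first calendar year (defaults to the rate tables'
#'   first year).
#' @return 9 x (n_steps + 1) matrix of shares, one column per year.
#' @export
evolve_cohort <- function(shares0, age0, gender, n_steps, rates,
                          params = NULL, scenario = c("no_nvp", "nvp"),
                          start_year = NULL) {
  scenario <- match.arg(scenario)
  path <- cohort_rate_path(rates, params, scenario, age0, gender,
                           n_steps, start_year)
  x <- as_state_vector(shares0)
  out <- matrix(NA_real_, nrow = 9L, ncol = n_steps + 1L,
                dimnames = list(state = use_states(), NULL))
  out[, 1L] <- x
  for (s in seq_len(n_steps)) {
    p <- path[[s]]
    nxt <- .step_core(matrix(x, ncol = 1), matrix(p$mu, ncol = 1),
                      p$smk_init, p$nvp_init, p$smk_cess, p$nvp_cess,
                      p$switch, p$lowrisk)
    x <- drop(nxt) / sum(nxt)
    out[, s + 1L] <- x
  }
  out
}

# Per-step scalar rates and 9-state mortality for one cohort; shared between
# the deterministic engine wrapper and the microsimulation oracle so both
# consume identical inputs.
cohort_rate_path <- function(rates, params, scenario, age0, gender, n_steps,
                             start_year = NULL) {
  years <- agy_years(rates$init)
  ages <- agy_ages(rates$init)
  if (is.null(start_year)) start_year <- years[1L]
  thr <- if (is.null(params)) 35L else params$age35_threshold
  rr <- if (scenario == "nvp") params$rr_nvp else 0
  mode <- if (is.null(params)) "additive" else params$fsnvp_excess_mode
  sched <- if (scenario == "nvp") {
    build_schedule(rates$init, rates$cess, params)
  } else NULL
  lapply(seq_len(n_steps), function(s) {
    a <- age0 + s - 1L
    y <- start_year + s - 1L
    if (!(a %in% ages) || !(y %in% years)) {
      stop("coverage error: cohort leaves the rate tables' index")
    }
    ai <- as.character(a); yi <- as.character(y)
    mu <- state_mu(rates$mu$never[ai, gender, yi],
                   rates$mu$current[ai, gender, yi],
                   rates$mu$former[ai, gender, yi], rr, mode)
    if (scenario == "nvp") {
      list(smk_init = sched$smk_init[ai, gender, yi],
           nvp_init = sched$nvp_init[ai, gender, yi],
           smk_cess = sched$smk_cess[ai, gender, yi],
           nvp_cess = sched$nvp_cess[ai, gender, yi],
           switch = sched$switch[ai, gender, yi],
           mu = mu, lowrisk = (a + 1L) <= (thr - 1L))
    } else {
      list(smk_init = rates$init[ai, gender, yi], nvp_init = 0,
           smk_cess = rates$cess[ai, gender, yi], nvp_cess = 0,
           switch = 0, mu = mu, lowrisk = (a + 1L) <= (thr - 1L))
    }
  })
}
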