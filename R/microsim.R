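#' Individual-level microsimulation oracle
#'
#' Simulates a closed cohort of individual agents through the same annual
#' survival-then-transition rules as the deterministic engine, using
#' pseudo-random draws, and returns state-share estimates with standard
#' errors.  Serves as an independent stochastic cross-check of
#' [evolve_cohort()] on short horizons: with enough agents every cohort state
#' share should lie within a few standard errors of the microsimulation
#' estimate.
#'
#' @param rates a `country_rates` object.
#' @param params optional [scenario_params()] (required for
#'   `scenario = "nvp"`).
#' @param scenario `"no_nvp"` or `"nvp"`.
#' @param shares0 named initial state shares (summing to 1).
#' @param age0 starting age of the cohort.
#' @param gender `"male"` or `"female"`.
#' @param n_steps number of annual steps; capped at 15 (the oracle is meant
#'   for short-horizon checks).
#' @param n_agents number of simulated individuals; at least 1000 (fewer is
#'   refused as too noisy to act as an oracle).
#' @param seed integer seed for the agent draws (global RNG state is
#'   restored on exit).
#' @return list with `share` (9 x (n_steps + 1) matrix of state shares among
#'   survivors), `se` (matching binomial standard errors), `n_alive`
#'   (survivors per year).
#' @export
microsim_oracle <- function(rates, params = NULL,
                            scenario = c("no_nvp", "nvp"),
                            shares0, age0, gender, n_steps,
                            n_agents = 1e5, seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_agents < 1e3) {
    stop("n_agents < 1000 is too noisy to serve as an oracle")
  }
  if (n_steps > 15) stop("oracle horizon capped at 15 years")
  x0 <- as_state_vector(shares0)
  path <- cohort_rate_path(rates, params, scenario, age0, gender, n_steps)

  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  n <- as.integer(n_agents)
  state <- sample.int(9L, n, replace = TRUE, prob = x0)
  share <- matrix(0, nrow = 9L, ncol = n_steps + 1L,
                  dimnames = list(state = use_states(), NULL))
  n_alive <- integer(n_steps + 1L)
  share[, 1L] <- tabulate(state, 9L) / n
  n_alive[1L] <- n

  for (s in seq_len(n_steps)) {
    p <- path[[s]]
    mu <- p$mu
    dead <- stats::runif(length(state)) < mu[state]
    state <- state[!dead]
    u <- stats::runif(length(state))
    new <- state
    i1 <- state == 1L
    new[i1 & u < p$smk_init] <- 2L
    new[i1 & u >= p$smk_init & u < p$smk_init + p$nvp_init] <- 5L
    i2 <- state == 2L
    quit_to <- if (p$lowrisk) 4L else 3L
    switch_to <- if (p$lowrisk) 6L else 7L
    new[i2 & u < p$smk_cess] <- quit_to
    new[i2 & u >= p$smk_cess & u < p$smk_cess + p$switch] <- switch_to
    iv <- state %in% c(5L, 6L)
    new[iv & u < p$nvp_cess] <- 8L
    i7 <- state == 7L
    new[i7 & u < p$nvp_cess] <- 9L
    state <- new
    n_alive[s + 1L] <- length(state)
    share[, s + 1L] <- tabulate(state, 9L) / length(state)
  }
  se <- sqrt(share * (1 - share) /
               matrix(n_alive, nrow = 9L, ncol = n_steps + 1L, byrow = TRUE))
  list(share = share, se = se, n_alive = n_alive)
}
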