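# Three-unit stochastic competition network integrated with Euler-Maruyama.
#
# Each unit k in {A, AB, B} carries a firing rate r_k, an NMDA-like
# recurrent excitation e_k, a linear spike-frequency adaptation a_k and an
# additive Ornstein-Uhlenbeck noise term chi_k:
#
#   tau_r dr_k = -r_k + F(beta_e e_k - beta_i (r_A + r_AB + r_B)
#                         - g a_k + I_k + chi_k)
#   tau_e de_k = -e_k + r_k
#   tau_a da_k = -a_k + r_k
#
# with F a logistic sigmoid. Global inhibition pools all three rates
# (self-inclusive). The OU term is updated with its exact discretization.

#' Competition-stage parameters
#'
#' @param tau_r cortical rate timescale, ms (default 10).
#' @param tau_e recurrent (NMDA-like) excitation timescale, ms (default 70).
#' @param tau_a slow adaptation timescale, ms (default 1400).
#' @param beta_e recurrent excitation strength (default 0.65).
#' @param beta_i global inhibition strength (default 0.3); must be below
#'   `beta_e` (net local excitation).
#' @param g adaptation strength (default 0.045).
#' @param F_threshold,F_slope threshold and slope of the sigmoidal firing
#'   rate function.
#' @param noise_sigma stationary standard deviation of the OU noise.
#' @param noise_tau OU correlation time, ms.
#' @param dt Euler-Maruyama step, ms (default `0.5 * tau_r`); must not
#'   exceed `tau_r`.
#' @return a `network_params` list.
#' @export
network_params <- function(tau_r = 10, tau_e = 70, tau_a = 1400,
                           beta_e = 0.65, beta_i = 0.3, g = 0.045,
                           F_threshold = 0.32, F_slope = 0.05,
                           noise_sigma = 0.07, noise_tau = 30,
                           dt = 0.5 * tau_r) {
  if (any(c(tau_r, tau_e, tau_a, noise_tau) <= 0))
    stop("all timescales must be > 0", call. = FALSE)
  if (beta_e <= beta_i)
    stop("beta_e must exceed beta_i (net local excitation)", call. = FALSE)
  if (dt <= 0 || dt > tau_r)
    stop("dt must lie in (0, tau_r]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(tau_r = tau_r, tau_e = tau_e, tau_a = tau_a,
                 beta_e = beta_e, beta_i = beta_i, g = g,
                 F_threshold = F_threshold, F_slope = F_slope,
                 noise_sigma = noise_sigma, noise_tau = noise_tau, dt = dt),
            class = "network_params")
}

#' Sigmoidal firing rate function
#'
#' Logistic sigmoid `1 / (1 + exp(-(x - F_threshold) / F_slope))`; strictly
#' increasing, 0.5 at threshold, saturating at 0 and 1.
#'
#' @param x total drive.
#' @param params a [network_params()] set.
#' @return rate in (0, 1).
#' @export
firing_rate_function <- function(x, params) {
  stats::plogis((x - params$F_threshold) / params$F_slope)
}

#' Frozen-noise and initial-condition bank
#'
#' Pre-generates, for `n_trials` trials, randomized initial conditions and
#' per-unit Ornstein-Uhlenbeck noise paths. Trial `i` is drawn under seed
#' `master_seed + i` (a documented counter scheme), so the path for a given
#' `(master_seed, trial)` pair is identical regardless of bank size or the
#' order in which conditions are simulated, and a longer bank shares its
#' prefix with a shorter one. Reusing one bank across stimulus conditions
#' implements frozen noise: condition differences are then attributable
#' solely to the inputs.
#'
#' Initial conditions draw `r`, `e`, `a` uniformly from [0, 0.1] and the
#' noise from its stationary distribution. OU paths use the exact
#' discretization `chi' = chi * exp(-dt/tau) + sigma *
#' sqrt(1 - exp(-2 dt/tau)) * Z`.
#'
#' @param n_trials number of trials.
#' @param n_steps number of grid points per path.
#' @param params a [network_params()] set (supplies `noise_sigma`,
#'   `noise_tau`, `dt`).
#' @param master_seed integer master seed.
#' @return a `noise_bank`: `chi` array `[n_steps, n_trials, 3]` and `init`
#'   matrix `[n_trials, 9]` (r_A, r_AB, r_B, e_*, a_*).
#' @export
noise_bank <- function(n_trials, n_steps, params, master_seed = 1) {
  stopifnot(n_trials >= 1, n_steps >= 1)
  k <- exp(-params$dt / params$noise_tau)
  s_step <- params$noise_sigma * sqrt(1 - k^2)
  chi <- array(0, dim = c(n_steps, n_trials, 3))
  init <- matrix(0, n_trials, 9)
  colnames(init) <- c("r_A", "r_AB", "r_B", "e_A", "e_AB", "e_B",
                      "a_A", "a_AB", "a_B")
  for (i in seq_len(n_trials)) {
    draws <- with_local_seed(master_seed + i, {
      u <- stats::runif(9, 0, 0.1)
      z0 <- stats::rnorm(3)
      z <- if (n_steps > 1) stats::rnorm((n_steps - 1) * 3) else numeric(0)
      list(u = u, z0 = z0, z = z)
    })
    init[i, ] <- draws$u
    path <- matrix(0, n_steps, 3)
    path[1, ] <- params$noise_sigma * draws$z0
    if (n_steps > 1) {
      zm <- matrix(draws$z, n_steps - 1, 3, byrow = TRUE)
      for (s in 2:n_steps) path[s, ] <- path[s - 1, ] * k + s_step * zm[s - 1, ]
    }
    chi[, i, ] <- path
  }
  structure(list(chi = chi, init = init, n_trials = n_trials,
                 n_steps = n_steps, master_seed = master_seed,
                 noise_sigma = params$noise_sigma,
                 noise_tau = params$noise_tau, dt = params$dt),
            class = "noise_bank")
}

#' One Euler-Maruyama step of the competition network
#'
#' Advances all twelve state variables by `dt`: the rates through the
#' sigmoid of their total drive (recurrent excitation minus self-inclusive
#' global inhibition minus adaptation plus input plus noise), the slow
#' variables toward their rates, and the noise by its exact OU update.
#'
#' @param state named list with numeric length-3 vectors `r`, `e`, `a`,
#'   `chi` (order A, AB, B).
#' @param inputs length-3 input drive at the current time.
#' @param params a [network_params()] set.
#' @param noise_increment length-3 standard normal increments for the OU
#'   update (zero vector for deterministic stepping).
#' @return the updated state list.
#' @export
step_network <- function(state, inputs, params, noise_increment = c(0, 0, 0)) {
  drive <- params$beta_e * state$e - params$beta_i * sum(state$r) -
    params$g * state$a + inputs + state$chi
  r_new <- state$r + params$dt / params$tau_r *
    (-state$r + firing_rate_function(drive, params))
  e_new <- state$e + params$dt / params$tau_e * (-state$e + state$r)
  a_new <- state$a + params$dt / params$tau_a * (-state$a + state$r)
  k <- exp(-params$dt / params$noise_tau)
  chi_new <- state$chi * k +
    params$noise_sigma * sqrt(1 - k^2) * noise_increment
  bad <- !is.finite(c(r_new, e_new, a_new, chi_new))
  if (any(bad)) {
    nm <- rep(c("r", "e", "a", "chi"), each = 3)[bad][1]
    stop(sprintf("non-finite value in state variable '%s'", nm), call. = FALSE)
  }
  list(r = r_new, e = e_new, a = a_new, chi = chi_new)
}

# Core vectorised integrator: all trials advance together. chi paths are
# pre-generated (noise_bank), so the loop is deterministic.
integrate_ensemble <- function(input, params, bank, keep_slow = FALSE) {
  stopifnot(inherits(input, "a1_input_trace"))
  if (abs(input$dt - params$dt) > 1e-9)
    stop(sprintf("input grid step (%g ms) must equal params$dt (%g ms)",
                 input$dt, params$dt), call. = FALSE)
  n_t <- length(input$t)
  if (bank$n_steps < n_t)
    stop("noise bank shorter than the input trace", call. = FALSE)
  n <- bank$n_trials
  R <- bank$init[, 1:3, drop = FALSE]
  E <- bank$init[, 4:6, drop = FALSE]
  A <- bank$init[, 7:9, drop = FALSE]
  r_arr <- array(NA_real_, dim = c(n_t, n, 3))
  r_arr[1, , ] <- R
  if (keep_slow) {
    e_arr <- array(NA_real_, dim = c(n_t, n, 3)); e_arr[1, , ] <- E
    a_arr <- array(NA_real_, dim = c(n_t, n, 3)); a_arr[1, , ] <- A
  }
  dt <- params$dt
  inv_slope <- 1 / params$F_slope
  for (s in 2:n_t) {
    chi <- bank$chi[s - 1, , , drop = FALSE]
    dim(chi) <- c(n, 3)
    drive <- params$beta_e * E - params$beta_i * rowSums(R) - params$g * A +
      rep(input$I[s - 1, ], each = n) + chi
    Fx <- stats::plogis((drive - params$F_threshold) * inv_slope)
    R <- R + dt / params$tau_r * (-R + Fx)
    E <- E + dt / params$tau_e * (-E + R)
    A <- A + dt / params$tau_a * (-A + R)
    if (anyNA(R) || any(!is.finite(R)))
      stop(sprintf("non-finite firing rate at step %d", s), call. = FALSE)
    r_arr[s, , ] <- R
    if (keep_slow) { e_arr[s, , ] <- E; a_arr[s, , ] <- A }
  }
  out <- list(t = input$t, r = r_arr, n_trials = n,
              master_seed = bank$master_seed, params = params,
              input = input)
  if (keep_slow) { out$e <- e_arr; out$a <- a_arr }
  out
}

#' Simulate a single trial
#'
#' Runs one trial of the competition network on an input trace, with its
#' own noise path and randomized initial condition derived from
#' `trial_seed`. Deterministic: the same (input, params, seed) always
#' yields the identical trajectory.
#'
#' @param input an `a1_input_trace` with grid step equal to `params$dt`.
#' @param params a [network_params()] set.
#' @param trial_seed integer seed for this trial.
#' @return a `network_trajectory`: time grid `t` (ms) and matrices `r`,
#'   `e`, `a`, `chi` (columns A, AB, B).
#' @export
simulate_trial <- function(input, params, trial_seed = 1) {
  bank <- noise_bank(1, length(input$t), params, master_seed = trial_seed - 1L)
  sim <- integrate_ensemble(input, params, bank, keep_slow = TRUE)
  structure(list(t = sim$t,
                 r = matrix(sim$r[, 1, ], ncol = 3,
                            dimnames = list(NULL, c("A", "AB", "B"))),
                 e = matrix(sim$e[, 1, ], ncol = 3,
                            dimnames = list(NULL, c("A", "AB", "B"))),
                 a = matrix(sim$a[, 1, ], ncol = 3,
                            dimnames = list(NULL, c("A", "AB", "B"))),
                 chi = matrix(bank$chi[seq_along(sim$t), 1, ], ncol = 3,
                              dimnames = list(NULL, c("A", "AB", "B"))),
                 seed = trial_seed, params = params, input = input),
            class = "network_trajectory")
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat(sprintf("<network_trajectory> %d steps of %g ms (seed %d)\n",
              length(x$t), x$params$dt, x$seed))
  invisible(x)
}

#' Run a frozen-noise ensemble
#'
#' Simulates `n_trials` trials of the network on one input trace, each with
#' its own noise path and initial condition from a [noise_bank()]. Passing
#' the same `master_seed` (or the same bank) for different stimulus
#' conditions freezes the noise across conditions.
#'
#' @param input an `a1_input_trace`.
#' @param params a [network_params()] set.
#' @param n_trials ensemble size (default 500); ignored when `bank` is
#'   given.
#' @param master_seed integer master seed; ignored when `bank` is given.
#' @param bank optional pre-built [noise_bank()] (must cover the input
#'   length).
#' @param discard_ms initial interval to simulate but drop from the
#'   returned trajectories (time is re-zeroed). Used for static-input
#'   ensembles, which represent the post-build-up alternation regime: a
#'   burn-in equilibrates the ensemble before observation starts.
#' @return a `stream_ensemble`: `t`, rate array `r` of dimension
#'   `[time, trial, unit]`, and metadata.
#' @export
run_ensemble <- function(input, params, n_trials = 500, master_seed = 1,
                         bank = NULL, discard_ms = 0) {
  if (is.null(bank))
    bank <- noise_bank(n_trials, length(input$t), params, master_seed)
  sim <- integrate_ensemble(input, params, bank)
  if (discard_ms > 0) {
    keep <- sim$t >= discard_ms - 1e-9
    sim$t <- sim$t[keep] - discard_ms
    sim$r <- sim$r[keep, , , drop = FALSE]
  }
  structure(sim, class = "stream_ensemble")
}

#' @export
print.stream_ensemble <- function(x, ...) {
  cat(sprintf("<stream_ensemble> %d trials x %d steps (master seed %d)\n",
              x$n_trials, length(x$t), x$master_seed))
  invisible(x)
}

#' Export a trajectory to a columnar text file
#'
#' @param traj a `network_trajectory`.
#' @param path output path (tab-separated: t, r_*, e_*, a_*).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$t,
                   r_A = traj$r[, "A"], r_AB = traj$r[, "AB"], r_B = traj$r[, "B"],
                   e_A = traj$e[, "A"], e_AB = traj$e[, "AB"], e_B = traj$e[, "B"],
                   a_A = traj$a[, "A"], a_AB = traj$a[, "AB"], a_B = traj$a[, "B"])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
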