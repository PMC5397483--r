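# Competition network: sigmoid, stepping, determinism, numerics oracles.

test_that("network parameter constraints are enforced", {
  expect_error(network_params(beta_e = 0.3, beta_i = 0.4), "beta_e")
  expect_error(network_params(dt = 20), "dt")
  expect_error(network_params(tau_e = -1), "timescales")
  p <- network_params()
  expect_equal(p$dt, 0.5 * p$tau_r)
})

test_that("the firing rate function is a logistic sigmoid", {
  p <- network_params()
  expect_equal(firing_rate_function(p$F_threshold, p), 0.5)
  expect_lt(firing_rate_function(-1e3, p), 1e-10)
  expect_gt(firing_rate_function(1e3, p), 1 - 1e-10)
  x <- seq(-1, 1, by = 0.01)
  expect_true(all(diff(firing_rate_function(x, p)) > 0))
})

test_that("step_network performs one Euler-Maruyama update and flags non-finite states", {
  p <- network_params(noise_sigma = 0)
  s <- list(r = c(0.2, 0.5, 0.1), e = c(0.2, 0.4, 0.1), a = c(0.1, 0.3, 0),
            chi = c(0, 0, 0))
  s2 <- step_network(s, inputs = c(0.1, 0.3, 0.1), p)
  drive <- p$beta_e * s$e - p$beta_i * sum(s$r) - p$g * s$a + c(0.1, 0.3, 0.1)
  expect_equal(s2$r, s$r + p$dt / p$tau_r * (-s$r + firing_rate_function(drive, p)))
  expect_equal(s2$e, s$e + p$dt / p$tau_e * (-s$e + s$r))
  expect_equal(s2$a, s$a + p$dt / p$tau_a * (-s$a + s$r))
  s$r[1] <- Inf
  expect_error(step_network(s, c(0, 0, 0), p), "non-finite")
})

test_that("quiescent fixed point matches a scalar fixed-point solve", {
  # zero input, zero noise: all units relax to r* = F(beta_e r* - 3 beta_i r*)
  p <- network_params(noise_sigma = 0)
  inp <- compute_input_trace(make_triplet_sequence(2, 7, 420), a1_params(), p$dt)
  inp$I[] <- 0
  bank <- noise_bank(1, length(inp$t), p, 1)
  bank$init[] <- 0
  traj <- run_ensemble(inp, p, bank = bank)
  # independent oracle: scalar fixed-point iteration
  r_star <- 0
  for (i in 1:200) r_star <- plogis(((p$beta_e - 3 * p$beta_i) * r_star - p$F_threshold) / p$F_slope)
  expect_lt(max(abs(traj$r[length(inp$t), 1, ] - r_star)), 1e-4)
})

test_that("adaptation relaxes exponentially toward a clamped rate", {
  # drive the unit hard so r ~ 1, then a(t) tracks 1 - exp(-t/tau_a)
  p <- network_params(noise_sigma = 0)
  tl <- make_triplet_sequence(10, 7, 420)
  inp <- compute_input_trace(tl, a1_params(), p$dt)
  inp$I[] <- 10  # saturating drive
  tr <- simulate_trial(inp, p, trial_seed = 1)
  i_tau <- which.min(abs(tr$t - p$tau_a))
  a0 <- unname(tr$a[1, 1])
  expect_equal(unname(tr$a[i_tau, 1]), 1 + (a0 - 1) * exp(-1), tolerance = 0.02)
})

test_that("symmetric inputs with no noise give identical A and B trajectories", {
  p <- network_params(noise_sigma = 0)
  a1 <- a1_params(a_rate_masking = 1)
  # symmetric artificial input: same pulse train to A and B
  inp <- compute_input_trace(make_triplet_sequence(6, 7, 420), a1, p$dt)
  inp$I[, "A"] <- inp$I[, "B"]
  bank <- noise_bank(1, length(inp$t), p, 1)
  bank$init[] <- 0.05
  ens <- run_ensemble(inp, p, bank = bank)
  expect_identical(ens$r[, 1, 1], ens$r[, 1, 3])
})

test_that("trials are deterministic given a seed and rates stay in (0,1)", {
  p <- network_params()
  inp <- compute_input_trace(make_triplet_sequence(6, 7, 420), a1_params(), p$dt)
  t1 <- simulate_trial(inp, p, trial_seed = 7)
  t2 <- simulate_trial(inp, p, trial_seed = 7)
  expect_identical(t1$r, t2$r)
  expect_identical(t1$chi, t2$chi)
  t3 <- simulate_trial(inp, p, trial_seed = 8)
  expect_false(identical(t1$r, t3$r))
  expect_true(all(t1$r > 0 & t1$r < 1))
})

test_that("grid mismatch between input and params is rejected", {
  p <- network_params()
  inp <- compute_input_trace(make_triplet_sequence(2, 7, 420), a1_params(), dt = 10)
  expect_error(simulate_trial(inp, p, 1), "grid|dt")
})

test_that("noise-off Euler matches an independent adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  p <- network_params(noise_sigma = 0, dt = 0.015625)  # fine step: O(dt) error < 1e-3
  a1 <- a1_params()
  inp <- compute_input_trace(make_triplet_sequence(1, 7, 420), a1, p$dt)
  bank <- noise_bank(1, length(inp$t), p, 1)
  init <- bank$init[1, ]
  ens <- run_ensemble(inp, p, bank = bank)
  # independent oracle: deSolve::lsoda run piecewise between the input's
  # 100 ms discontinuities; within a segment the (smoothly adapting) input
  # is interpolated from the trace
  y <- init
  sol_r <- matrix(NA_real_, length(inp$t), 3)
  sol_r[1, ] <- y[1:3]
  for (seg in seq_len(round(max(inp$t) / 100))) {
    rows <- which(inp$t >= (seg - 1) * 100 - 1e-9 & inp$t <= seg * 100 + 1e-9)
    i_fun <- lapply(1:3, function(k)
      approxfun(inp$t[rows], inp$I[rows, k], rule = 2))
    rhs <- function(t, y, parms) {
      r <- y[1:3]; e <- y[4:6]; a <- y[7:9]
      I <- c(i_fun[[1]](t), i_fun[[2]](t), i_fun[[3]](t))
      drive <- p$beta_e * e - p$beta_i * sum(r) - p$g * a + I
      list(c((-r + plogis((drive - p$F_threshold) / p$F_slope)) / p$tau_r,
             (-e + r) / p$tau_e, (-a + r) / p$tau_a))
    }
    sol <- deSolve::lsoda(y, inp$t[rows], rhs, NULL, rtol = 1e-10, atol = 1e-10)
    sol_r[rows, ] <- sol[, 2:4]
    y <- sol[nrow(sol), -1]
  }
  expect_lt(max(abs(sol_r - ens$r[, 1, ])), 1e-3)
})

test_that("Euler refinement converges with decreasing step", {
  # deterministic comparison over the pre-switch transient; the error
  # shrinks roughly linearly with dt (first-order scheme)
  a1 <- a1_params()
  tl <- make_triplet_sequence(2, 7, 420)
  err <- vapply(c(5, 1), function(dt) {
    p <- network_params(noise_sigma = 0, dt = dt)
    p_ref <- network_params(noise_sigma = 0, dt = 0.125)
    inp <- compute_input_trace(tl, a1, dt)
    inp_ref <- compute_input_trace(tl, a1, 0.125)
    b <- noise_bank(1, length(inp$t), p, 1)
    b_ref <- noise_bank(1, length(inp_ref$t), p_ref, 1)
    e1 <- run_ensemble(inp, p, bank = b)
    e2 <- run_ensemble(inp_ref, p_ref, bank = b_ref)
    common <- match(inp$t, inp_ref$t)
    max(abs(e1$r[, 1, ] - e2$r[common, 1, ]))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.02)
})

test_that("OU noise bank matches its stationary statistics", {
  p <- network_params()
  n_steps <- 2001
  bank <- noise_bank(500, n_steps, p, master_seed = 3)
  x <- bank$chi[, , 1]
  expect_equal(mean(x), 0, tolerance = 0.005)
  expect_equal(sd(as.vector(x)), p$noise_sigma, tolerance = 0.05 * p$noise_sigma)
  # autocorrelation time: fit log-acf over the first lags
  lag <- round(p$noise_tau / p$dt)
  ac <- mean(vapply(1:200, function(i)
    cor(x[-(1:lag), i], x[1:(n_steps - lag), i]), numeric(1)))
  expect_equal(ac, exp(-1), tolerance = 0.1)
})

test_that("the noise bank is reproducible and prefix-stable", {
  p <- network_params()
  b1 <- noise_bank(5, 100, p, master_seed = 9)
  b2 <- noise_bank(5, 100, p, master_seed = 9)
  expect_identical(b1$chi, b2$chi)
  expect_identical(b1$init, b2$init)
  # longer bank shares its prefix; smaller bank is a sub-bank
  b3 <- noise_bank(5, 200, p, master_seed = 9)
  expect_identical(b3$chi[1:100, , ], b1$chi)
  b4 <- noise_bank(3, 100, p, master_seed = 9)
  expect_identical(b4$chi, b1$chi[, 1:3, ])
})

test_that("frozen noise makes paired conditions identical before the perturbation", {
  p <- network_params()
  a1 <- a1_params()
  ctl <- make_triplet_sequence(10, 7, 420)
  tst <- apply_pause(ctl, 600, 7)
  e_ctl <- run_ensemble(compute_input_trace(ctl, a1, p$dt), p, 40, master_seed = 5)
  e_tst <- run_ensemble(compute_input_trace(tst, a1, p$dt), p, 40, master_seed = 5)
  expect_identical(e_ctl$r[e_ctl$t < 2800, , ], e_tst$r[e_tst$t < 2800, , ])
  expect_false(identical(e_ctl$r[e_ctl$t >= 2800, , ],
                         e_tst$r[e_tst$t >= 3400 & e_tst$t <= 4600, , ]))
})

test_that("an ensemble of one trial reduces to simulate_trial", {
  p <- network_params()
  inp <- compute_input_trace(make_triplet_sequence(4, 7, 420), a1_params(), p$dt)
  ens <- run_ensemble(inp, p, n_trials = 1, master_seed = 41)
  tr <- simulate_trial(inp, p, trial_seed = 42)  # bank seed 41 + trial 1
  expect_equal(ens$r[, 1, ], unname(tr$r))
})

test_that("winner-take-all: dominance suppresses the losing group", {
  p <- network_params()
  inp <- compute_input_trace(make_triplet_sequence(10, 7, 420), a1_params(), p$dt)
  tr <- simulate_trial(inp, p, trial_seed = 3)
  late <- tr$t > 2000
  dom_ab <- tr$r[late, "AB"] > 0.6
  if (any(dom_ab)) {
    expect_lt(max(pmax(tr$r[late, "A"], tr$r[late, "B"])[dom_ab]), 0.5)
  }
  dom_a <- tr$r[late, "A"] > 0.6
  if (any(dom_a)) expect_lt(max(tr$r[late, "AB"][dom_a]), 0.5)
})

test_that("trajectories export to columnar text", {
  p <- network_params()
  inp <- compute_input_trace(make_triplet_sequence(2, 7, 420), a1_params(), p$dt)
  tr <- simulate_trial(inp, p, 1)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  df <- read.delim(f)
  expect_equal(ncol(df), 10)
  expect_equal(nrow(df), length(tr$t))
  unlink(f)
})
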