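test_that("transfer functions evaluate correctly and softplus limits to relu", {
  relu <- transfer_function("rectified_linear", gain = 1, threshold = 1.19)
  expect_equal(evaluate_tf(0, relu), 0)
  expect_equal(evaluate_tf(8.51, relu), 7.32)
  sp <- transfer_function("softplus", gain = 1, threshold = 0, smoothing = 1e-6)
  expect_equal(evaluate_tf(5, sp), 5, tolerance = 1e-4)
  # pointwise convergence to relu as b -> 0 on a grid spanning the threshold
  relu0 <- transfer_function("rectified_linear", gain = 1.7, threshold = 2)
  sp0 <- transfer_function("softplus", gain = 1.7, threshold = 2, smoothing = 1e-6)
  x <- seq(-5, 10, by = 0.25)
  expect_lt(max(abs(evaluate_tf(x, sp0) - evaluate_tf(x, relu0))), 1e-4)
  # overflow guard: huge inputs stay finite and follow the linear asymptote
  big <- transfer_function("softplus", gain = 1, threshold = 0, smoothing = 1)
  expect_equal(evaluate_tf(1e6, big), 1e6)
  expect_error(evaluate_tf(NaN, relu), "finite")
  expect_error(transfer_function(gain = -1), "positive")
  expect_error(transfer_function("softplus", smoothing = 0), "smoothing")
})

test_that("blocker transforms scale the glutamatergic and GABAergic terms", {
  p <- eq_params()
  # full-efficacy blockers are the identity in every phase
  for (ph in isn_phases)
    expect_equal(apply_blockers(p, ph, blocker_efficacy(1, 1)), p)
  # E blockers scale W_EE, I_EX, W_IE, I_IX (external inputs included)
  b <- apply_blockers(p, "e_blocked", blocker_efficacy(0.5, 0.9))
  expect_equal(b$W_EE, 1.28)
  expect_equal(b$I_EX, 4.255)
  expect_equal(b$W_IE, 4.27)
  expect_equal(b$I_IX, 17.08)
  expect_equal(b$W_EI, p$W_EI)
  expect_equal(b$W_II, p$W_II)
  expect_equal(b$lambda, p$lambda) # opsin efficacy never scaled
  # with both phases, inhibitory weights are additionally scaled
  bb <- apply_blockers(p, "ei_blocked", blocker_efficacy(0.5, 0.25))
  expect_equal(bb$W_EI, 0.25 * p$W_EI)
  expect_equal(bb$W_II, 0.25 * p$W_II)
  expect_equal(bb$W_EE, 1.28)
  # complete blockade: only direct opsin drive remains, r_I = phi_I(lambda L)
  z <- apply_blockers(p, "ei_blocked", blocker_efficacy(0, 0))
  expect_equal(z$W_EE + z$W_EI + z$W_IE + z$W_II + z$I_EX + z$I_IX, 0)
  L <- c(0, 1, 2, 4)
  fp <- fixed_point(z, L)
  expect_equal(fp$r_E, rep(0, 4))
  expect_equal(fp$r_I, evaluate_tf(p$lambda * L, p$tf_I))
})

test_that("fixed point solves both branches of the equilibrium", {
  p <- eq_params()
  fp0 <- fixed_point(p, 0)
  expect_equal(fp0$r_E, 5.768, tolerance = 1e-3)
  expect_equal(fp0$r_I, 9.219, tolerance = 1e-3)
  expect_equal(fp0$branch, "interior")
  fp3 <- fixed_point(p, 3)
  expect_equal(fp3$r_E, 0)
  expect_equal(fp3$r_I, (34.16 + 6.3 * 3 - 8.65) / 8.11, tolerance = 1e-9)
  expect_equal(fp3$branch, "boundary")
  # lambda = 0: intensity has no effect
  p0 <- two_pop_params(p$W_EE, p$W_EI, p$W_IE, p$W_II, p$I_EX, p$I_IX,
                       lambda = 0, tf_E = p$tf_E, tf_I = p$tf_I)
  fp <- fixed_point(p0, c(0, 1, 5, 50))
  expect_equal(diff(range(fp$r_E)), 0)
  expect_equal(diff(range(fp$r_I)), 0)
  # singular determinant is an error
  ps <- two_pop_params(2, 1, 2, 1, 5, 5, 1)
  expect_error(fixed_point(ps, 0), "singular")
})

test_that("fixed point equals the long-time limit of the dynamics", {
  set.seed(42)
  for (i in 1:5) {
    p <- random_stable_params()
    taus <- time_constants(runif(1, 5, 15), runif(1, 5, 25))
    ev <- eigenvalues_closed_form(p, taus)
    if (!ev$stable || ev$max_real > -0.01) next # keep decay fast enough to test
    for (L in c(0, 0.7)) {
      fp <- fixed_point(p, L)
      tr <- simulate_dynamics(p, taus, L, T_ms = 60 * max(taus$tau_E, taus$tau_I),
                              dt = 0.1, init = c(r_E = fp$r_E + 1, r_I = fp$r_I + 1))
      n <- nrow(tr)
      expect_equal(tr$r_E[n], fp$r_E, tolerance = 1e-4)
      expect_equal(tr$r_I[n], fp$r_I, tolerance = 1e-4)
    }
  }
})

test_that("dynamics stay at equilibrium, converge under dt halving, and guard dt", {
  p <- eq_params(); taus <- eq_taus()
  fp <- fixed_point(p, 1)
  tr <- simulate_dynamics(p, taus, 1, T_ms = 100,
                          init = c(r_E = fp$r_E, r_I = fp$r_I))
  expect_lt(max(abs(tr$r_E - fp$r_E)), 1e-9)
  expect_lt(max(abs(tr$r_I - fp$r_I)), 1e-9)
  t1 <- simulate_dynamics(p, taus, laser_step(1, 0), T_ms = 300, dt = 0.1)
  t2 <- simulate_dynamics(p, taus, laser_step(1, 0), T_ms = 300, dt = 0.05)
  expect_lt(abs(t1$r_E[nrow(t1)] - t2$r_E[nrow(t2)]), 1e-6)
  expect_lt(abs(t1$r_I[nrow(t1)] - t2$r_I[nrow(t2)]), 1e-6)
  expect_error(simulate_dynamics(p, taus, 0, T_ms = 10, dt = 2), "dt too large")
})

test_that("a step of inhibitory drive in an ISN produces the inhibitory transient", {
  p <- eq_params(); taus <- eq_taus()
  fp0 <- fixed_point(p, 0)
  tr <- simulate_dynamics(p, taus, laser_step(1, t_on = 0), T_ms = 600, dt = 0.05,
                          init = c(r_E = fp0$r_E, r_I = fp0$r_I))
  early <- tr$time_ms > 0 & tr$time_ms <= 10
  expect_gt(max(tr$r_I[early]), fp0$r_I)      # transient rise within ~10 ms
  expect_lt(tr$r_I[nrow(tr)], fp0$r_I)        # paradoxical steady-state suppression
  # excitatory rate falls and never exceeds its baseline; residual ripples
  # from the damped oscillation stay small relative to the overall drop
  expect_lte(max(tr$r_E), fp0$r_E + 1e-9)
  expect_lt(max(diff(tr$r_E)), 0.02 * (fp0$r_E - min(tr$r_E)))
})

test_that("parameters rescale along the invariance family without moving fixed points", {
  p <- eq_params()
  expect_equal(rescale_params(p, 1, 1), p)
  q <- rescale_params(p, 2, 0.5)
  for (L in c(0, 2)) {
    a <- fixed_point(p, L); b <- fixed_point(q, L)
    expect_equal(b$r_E, a$r_E, tolerance = 1e-9)
    expect_equal(b$r_I, a$r_I, tolerance = 1e-9)
  }
  # composition: gamma1 then gamma2 equals gamma1 * gamma2
  r1 <- rescale_params(rescale_params(p, 1.5, 0.8), 2, 1.25)
  r2 <- rescale_params(p, 3, 1)
  expect_equal(r1, r2)
  # leaving the non-negative weight region errors
  low <- two_pop_params(0.5, 1, 2, 1, 5, 10, 1)
  expect_error(rescale_params(low, 3, 1), "negative")
})

test_that("paradoxical-slope law holds on random stable draws", {
  set.seed(7)
  n_checked <- 0
  while (n_checked < 100) {
    p <- random_stable_params()
    D <- model_determinant(p)
    dL <- 1e-5
    fp <- fixed_point(p, c(0, dL))
    if (any(fp$branch != "interior")) next
    slope_fd <- diff(fp$r_I) / dL
    slope_law <- -(p$W_EE - 1) * p$lambda / D
    expect_equal(slope_fd, slope_law, tolerance = 1e-5)
    expect_equal(slope_fd < 0, is_isn(p))
    n_checked <- n_checked + 1
  }
})

test_that("the inhibitory minimum coincides with excitatory silencing", {
  p <- eq_params()
  L <- seq(0, 3, by = 0.001)
  fp <- fixed_point(p, L)
  L_sil <- L[which(fp$r_E <= 0)[1]]        # first silencing intensity
  L_min <- L[which.min(fp$r_I)]            # inhibitory minimum
  expect_equal(L_min, L_sil, tolerance = 2e-3)
  # above the transition the slope is lambda / (W_II + 1) in every phase
  hi_slope <- (fp$r_I[length(L)] - fp$r_I[length(L) - 1]) / 0.001
  expect_equal(hi_slope, p$lambda / (p$W_II + 1), tolerance = 1e-6)
  pb <- apply_blockers(p, "e_blocked", blocker_efficacy(0.4, 1))
  fpb <- fixed_point(pb, L)
  hi_slope_b <- (fpb$r_I[length(L)] - fpb$r_I[length(L) - 1]) / 0.001
  expect_equal(hi_slope_b, hi_slope, tolerance = 1e-6)
})

test_that("parameter JSON round-trips, with rectified-linear as the b-less default", {
  p <- eq_params()
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_params_json(p, f, taus = eq_taus())
  got <- read_params_json(f)
  expect_equal(got$params, p)
  expect_equal(got$taus, eq_taus())
  sp <- two_pop_params(2, 1, 3, 2, 5, 20, 2,
                       tf_E = transfer_function("softplus", 1, 1, 0.5),
                       tf_I = transfer_function("softplus", 1, 4, 0.5))
  write_params_json(sp, f)
  expect_equal(read_params_json(f)$params, sp)
})
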