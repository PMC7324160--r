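test_that("pharmacological classification detects opsin-driven units with high power", {
  set.seed(101)
  # expressing unit: strong positive change under full blockade
  u_inh <- make_unit("inh", "ei_blocked", c(0, 1, 2), c(5, 15, 25))
  r <- classify_pharma(u_inh)
  expect_equal(r$label, "I")
  expect_lt(r$p_value, 0.01)
  expect_gt(r$effect, 0)
  # silent-under-blockade unit
  u_exc <- make_unit("exc", "ei_blocked", c(0, 1, 2), c(3, 1, 0))
  expect_equal(classify_pharma(u_exc)$label, "E")
  # constant zero counts: no positive change, never inhibitory
  u0 <- make_unit("zero", "ei_blocked", c(0, 2), c(0, 0))
  expect_equal(classify_pharma(u0)$label, "E")
  # method unavailable without the blocker phase
  u_only_intact <- make_unit("x", "intact", c(0, 2), c(5, 3))
  expect_error(classify_pharma(u_only_intact), "unavailable|no")
})

test_that("pharmacological classification keeps its false-inhibitory rate at alpha", {
  set.seed(202)
  # 1000 non-expressing units: identical Poisson rates at baseline and max
  n_false <- 0
  for (i in 1:1000) {
    u <- make_unit("null", "ei_blocked", c(0, 2), c(5, 5), trials = 50)
    if (classify_pharma(u, alpha = 0.01)$label == "I") n_false <- n_false + 1
  }
  # two-sided test plus positive-sign requirement: expected rate alpha / 2
  expect_lte(n_false / 1000, 0.015)
})

test_that("high-power classification works on the intact phase and is stringent", {
  set.seed(303)
  # inhibitory unit whose rate at max intensity exceeds baseline (non-ISN branch)
  u_i <- make_unit("i1", "intact", c(0, 1, 6), c(9, 5, 14), trials = 200)
  expect_equal(classify_high_power(u_i)$label, "I")
  # monotonically suppressed excitatory unit
  u_e <- make_unit("e1", "intact", c(0, 1, 6), c(8, 4, 0.5), trials = 200)
  expect_equal(classify_high_power(u_e)$label, "E")
  # inhibitory unit that never rises above baseline: a documented miss
  u_miss <- make_unit("i2", "intact", c(0, 1, 6), c(9, 5, 7), trials = 200)
  expect_equal(classify_high_power(u_miss)$label, "E")
})

test_that("waveform-width classification splits the bimodal mixture", {
  set.seed(404)
  n <- 200
  labels <- rep(c("E", "I"), c(160, 40))
  widths <- ifelse(labels == "E", rnorm(n, 0.58, 0.05), rnorm(n, 0.46, 0.05))
  units <- data.frame(session = "s01", unit_id = sprintf("u%03d", 1:n),
                      phase = "intact", laser_mW = 0, trial = 1,
                      spike_count = 1, window_s = 0.3, width_ms = widths)
  cw <- classify_width(units)
  expect_gt(cw$threshold_ms, 0.46)
  expect_lt(cw$threshold_ms, 0.58)
  acc <- mean(cw$result$label == labels[match(cw$result$unit_id, units$unit_id)])
  expect_gt(acc, 0.85)
  # permutation invariance
  perm <- units[sample(nrow(units)), ]
  cw2 <- classify_width(perm)
  o1 <- order(cw$result$unit_id); o2 <- order(cw2$result$unit_id)
  expect_equal(cw2$result$label[o2], cw$result$label[o1])
  expect_equal(cw2$threshold_ms, cw$threshold_ms)
  # degenerate width distribution
  units$width_ms <- 0.5
  expect_error(classify_width(units), "unimodal")
})

test_that("L0 is found as the breakpoint of a two-segment piecewise-linear fit", {
  # noiseless V shape with minimum at 1.5 mW
  x <- seq(0, 4, by = 0.25)
  y <- ifelse(x < 1.5, 10 - 4 * (x - 0) , 4 + 2 * (x - 1.5))
  y[x < 1.5] <- 10 - 4 * x[x < 1.5]
  nf <- find_L0(data.frame(laser_mW = x, rate = y))
  expect_true(nf$paradoxical)
  expect_equal(nf$L0_mW, 1.5, tolerance = 0.01 / 1.5)
  expect_equal(nf$slope1, -4, tolerance = 1e-3)
  expect_equal(nf$slope2, 2, tolerance = 1e-3)
  # small noise: breakpoint within one grid step of truth
  set.seed(55)
  nf2 <- find_L0(data.frame(laser_mW = x, rate = y + rnorm(length(x), 0, 0.15)))
  expect_lt(abs(nf2$L0_mW - 1.5), 0.25)
  # monotone response: no paradoxical minimum
  nf3 <- find_L0(data.frame(laser_mW = x, rate = 2 + 3 * x))
  expect_false(nf3$paradoxical)
  expect_true(is.na(nf3$L0_mW))
  expect_error(find_L0(data.frame(laser_mW = 1:3, rate = 1:3)), "4 intensity")
})

test_that("initial slopes are OLS over the sub-minimum range with the +0.1 regularizer", {
  u <- make_unit("u", "intact", c(0, 1), c(10, 4), trials = 4000)
  sl <- initial_slope(u, normalization = 1)
  expect_equal(sl$raw_slope, -6, tolerance = 0.05)
  expect_equal(sl$normalized_slope, -6 / 10.1, tolerance = 0.05)
  # flat response
  set.seed(14)
  u2 <- make_unit("u2", "intact", c(0, 0.5, 1), c(7, 7, 7), trials = 20000)
  expect_lt(abs(initial_slope(u2, 1)$raw_slope), 0.1)
  # silent baseline: the 0.1 floor keeps the normalized slope finite
  u3 <- make_unit("u3", "intact", c(0, 1), c(0, 1), trials = 500)
  sl3 <- initial_slope(u3, 1)
  expect_gte(sl3$normalized_slope, 0)
  expect_true(is.finite(sl3$normalized_slope))
  # intensities above L0 are excluded; fewer than 2 usable levels errors
  expect_error(initial_slope(make_unit("u4", "intact", c(0, 5), c(5, 5)), 1),
               "fewer than 2")
})

test_that("population averages match single units and locate the inhibitory minimum", {
  set.seed(66)
  u <- make_unit("a", "intact", c(0, 1, 2), c(10, 6, 8), trials = 300)
  lab <- c(a = "I")
  pa <- population_average(u, lab, "I")
  expect_equal(pa$mean_rate, c(10, 6, 8), tolerance = 0.05)
  expect_equal(pa$n_units, rep(1, 3))
  expect_true(all(pa$sem > 0))
  # two identical-rate units: same mean, smaller sem
  u2 <- rbind(u, make_unit("b", "intact", c(0, 1, 2), c(10, 6, 8), trials = 300))
  pa2 <- population_average(u2, c(a = "I", b = "I"), "I")
  expect_equal(pa2$mean_rate, pa$mean_rate, tolerance = 0.05)
  expect_lt(mean(pa2$sem), mean(pa$sem))
  # model-generated population: the average I curve dips at E silencing
  p <- eq_params()
  grid <- seq(0, 3, by = 0.25)
  fp <- fixed_point(p, grid)
  units <- do.call(rbind, lapply(1:6, function(k)
    make_unit(paste0("i", k), "intact", grid, fp$r_I, trials = 150)))
  labs <- stats::setNames(rep("I", 6), paste0("i", 1:6))
  pai <- population_average(units, labs, "I")
  L_star <- grid[which(fp$r_E <= 0)[1]]
  expect_lte(abs(pai$laser_mW[which.min(pai$mean_rate)] - L_star), 0.25 + 1e-9)
})

test_that("the inhibitory onset transient is detected and measured", {
  # the model transient at 2.6x the inhibitory minimum is ~1 spk/s on a
  # ~9 spk/s baseline, so the pooled PSTH needs many sweeps for the
  # 12-bin KS comparison to resolve it
  gd <- generate_dynamics(generator_config(), L_level = 2.6, seed = 7,
                          n_units_I = 56, n_trials = 6000, onset_artifact = TRUE)
  psth_I <- gd$psth[gd$psth$population == "I", ]
  tr <- detect_transient(psth_I, onset_ms = 0)
  expect_true(tr$significant)
  expect_gt(tr$peak_amplitude, 0)
  expect_gt(tr$crossing_time_ms, 5)
  expect_lt(tr$crossing_time_ms, 25)
  expect_lt(tr$normalized_steady_state, 0)   # paradoxical suppression
  expect_gt(tr$normalized_transient, 0)
  expect_error(detect_transient(psth_I[psth_I$time_ms > -5, ], 0), "baseline")
})

test_that("transient detection is calibrated on flat PSTHs and silent on clamped ones", {
  set.seed(77)
  n_false <- 0
  for (i in 1:200) {
    flat <- data.frame(time_ms = seq(-20, 40), rate = rpois(61, 50) / 5)
    if (detect_transient(flat, onset_ms = 0)$significant) n_false <- n_false + 1
  }
  expect_lte(n_false / 200, 0.05)
  # clamping the rise removes significance most of the time
  gd <- generate_dynamics(generator_config(), L_level = 2.6, seed = 13,
                          n_units_I = 56, n_trials = 100)
  psth_I <- gd$psth[gd$psth$population == "I", ]
  base <- mean(psth_I$rate[psth_I$time_ms < 0])
  n_sig <- 0
  for (i in 1:20) {
    clamped <- psth_I
    post <- clamped$time_ms >= 0
    clamped$rate[post] <- pmin(clamped$rate[post], base)
    # re-jitter the clamped section so repeats differ
    clamped$rate <- clamped$rate * runif(nrow(clamped), 0.97, 1.03)
    if (detect_transient(clamped, onset_ms = 0)$significant) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / 20, 0.2)
})

test_that("model current decomposition obeys the fixed-point identity", {
  cur <- currents_into_E(eq_params(), 0)
  expect_equal(cur$E_current, 19.6, tolerance = 5e-3)
  expect_equal(cur$I_current, -13.7, tolerance = 5e-3)
  expect_equal(cur$net, 5.85, tolerance = 1e-3)
  set.seed(88)
  for (i in 1:100) {
    p <- random_stable_params()
    fp <- fixed_point(p, 0)
    cur <- currents_into_E(p, 0)
    expect_equal(cur$net * p$tf_E$threshold - p$tf_E$threshold, fp$r_E,
                 tolerance = 1e-9)
  }
  # zero recurrence
  p0 <- two_pop_params(0, 0, 0, 0, 5, 20, 1,
                       tf_E = transfer_function(threshold = 2),
                       tf_I = transfer_function(threshold = 2))
  c0 <- currents_into_E(p0, 0)
  expect_equal(c0$E_current, 5 / 2)
  expect_equal(c0$I_current, 0)
})

test_that("pharma and high-power classification agree on most synthetic units", {
  cfg <- generator_config(n_sessions = 1, units_per_session = 40,
                          trials_per_level = 400, rate_sigma = 0.3,
                          laser_mW = c(0, 0.5, 1, 2, 5, 10),
                          L0_range = c(1, 1), eps_range = c(0.3, 0.3))
  gen <- generate_dataset(cfg, seed = 31)
  c1 <- classify_units(gen$units, "pharma")
  c2 <- classify_units(gen$units, "high_power")
  agree <- mean(c1$label[order(c1$unit_id)] == c2$label[order(c2$unit_id)])
  expect_gt(agree, 0.8)
})

test_that("normalized slopes are invariant under the raw laser unit", {
  set.seed(91)
  grid <- c(0, 0.4, 0.8, 1.2, 1.6)
  fp <- fixed_point(eq_params(), grid)
  u <- make_unit("u", "intact", grid, fp$r_I, trials = 400)
  sl1 <- initial_slope(u, 1.2)
  u2 <- u; u2$laser_mW <- u2$laser_mW * 37.5   # arbitrary raw unit
  sl2 <- initial_slope(u2, 1.2 * 37.5)
  expect_equal(sl2$raw_slope, sl1$raw_slope, tolerance = 1e-9)
  expect_equal(sl2$normalized_slope, sl1$normalized_slope, tolerance = 1e-9)
})
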