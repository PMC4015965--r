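test_that("noise-free steady state reproduces a hand evaluation of the cascade", {
  c1 <- prbs_component("J6", "constitutive", P_c = 6)
  c2 <- hand_repressor("L3", P_M = 25, P_m = 0.4, K_tf = 40, n_tf = 2,
                       K_I = 0.2, n_I = 2)
  c3 <- hand_repressor("T3", P_M = 60, P_m = 1, K_tf = 30, n_tf = 2,
                       K_I = 8, n_I = 1.5)
  ctx <- cell_context(mu = 0.02, gamma_repressor1 = 0.01,
                      gamma_repressor2 = 0.012, gamma_im_x1 = 0.01,
                      gamma_m_x1 = 0.004, gamma_im_x2 = 0.011,
                      gamma_m_x2 = 0.005, m1 = 0.05, m2 = 0.06)
  circ <- transistor_circuit(c1, c2, c3, ctx)
  I1 <- 0.1; I2 <- 2

  # independent evaluation, written out formula by formula
  x_r1 <- 6 / (0.02 + 0.01)
  xf1 <- x_r1 / (1 + (I1 / 0.2)^2)
  p2 <- 0.4 + (25 - 0.4) / (1 + (xf1 / 40)^2)
  x_r2 <- p2 / (0.02 + 0.012)
  x1 <- p2 / (0.05 + 0.02 + 0.01)
  g1 <- 0.05 * x1 / (0.02 + 0.004)
  xf2 <- x_r2 / (1 + (I2 / 8)^1.5)
  p3 <- 1 + (60 - 1) / (1 + (xf2 / 30)^2)
  x2 <- p3 / (0.06 + 0.02 + 0.011)
  g2 <- 0.06 * x2 / (0.02 + 0.005)

  ss <- steady_state(circ, I1, I2)
  expect_equal(unclass(ss),
               c(x_repressor1 = x_r1, x_repressor2 = x_r2, x1 = x1,
                 g1 = g1, x2 = x2, g2 = g2))
  # the two reporter identities hold exactly for any circuit
  expect_equal(ss[["g2"]], 0.06 * ss[["x2"]] / (0.02 + 0.005))
  expect_equal(ss[["x_repressor1"]], 6 / (0.02 + 0.01))
})

test_that("the steady state is a fixed point and attracts the zero state", {
  for (seed in c(2, 9)) {
    circ <- quick_circuit(seed)
    ss <- unclass(steady_state(circ, 0.2, 0.5))
    traj <- simulate_dynamics(circ, 0.2, 0.5, t_span = 50, dt = 1, init = ss)
    final <- unlist(traj[nrow(traj), -1])
    expect_equal(final, ss, tolerance = 1e-6)

    rates <- with(circ$context,
                  c(mu + gamma_repressor1, mu + gamma_repressor2,
                    m1 + mu + gamma_im_x1, mu + gamma_m_x1,
                    m2 + mu + gamma_im_x2, mu + gamma_m_x2))
    t_conv <- 14 / min(rates)
    traj0 <- simulate_dynamics(circ, 0.2, 0.5, t_span = t_conv, dt = t_conv / 200)
    final0 <- unlist(traj0[nrow(traj0), -1])
    expect_equal(final0, ss, tolerance = 1e-3)
  }
})

test_that("an all-zero fluctuation spec makes noisy paths identical to deterministic ones", {
  circ <- quick_circuit(3, fluctuations = no_fluctuations())
  det <- simulate_dynamics(circ, 0.1, 1, t_span = 30, dt = 0.5)
  for (seed in c(1, 77)) {
    sto <- simulate_dynamics(circ, 0.1, 1, t_span = 30, dt = 0.5,
                             noise = TRUE, seed = seed)
    expect_identical(sto, det)
    expect_equal(unclass(steady_state(circ, 0.1, 1, noise = TRUE, seed = seed)),
                 unclass(steady_state(circ, 0.1, 1)))
  }
})

test_that("stochastic paths stay non-negative and seeded runs are reproducible", {
  circ <- quick_circuit(4, fluctuations = fluctuation_spec(0.05, 1, 0.5))
  a <- simulate_dynamics(circ, 0.05, 0, t_span = 60, dt = 0.1,
                         noise = TRUE, seed = 11)
  b <- simulate_dynamics(circ, 0.05, 0, t_span = 60, dt = 0.1,
                         noise = TRUE, seed = 11)
  expect_identical(a, b)
  expect_true(all(as.matrix(a[-1]) >= 0))
})

test_that("the stochastic ensemble mean agrees with the deterministic steady state", {
  circ <- quick_circuit(5, fluctuations = fluctuation_spec(0.05, 0.5, 0))
  ss <- unclass(steady_state(circ, 0.2, 0))
  n_rep <- 100
  finals <- vapply(seq_len(n_rep), function(s) {
    traj <- simulate_dynamics(circ, 0.2, 0, t_span = 120, dt = 0.1,
                              noise = TRUE, seed = 1000 + s, init = ss)
    traj$g2[nrow(traj)]
  }, numeric(1))
  se <- sd(finals) / sqrt(n_rep)
  expect_lt(abs(mean(finals) - ss[["g2"]]), 3 * se)
})

test_that("io_response inverts monotonically and responds to the output inducer", {
  circ <- quick_circuit(6)
  grid <- exp(seq(log(1e-3), log(10), length.out = 20))
  r0 <- io_response(circ, grid, I2 = 0)
  expect_true(all(diff(r0$g1) > 0))
  expect_true(all(diff(r0$g2) <= 1e-9 * max(r0$g2)))
  r2 <- io_response(circ, grid, I2 = 5)
  expect_true(all(r2$g2 >= r0$g2 - 1e-9 * max(r0$g2)))
  # single-point grid equals a steady-state call
  r1 <- io_response(circ, grid[3], I2 = 5)
  ss <- steady_state(circ, grid[3], 5)
  expect_equal(c(r1$g1, r1$g2), c(ss[["g1"]], ss[["g2"]]))
  expect_error(io_response(circ, numeric(0), 0), class = "gt_argument_error")
})

test_that("input_range_map is ordered, degenerate-safe and widens monotonically", {
  circ <- quick_circuit(7)
  rng <- input_range_map(circ, 1e-3, 10)
  expect_true(is.finite(rng[["g1_low"]]) && is.finite(rng[["g1_high"]]))
  expect_lte(rng[["g1_low"]], rng[["g1_high"]])
  deg <- input_range_map(circ, 0.5, 0.5)
  expect_equal(deg[["g1_low"]], deg[["g1_high"]])
  wide <- input_range_map(circ, 1e-4, 100)
  expect_lte(wide[["g1_low"]], rng[["g1_low"]])
  expect_gte(wide[["g1_high"]], rng[["g1_high"]])
  expect_error(input_range_map(circ, 2, 1), class = "gt_argument_error")
})
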