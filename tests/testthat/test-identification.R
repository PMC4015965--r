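make_id_problem <- function(seed = 4, noise = 0, tc_seed = 1,
                            times = seq(5, 360, by = 5)) {
  lib <- make_library(quick_cfg(seed), "repressor_regulated")
  comp <- lib$components[[2]]
  ctx <- cell_context()
  sched <- data.frame(time = c(0, 180), I = c(0, 100 * comp$K_I))
  tc <- make_timecourse(comp, ctx, x_reg = 3 * comp$K_tf, schedule = sched,
                        noise_level = noise, seed = tc_seed, times = times)
  list(component = comp, context = ctx, tc = tc)
}

test_that("the analytic reporter trajectory matches a numerical integration", {
  pb <- make_id_problem()
  comp <- pb$component; ctx <- pb$context
  sched <- attr(pb$tc, "schedule")
  x_reg <- attr(pb$tc, "x_reg")
  times <- seq(0, 360, by = 5)
  ana <- reporter_trajectory(comp, ctx, times, x_reg, sched)

  a <- ctx$m1 + ctx$mu + ctx$gamma_im_x1
  b <- ctx$mu + ctx$gamma_m_x1
  rhs <- function(t, s, p) {
    I <- sched$I[findInterval(t, sched$time)]
    r <- repressor_rate(comp, x_reg, I)
    list(c(r - a * s[1], ctx$m1 * s[1] - b * s[2]))
  }
  num <- deSolve::lsoda(c(x = 0, g = 0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(ana$g, unname(num[, "g"]), tolerance = 1e-6)
  expect_equal(ana$x, unname(num[, "x"]), tolerance = 1e-6)
})

test_that("noiseless generate-then-fit recovers the kinetic strengths", {
  for (seed in c(4, 8)) {
    pb <- make_id_problem(seed)
    fit <- identify_kinetics(pb$tc, pb$component, pb$context, seed = 1)
    truth <- c(P_M = pb$component$P_M, P_m = pb$component$P_m)
    expect_lt(max(abs(fit$estimates - truth) / truth), 0.02)
    # residual is numerically zero relative to the signal
    expect_lt(fit$rss, 1e-8 * sum(pb$tc$fluorescence_au^2))
    expect_true(fit$converged)
  }
})

test_that("constitutive strengths are recovered through the same interface", {
  cfg1 <- quick_cfg(seed = 2, n = 1)
  comp <- make_library(cfg1, "constitutive")$components[[1]]
  ctx <- cell_context()
  tc <- make_timecourse(comp, ctx, noise_level = 0, seed = 1)
  fit <- identify_kinetics(tc, comp, ctx, seed = 1)
  expect_equal(unname(fit$estimates["P_c"]), comp$P_c, tolerance = 1e-4)
})

test_that("degenerate and undersized inputs raise classed errors", {
  pb <- make_id_problem()
  zero <- timecourse(pb$tc$time_min, rep(0, nrow(pb$tc)),
                     x_reg = attr(pb$tc, "x_reg"),
                     schedule = attr(pb$tc, "schedule"))
  expect_error(identify_kinetics(zero, pb$component, pb$context),
               class = "gt_identifiability_error")
  short <- timecourse(pb$tc$time_min[1:3], pb$tc$fluorescence_au[1:3],
                      x_reg = attr(pb$tc, "x_reg"),
                      schedule = attr(pb$tc, "schedule"))
  expect_error(identify_kinetics(short, pb$component, pb$context),
               class = "gt_argument_error")
})

test_that("estimates respect bounds and widening bounds never worsens the fit", {
  pb <- make_id_problem(noise = 0.05, tc_seed = 3)
  truth <- c(P_M = pb$component$P_M, P_m = pb$component$P_m)
  narrow <- identify_kinetics(pb$tc, pb$component, pb$context,
                              lower = truth * 1.1, upper = truth * 2,
                              seed = 1)
  expect_true(all(narrow$estimates >= truth * 1.1 - 1e-9) &&
                all(narrow$estimates <= truth * 2 + 1e-9))
  wide <- identify_kinetics(pb$tc, pb$component, pb$context,
                            lower = truth / 10, upper = truth * 10,
                            init = narrow$estimates, seed = 1)
  expect_lte(wide$rss, narrow$rss + 1e-9)
  # the fitted residual is no worse than the residual at the true parameters
  traj <- reporter_trajectory(pb$component, pb$context, pb$tc$time_min,
                              attr(pb$tc, "x_reg"), attr(pb$tc, "schedule"))
  rss_truth <- sum((traj$g - pb$tc$fluorescence_au)^2)
  expect_lte(wide$rss, rss_truth + 1e-9)
})

test_that("recovery error shrinks as the time course grows", {
  lengths <- list(seq(5, 360, by = 60), seq(5, 360, by = 20),
                  seq(5, 360, by = 5))
  err <- vapply(lengths, function(tt) {
    errs <- vapply(1:30, function(s) {
      pb <- make_id_problem(seed = 4, noise = 0.05, tc_seed = 100 + s,
                            times = tt)
      fit <- identify_kinetics(pb$tc, pb$component, pb$context,
                               n_starts = 4, seed = 1)
      abs(fit$estimates[["P_M"]] - pb$component$P_M) / pb$component$P_M
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("time courses round-trip through CSV with their metadata sidecar", {
  pb <- make_id_problem(noise = 0.05, tc_seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(pb$tc, path)
  tc2 <- read_timecourse(path)
  expect_equal(tc2$fluorescence_au, pb$tc$fluorescence_au)
  expect_equal(attr(tc2, "x_reg"), attr(pb$tc, "x_reg"))
  expect_equal(as.data.frame(attr(tc2, "schedule")),
               as.data.frame(attr(pb$tc, "schedule")))
})
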