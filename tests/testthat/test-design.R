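test_that("desired amplifier response is the specified line", {
  sp <- amplifier_spec(gain = -2, g1_low = 298, g1_high = 431, g2_high = 690)
  yd <- desired_response(sp)
  g <- seq(298, 431, length.out = 7)
  expect_equal(yd(g), -2 * g + 1286)
  expect_equal(yd(298), 690)                       # y_d(g1_low) = g2_high
  expect_equal((yd(340) - yd(320)) / 20, -2)       # slope by finite difference
  expect_error(yd(200), class = "gt_domain_error")
  expect_error(amplifier_spec(2, 0, 10, 5), class = "gt_argument_error")
})

test_that("desired switch response has the stated limits and midpoint", {
  sp <- switch_spec(H_s = 3249.7, L_s = 120, g_t = 150.4)
  yd <- desired_response(sp)
  expect_equal(yd(0), 3249.7)
  expect_equal(yd(150.4), (3249.7 + 120) / 2)
  expect_lt(yd(1e9), 120 + 1e-3)
  expect_error(yd(-1), class = "gt_domain_error")
  expect_error(switch_spec(10, 20, 5), class = "gt_argument_error")
})

test_that("the quadrature of a squared deviation is zero iff the curves agree", {
  g <- seq(0, 10, length.out = 41)
  expect_identical(gtdesign:::.integrate_sq_dev(sin(g), sin(g), g), 0)
  expect_gt(gtdesign:::.integrate_sq_dev(sin(g), cos(g), g), 0)
})

test_that("design cost is non-negative and matches the curve's deviation from its own secant", {
  pp <- make_planted_design_problem(quick_cfg(seed = 1), "amplifier")
  comp <- pp$library$components[[pp$planted$component_id]]
  cv <- design_cost(pp$circuit_template, comp, pp$planted$I2, pp$spec,
                    quadrature_points = 201)
  expect_gte(cv$J, 0)

  # independent reference: deviation from linearity of the transfer curve,
  # computed directly from steady-state evaluations on a dense grid
  circ <- transistor_circuit(pp$circuit_template$c1, pp$circuit_template$c2,
                             comp, pp$circuit_template$context,
                             no_fluctuations())
  sp <- pp$spec
  g1 <- seq(sp$g1_low, sp$g1_high, length.out = 201)
  g2 <- vapply(g1, function(g) {
    I1 <- gtdesign:::.invert_g1(circ, g)
    steady_state(circ, I1, pp$planted$I2)[["g2"]]
  }, numeric(1))
  secant <- sp$gain * (g1 - sp$g1_low) + sp$g2_high
  ref <- gtdesign:::.integrate_sq_dev(g2, secant, g1)
  expect_equal(cv$J, ref, tolerance = 1e-6)
})

test_that("an unreachable input range raises an infeasibility error naming the achievable interval", {
  circ <- quick_circuit(2)
  rng <- input_range_map(circ, 0, Inf)
  sp <- amplifier_spec(-1, rng[["g1_high"]] * 2, rng[["g1_high"]] * 3,
                       g2_high = 100)
  expect_error(design_cost(circ, circ$c3, 0, sp), class = "gt_infeasible")
  err <- tryCatch(design_cost(circ, circ$c3, 0, sp), gt_infeasible = identity)
  expect_match(conditionMessage(err), "achieves g1 in")
})

test_that("GA on a singleton domain returns that pair without searching", {
  pp <- make_planted_design_problem(quick_cfg(seed = 3), "amplifier")
  one <- prbs_library("one", pp$library$components[2])
  dom <- search_domain(one, 0.5, 0.5)
  res <- ga_search(dom, pp$circuit_template, pp$spec, ga_config(seed = 1))
  expect_identical(res$component_id, names(one$components)[1])
  expect_identical(res$I2, 0.5)
})

test_that("seeded GA runs are bit-reproducible and best-so-far cost never increases", {
  pp <- make_planted_design_problem(quick_cfg(seed = 4), "switch")
  cfgga <- ga_config(pop_size = 20, generations = 25, seed = 9)
  a <- ga_search(pp$domain, pp$circuit_template, pp$spec, cfgga)
  b <- ga_search(pp$domain, pp$circuit_template, pp$spec, cfgga)
  expect_identical(a[c("component_id", "I2", "J", "history")],
                   b[c("component_id", "I2", "J", "history")])
  expect_true(all(diff(a$history) <= 0))
})

test_that("demanding a gain no candidate achieves strictly raises the minimal cost", {
  pp <- make_planted_design_problem(quick_cfg(seed = 5), "amplifier")
  sp <- pp$spec
  harder <- amplifier_spec(gain = 5 * sp$gain, g1_low = sp$g1_low,
                           g1_high = sp$g1_high, g2_high = sp$g2_high)
  ref <- exhaustive_search(pp$domain, pp$circuit_template, sp)
  ref_hard <- exhaustive_search(pp$domain, pp$circuit_template, harder)
  expect_gt(ref_hard$J, ref$J)
})

test_that("the lookup table composes GA results and flags infeasible specs", {
  pp <- make_planted_design_problem(quick_cfg(seed = 6), "amplifier")
  rng <- input_range_map(pp$circuit_template, 0, Inf)
  bad <- amplifier_spec(-1, rng[["g1_high"]] * 2, rng[["g1_high"]] * 3, 50)
  cfgga <- ga_config(pop_size = 20, generations = 25, seed = 2)
  tab <- build_lookup_table(pp$domain, pp$circuit_template,
                            list(pp$spec, bad), cfgga)
  expect_identical(nrow(tab), 2L)
  expect_identical(names(tab),
                   c("input_range_low", "input_range_high", "gain_or_levels",
                     "component", "inducer_concentration", "units", "J"))
  single <- ga_search(pp$domain, pp$circuit_template, pp$spec, cfgga)
  expect_identical(tab$component[1], single$component_id)
  expect_identical(tab$inducer_concentration[1], single$I2)
  expect_identical(tab$J[1], single$J)
  expect_true(is.na(tab$component[2]) && is.na(tab$J[2]))
  expect_error(build_lookup_table(pp$domain, pp$circuit_template, list()),
               class = "gt_argument_error")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_lookup_table(tab, path)
  back <- utils::read.delim(path)
  expect_identical(nrow(back), 2L)
  expect_identical(back$component[1], single$component_id)
})

test_that("design specs round-trip through the JSON config dialect", {
  sp <- amplifier_spec(-2, 298, 431, 690)
  path <- withr::local_tempfile(fileext = ".json")
  write_spec_json(sp, path)
  sp2 <- read_design_spec(path)
  expect_s3_class(sp2, "amplifier_spec")
  expect_equal(unclass(sp2), unclass(sp))
  expect_error(read_design_spec(withr::local_tempfile(fileext = ".json")),
               class = "gt_parse_error")
})
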