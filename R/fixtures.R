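# Seeded synthetic-data generators: promoter-RBS libraries, cellular
# contexts, full circuits, noisy reporter time courses, and planted design
# problems with a known optimum.  Everything is reproducible bit-exactly
# from (seed, config).

#' Configuration of the synthetic-data generators
#'
#' Kinetic strengths are sampled log-uniformly because mutagenised promoter
#' libraries span orders of magnitude; basal levels are a small fraction of
#' the maximal strength; binding constants and context rates are drawn
#' within physiological ranges for exponentially growing *E. coli*.
#'
#' @param seed Master RNG seed.
#' @param n_components Components per generated library.
#' @param P_range Log-uniform sampling range for `P_M` (and `P_c`),
#'   a.u. min^-1.
#' @param basal_fraction_range Range of `P_m / P_M` ratios.
#' @param K_tf_range Log-uniform range for the regulator half-effect
#'   constant (a.u.).
#' @param n_tf_range Uniform range for the regulator Hill coefficient.
#' @param K_I_range Log-uniform range for the inducer half-effect constant
#'   (inducer units).
#' @param n_I_range Uniform range for the inducer Hill coefficient.
#' @param mu_range,gamma_range,maturation_range Uniform ranges for the
#'   context rates (min^-1).
#' @param noise_level Multiplicative measurement-noise CV for generated
#'   time courses.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1, n_components = 5,
                           P_range = c(5, 200),
                           basal_fraction_range = c(0.005, 0.05),
                           K_tf_range = c(10, 200),
                           n_tf_range = c(1, 3),
                           K_I_range = c(0.05, 2),
                           n_I_range = c(1, 3),
                           mu_range = c(0.015, 0.025),
                           gamma_range = c(0.004, 0.015),
                           maturation_range = c(0.03, 0.08),
                           noise_level = 0.05) {
  rng_ok <- function(r, positive = TRUE) {
    length(r) == 2L && all(is.finite(r)) && r[1L] <= r[2L] &&
      (!positive || r[1L] > 0)
  }
  for (nm in c("P_range", "basal_fraction_range", "K_tf_range", "n_tf_range",
               "K_I_range", "n_I_range", "mu_range", "gamma_range",
               "maturation_range")) {
    if (!rng_ok(get(nm)))
      gt_stop(sprintf("`%s` must be a positive ordered pair", nm),
              "gt_argument_error")
  }
  check_scalar(n_components, "n_components", 1)
  check_scalar(noise_level, "noise_level", 0)
  structure(list(seed = seed, n_components = as.integer(n_components),
                 P_range = P_range,
                 basal_fraction_range = basal_fraction_range,
                 K_tf_range = K_tf_range, n_tf_range = n_tf_range,
                 K_I_range = K_I_range, n_I_range = n_I_range,
                 mu_range = mu_range, gamma_range = gamma_range,
                 maturation_range = maturation_range,
                 noise_level = noise_level),
            class = "fixture_config")
}

.runif_log <- function(n, range) exp(stats::runif(n, log(range[1L]), log(range[2L])))

#' Generate a seeded promoter-RBS library
#'
#' @param cfg A [fixture_config()].
#' @param regulation_class Class of every generated component.
#' @param name Library name; defaults to a class-derived label.
#' @param inducer_name Inducer for regulated classes (e.g. `"IPTG"` in mM,
#'   `"aTc"` in ng/ml).
#' @param id_prefix One-letter id prefix in the field's naming style
#'   (`"J"` constitutive, `"L"` Lac-type, `"T"` Tet-type).
#' @return A [prbs_library()], deterministic given `cfg$seed`.
#' @export
make_library <- function(cfg, regulation_class = "repressor_regulated",
                         name = NULL, inducer_name = "aTc",
                         id_prefix = NULL) {
  if (!inherits(cfg, "fixture_config"))
    gt_stop("`cfg` must be a fixture_config", "gt_argument_error")
  if (is.null(id_prefix))
    id_prefix <- switch(regulation_class, constitutive = "J",
                        repressor_regulated = "T",
                        activator_regulated = "A")
  if (is.null(name))
    name <- switch(regulation_class, constitutive = "Lib_const",
                   repressor_regulated = paste0("Lib_", id_prefix),
                   activator_regulated = "Lib_act")
  with_preserved_seed(cfg$seed, {
    comps <- lapply(seq_len(cfg$n_components), function(i) {
      id <- paste0(id_prefix, i)
      if (regulation_class == "constitutive") {
        prbs_component(id, "constitutive",
                       P_c = .runif_log(1, cfg$P_range))
      } else {
        P_M <- .runif_log(1, cfg$P_range)
        P_m <- P_M * stats::runif(1, cfg$basal_fraction_range[1L],
                                  cfg$basal_fraction_range[2L])
        prbs_component(id, regulation_class,
                       P_M = P_M, P_m = P_m,
                       K_tf = .runif_log(1, cfg$K_tf_range),
                       n_tf = stats::runif(1, cfg$n_tf_range[1L],
                                           cfg$n_tf_range[2L]),
                       K_I = .runif_log(1, cfg$K_I_range),
                       n_I = stats::runif(1, cfg$n_I_range[1L],
                                          cfg$n_I_range[2L]),
                       inducer_name = inducer_name)
      }
    })
    prbs_library(name, comps)
  })
}

#' Generate a seeded cellular context
#'
#' @inheritParams make_library
#' @return A [cell_context()] with rates drawn from the config ranges.
#' @export
make_context <- function(cfg) {
  with_preserved_seed(cfg$seed + 104729L, {
    g <- function() stats::runif(1, cfg$gamma_range[1L], cfg$gamma_range[2L])
    cell_context(
      mu = stats::runif(1, cfg$mu_range[1L], cfg$mu_range[2L]),
      gamma_repressor1 = g(), gamma_repressor2 = g(),
      gamma_im_x1 = g(), gamma_m_x1 = g(),
      gamma_im_x2 = g(), gamma_m_x2 = g(),
      m1 = stats::runif(1, cfg$maturation_range[1L],
                        cfg$maturation_range[2L]),
      m2 = stats::runif(1, cfg$maturation_range[1L],
                        cfg$maturation_range[2L]))
  })
}

#' Generate a complete seeded transistor circuit
#'
#' Draws a constitutive `c1`, repressor-regulated `c2` (IPTG-type input
#' device) and `c3` (aTc-type output stage) plus a context, and wires them
#' with the standard 5% fluctuation specification.
#'
#' @inheritParams make_library
#' @param fluctuations A [fluctuation_spec()].
#' @return A [transistor_circuit()].
#' @export
make_circuit <- function(cfg, fluctuations = fluctuation_spec()) {
  cfg1 <- cfg; cfg1$n_components <- 1L
  cfg_c1 <- cfg1; cfg_c1$seed <- cfg$seed + 11L
  cfg_c2 <- cfg1; cfg_c2$seed <- cfg$seed + 23L
  cfg_c3 <- cfg1; cfg_c3$seed <- cfg$seed + 37L
  c1 <- make_library(cfg_c1, "constitutive")$components[[1L]]
  c2 <- make_library(cfg_c2, "repressor_regulated", inducer_name = "IPTG",
                     id_prefix = "L")$components[[1L]]
  c3 <- make_library(cfg_c3, "repressor_regulated", inducer_name = "aTc",
                     id_prefix = "T")$components[[1L]]
  transistor_circuit(c1, c2, c3, make_context(cfg), fluctuations)
}

#' Generate a noisy reporter time course
#'
#' Simulates the deterministic reporter trajectory of a component under a
#' constant regulator level and a stepwise inducer schedule, then applies
#' multiplicative Gaussian measurement noise (clipped at zero).
#'
#' @param component A [prbs_component()].
#' @param context A [cell_context()].
#' @param x_reg Constant regulator concentration (a.u.).
#' @param schedule Inducer schedule (`data.frame(time, I)`).
#' @param noise_level Multiplicative noise CV (0 gives the exact
#'   deterministic samples).
#' @param seed RNG seed.
#' @param times Sampling times (min).
#' @return A [timecourse()].
#' @export
make_timecourse <- function(component, context, x_reg = 0,
                            schedule = data.frame(time = 0, I = 0),
                            noise_level = 0.05, seed = 1,
                            times = seq(5, 360, by = 5)) {
  traj <- reporter_trajectory(component, context, times, x_reg, schedule)
  vals <- with_preserved_seed(seed, {
    pmax(traj$g * (1 + noise_level * stats::rnorm(length(times))), 0)
  })
  timecourse(times, vals, component_id = component$id, x_reg = x_reg,
             schedule = schedule)
}

#' Generate a design problem with a known (planted) optimum
#'
#' Builds a seeded candidate library and input device, then determines the
#' best {component, I2} pair by exhaustive evaluation on an inducer grid —
#' the planted optimum that a correct search must recover.  `spec` may be a
#' ready design spec, or the string `"amplifier"` / `"switch"`, in which
#' case the target response is derived from the noise-free transfer curve
#' of one library component (its secant line, or a Hill response anchored
#' at its high level and midpoint input), so that component is strongly
#' favoured.
#'
#' @param cfg A [fixture_config()].
#' @param spec A design spec, `"amplifier"` or `"switch"`.
#' @param n_I2 Number of inducer grid points.
#' @param I2_max Upper inducer bound (lower bound 0).
#' @param target_index Library component whose curve seeds the derived
#'   spec (string form only).
#' @return A list: `library`, `circuit_template`, `domain` (with the
#'   inducer grid), `spec`, and `planted` (`component_id`, `I2`, `J`).
#' @export
make_planted_design_problem <- function(cfg, spec = "amplifier", n_I2 = 20,
                                        I2_max = 10,
                                        target_index = NULL) {
  lib <- make_library(cfg, "repressor_regulated", inducer_name = "aTc")
  template <- make_circuit(cfg, fluctuations = no_fluctuations())
  I2_grid <- seq(0, I2_max, length.out = n_I2)
  domain <- search_domain(lib, 0, I2_max, I2_grid = I2_grid)

  if (is.character(spec)) {
    type <- match.arg(spec, c("amplifier", "switch"))
    if (is.null(target_index))
      target_index <- (length(lib$components) + 1L) %/% 2L
    target <- lib$components[[target_index]]
    rng <- .achievable_g1(template)
    g1_low <- rng[1L] + 0.15 * diff(rng)
    g1_high <- rng[1L] + 0.85 * diff(rng)
    probe <- transistor_circuit(template$c1, template$c2, target,
                                template$context, no_fluctuations())
    I1 <- .invert_g1(probe, c(g1_low, g1_high, (g1_low + g1_high) / 2))
    st <- .steady_core(.circuit_params(probe), probe$c2, probe$c3,
                       I1, I2_grid[1L])
    spec <- if (type == "amplifier") {
      slope <- (st$g2[2L] - st$g2[1L]) / (g1_high - g1_low)
      amplifier_spec(gain = slope, g1_low = g1_low, g1_high = g1_high,
                     g2_high = st$g2[1L])
    } else {
      H_s <- st$g2[1L]
      L_s <- max(st$g2[2L], 0)
      if (H_s <= L_s) H_s <- L_s + 1
      switch_spec(H_s = H_s, L_s = L_s, g_t = (g1_low + g1_high) / 2,
                  g1_low = g1_low, g1_high = g1_high)
    }
  }
  ref <- exhaustive_search(domain, template, spec, I2_grid = I2_grid)
  list(library = lib, circuit_template = template, domain = domain,
       spec = spec,
       planted = list(component_id = ref$component_id, I2 = ref$I2,
                      J = ref$J))
}
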