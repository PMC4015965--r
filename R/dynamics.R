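# Transistor-circuit dynamics: the six-species repressor cascade with
# reporter readouts, its closed-form steady state, the I/O characteristic,
# and the inducer-to-input-range map.

#' Shared cellular rate context
#'
#' Rates common to every species in the circuit: dilution by growth, specific
#' degradation of the two repressors and of the immature/mature reporters,
#' and reporter maturation.  Defaults describe exponentially growing
#' *E. coli* carrying stable fluorescent reporters: a ~35 min doubling time
#' (`mu = 0.02` min^-1), slow repressor turnover, and GFP/RFP-like
#' maturation around 20 min.
#'
#' @param mu Dilution rate from growth (min^-1).
#' @param gamma_repressor1,gamma_repressor2 Repressor degradation rates
#'   (min^-1).
#' @param gamma_im_x1,gamma_m_x1 Immature/mature input-reporter degradation
#'   rates (min^-1).
#' @param gamma_im_x2,gamma_m_x2 Immature/mature output-reporter degradation
#'   rates (min^-1).
#' @param m1,m2 Maturation rates of the input and output reporters (min^-1).
#' @return An object of class `cell_context`.
#' @export
cell_context <- function(mu = 0.02,
                         gamma_repressor1 = 0.01, gamma_repressor2 = 0.01,
                         gamma_im_x1 = 0.01, gamma_m_x1 = 0.004,
                         gamma_im_x2 = 0.01, gamma_m_x2 = 0.004,
                         m1 = 0.05, m2 = 0.05) {
  vals <- list(mu = mu,
               gamma_repressor1 = gamma_repressor1,
               gamma_repressor2 = gamma_repressor2,
               gamma_im_x1 = gamma_im_x1, gamma_m_x1 = gamma_m_x1,
               gamma_im_x2 = gamma_im_x2, gamma_m_x2 = gamma_m_x2,
               m1 = m1, m2 = m2)
  for (nm in names(vals)) check_scalar(vals[[nm]], nm, 0, strict = TRUE)
  structure(vals, class = "cell_context")
}

#' Stochastic parameter-fluctuation specification
#'
#' Kinetic strengths, degradation/maturation rates and the dilution rate are
#' treated as uncertain: each parameter p is perturbed to
#' `p + sd_frac * p * n(t)` where `n(t)` is a standard Gaussian shared within
#' a circuit branch (three independent sources: the constitutive input
#' branch, the c2 branch, the c3 branch).  `v_intensity` scales the six
#' additive white-noise disturbances of the dynamic model (a.u. min^-1);
#' `vs_scale` scales the additive steady-state disturbances per species.
#' An all-zero specification makes the model deterministic.
#'
#' @param sd_frac Fractional standard deviation applied to every perturbed
#'   parameter (dimensionless; 0.05 means 5% deviations).
#' @param v_intensity Additive disturbance intensity for the six dynamic
#'   noises, recycled to length 6.
#' @param vs_scale Additive steady-state disturbance scale per species,
#'   recycled to length 6.
#' @return An object of class `fluctuation_spec`.
#' @export
fluctuation_spec <- function(sd_frac = 0.05, v_intensity = 1, vs_scale = 0) {
  check_scalar(sd_frac, "sd_frac", 0)
  v_intensity <- rep_len(v_intensity, 6L)
  vs_scale <- rep_len(vs_scale, 6L)
  if (any(v_intensity < 0) || any(vs_scale < 0))
    gt_stop("noise intensities must be non-negative", "gt_argument_error")
  structure(list(sd_frac = sd_frac, v_intensity = v_intensity,
                 vs_scale = vs_scale),
            class = "fluctuation_spec")
}

#' @rdname fluctuation_spec
#' @export
no_fluctuations <- function() fluctuation_spec(0, 0, 0)

#' Assemble a genetic transistor circuit
#'
#' Wires the measured transistor: a constitutive component `c1` produces
#' repressor 1; `c2` (repressed by repressor 1, induced by I1) produces both
#' repressor 2 and the input reporter x1 (read out as fluorescence g1); `c3`
#' (repressed by repressor 2, induced by I2) produces the output reporter x2
#' (read out as g2).
#'
#' @param c1 Constitutive [prbs_component()].
#' @param c2,c3 Repressor-regulated [prbs_component()]s.
#' @param context A [cell_context()].
#' @param fluctuations A [fluctuation_spec()].
#' @return An object of class `transistor_circuit`.
#' @export
transistor_circuit <- function(c1, c2, c3, context = cell_context(),
                               fluctuations = fluctuation_spec()) {
  .check_class(c1, "constitutive", "transistor_circuit")
  .check_class(c2, "repressor_regulated", "transistor_circuit")
  .check_class(c3, "repressor_regulated", "transistor_circuit")
  if (!inherits(context, "cell_context"))
    gt_stop("`context` must be a cell_context", "gt_argument_error")
  if (!inherits(fluctuations, "fluctuation_spec"))
    gt_stop("`fluctuations` must be a fluctuation_spec", "gt_argument_error")
  structure(list(c1 = c1, c2 = c2, c3 = c3, context = context,
                 fluctuations = fluctuations),
            class = "transistor_circuit")
}

#' @export
print.transistor_circuit <- function(x, ...) {
  cat(sprintf("<transistor_circuit> c1 = %s, c2 = %s (%s), c3 = %s (%s)\n",
              x$c1$id, x$c2$id, x$c2$inducer_name,
              x$c3$id, x$c3$inducer_name))
  invisible(x)
}

.state_names <- c("x_repressor1", "x_repressor2", "x1", "g1", "x2", "g2")

# Flat parameter vector for one circuit realisation.
.circuit_params <- function(circuit) {
  ctx <- circuit$context
  c(Pc1 = circuit$c1$P_c,
    PM2 = circuit$c2$P_M, Pm2 = circuit$c2$P_m,
    PM3 = circuit$c3$P_M, Pm3 = circuit$c3$P_m,
    mu = ctx$mu,
    g_r1 = ctx$gamma_repressor1, g_r2 = ctx$gamma_repressor2,
    g_im1 = ctx$gamma_im_x1, g_m1 = ctx$gamma_m_x1,
    g_im2 = ctx$gamma_im_x2, g_m2 = ctx$gamma_m_x2,
    m1 = ctx$m1, m2 = ctx$m2)
}

# Branch membership of each perturbed parameter: source 1 perturbs the
# constitutive input branch, source 2 the c2 branch, source 3 the c3 branch.
.noise_group <- c(Pc1 = 1L, PM2 = 2L, Pm2 = 2L, PM3 = 3L, Pm3 = 3L,
                  mu = 1L, g_r1 = 1L, g_r2 = 2L,
                  g_im1 = 2L, g_m1 = 2L, g_im2 = 3L, g_m2 = 3L,
                  m1 = 2L, m2 = 3L)

# p -> p + sd_frac * p * n_group; negative excursions are clipped at 0 so
# rates stay physical.
.perturb_params <- function(p, sd_frac, n3) {
  pmax(p + sd_frac * p * n3[.noise_group[names(p)]], 0)
}

# Closed-form steady state of the cascade for a flat parameter vector,
# vectorised over I1 (and I2 of the same length or scalar).
.steady_core <- function(p, c2, c3, I1, I2) {
  x_r1 <- p[["Pc1"]] / (p[["mu"]] + p[["g_r1"]])
  pr2 <- hill_repression(p[["PM2"]], p[["Pm2"]], x_r1, I1,
                         c2$K_tf, c2$n_tf, c2$K_I, c2$n_I)
  x_r2 <- pr2 / (p[["mu"]] + p[["g_r2"]])
  x1 <- pr2 / (p[["m1"]] + p[["mu"]] + p[["g_im1"]])
  g1 <- p[["m1"]] * x1 / (p[["mu"]] + p[["g_m1"]])
  pr3 <- hill_repression(p[["PM3"]], p[["Pm3"]], x_r2, I2,
                         c3$K_tf, c3$n_tf, c3$K_I, c3$n_I)
  x2 <- pr3 / (p[["m2"]] + p[["mu"]] + p[["g_im2"]])
  g2 <- p[["m2"]] * x2 / (p[["mu"]] + p[["g_m2"]])
  list(x_repressor1 = rep_len(x_r1, length(g1)), x_repressor2 = x_r2,
       x1 = x1, g1 = g1, x2 = x2, g2 = g2)
}

#' Closed-form steady state of the transistor circuit
#'
#' Evaluates the six steady-state expressions of the cascade in order:
#' repressor 1, repressor 2, immature and mature input reporter, immature
#' and mature output reporter.  With `noise = TRUE`, one Gaussian draw per
#' branch perturbs the kinetic parameters (fractional deviations from the
#' circuit's [fluctuation_spec()]) and one additive Gaussian disturbance per
#' species is added; the result is clipped at zero.
#'
#' @param circuit A [transistor_circuit()].
#' @param I1 Inducer-1 concentration (input device), `>= 0`.
#' @param I2 Inducer-2 concentration (output stage), `>= 0`.
#' @param noise Apply the stochastic parameter/state perturbations?
#' @param seed Integer seed making the noisy evaluation reproducible; the
#'   caller's RNG stream is preserved.
#' @return A named numeric vector of class `circuit_state` with elements
#'   `x_repressor1`, `x_repressor2`, `x1`, `g1`, `x2`, `g2` (a.u.).
#' @export
steady_state <- function(circuit, I1, I2, noise = FALSE, seed = NULL) {
  check_scalar(I1, "I1", 0)
  check_scalar(I2, "I2", 0)
  p <- .circuit_params(circuit)
  if (!all(is.finite(p)))
    gt_stop(paste0("non-finite circuit parameters: ",
                   paste(sprintf("%s=%g", names(p), p), collapse = ", ")),
            "gt_numeric_error")
  st <- if (noise) {
    spec <- circuit$fluctuations
    with_preserved_seed(seed, {
      pp <- .perturb_params(p, spec$sd_frac, stats::rnorm(3))
      s <- .steady_core(pp, circuit$c2, circuit$c3, I1, I2)
      vs <- spec$vs_scale * stats::rnorm(6)
      lapply(seq_along(s), function(i) pmax(s[[i]] + vs[i], 0))
    })
  } else {
    .steady_core(p, circuit$c2, circuit$c3, I1, I2)
  }
  out <- unlist(st, use.names = FALSE)
  names(out) <- .state_names
  structure(out, class = "circuit_state")
}

#' @export
print.circuit_state <- function(x, ...) {
  cat("<circuit_state> (a.u.)\n")
  print(round(unclass(x), 4))
  invisible(x)
}

.deriv_core <- function(s, p, c2, c3, I1, I2) {
  pr2 <- hill_repression(p[["PM2"]], p[["Pm2"]], s[1L], I1,
                         c2$K_tf, c2$n_tf, c2$K_I, c2$n_I)
  pr3 <- hill_repression(p[["PM3"]], p[["Pm3"]], s[2L], I2,
                         c3$K_tf, c3$n_tf, c3$K_I, c3$n_I)
  c(p[["Pc1"]] - (p[["mu"]] + p[["g_r1"]]) * s[1L],
    pr2 - (p[["mu"]] + p[["g_r2"]]) * s[2L],
    pr2 - (p[["m1"]] + p[["mu"]] + p[["g_im1"]]) * s[3L],
    p[["m1"]] * s[3L] - (p[["mu"]] + p[["g_m1"]]) * s[4L],
    pr3 - (p[["m2"]] + p[["mu"]] + p[["g_im2"]]) * s[5L],
    p[["m2"]] * s[5L] - (p[["mu"]] + p[["g_m2"]]) * s[6L])
}

#' Simulate the transistor circuit dynamics
#'
#' Integrates the six-species cascade.  Noise-free runs use the adaptive
#' stiff-capable `deSolve::lsoda` integrator; stochastic runs use a
#' fixed-step Euler-Maruyama scheme in which the perturbed parameters of the
#' fluctuation model are resampled every step (scaled by `1/sqrt(dt)` so the
#' accumulated perturbation variance is step-size consistent) and the six
#' additive disturbances enter as independent Wiener increments.  States are
#' clipped at zero after every stochastic step.
#'
#' @inheritParams steady_state
#' @param t_span Total simulated time (min), `> 0`.
#' @param dt Output (and stochastic step) interval (min), `> 0`; default
#'   0.1 min for stochastic runs.
#' @param init Optional initial state, a numeric vector of length 6 in the
#'   order `x_repressor1, x_repressor2, x1, g1, x2, g2`; defaults to zeros.
#' @return A data frame: column `time` (min) plus the six state columns.
#' @export
simulate_dynamics <- function(circuit, I1, I2, t_span, dt = 0.1,
                              noise = FALSE, seed = NULL, init = NULL) {
  check_scalar(I1, "I1", 0)
  check_scalar(I2, "I2", 0)
  check_scalar(t_span, "t_span", 0, strict = TRUE)
  check_scalar(dt, "dt", 0, strict = TRUE)
  p <- .circuit_params(circuit)
  c2 <- circuit$c2; c3 <- circuit$c3
  if (is.null(init)) init <- numeric(6L)
  if (length(init) != 6L || any(!is.finite(init)) || any(init < 0))
    gt_stop("`init` must be 6 finite non-negative states", "gt_argument_error")
  times <- seq(0, t_span, by = dt)

  # an all-zero fluctuation spec makes the model deterministic
  spec <- circuit$fluctuations
  if (noise && spec$sd_frac == 0 && all(spec$v_intensity == 0))
    noise <- FALSE

  if (!noise) {
    rhs <- function(t, s, parms) list(.deriv_core(s, p, c2, c3, I1, I2))
    sol <- deSolve::lsoda(y = stats::setNames(init, .state_names),
                          times = times, func = rhs, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    out <- as.data.frame(sol)
    names(out)[1L] <- "time"
    return(out)
  }

  with_preserved_seed(seed, {
    n_steps <- length(times) - 1L
    out <- matrix(NA_real_, nrow = length(times), ncol = 6L,
                  dimnames = list(NULL, .state_names))
    s <- init
    out[1L, ] <- s
    sq <- sqrt(dt)
    for (k in seq_len(n_steps)) {
      # parameter white noise enters the drift as p + sd*p*n/sqrt(dt), i.e.
      # a Delta_p dW contribution after multiplying by dt
      pp <- .perturb_params(p, spec$sd_frac / sq, stats::rnorm(3))
      drift <- .deriv_core(s, pp, c2, c3, I1, I2)
      s <- s + drift * dt + spec$v_intensity * sq * stats::rnorm(6)
      if (any(!is.finite(s)))
        gt_stop(sprintf("non-finite state at t = %g; try a smaller dt",
                        times[k + 1L]), "gt_numeric_error")
      s <- pmax(s, 0)
      out[k + 1L, ] <- s
    }
    data.frame(time = times, out)
  })
}

#' Steady-state input/output characteristic
#'
#' Samples the transfer curve `(g1, g2)` of the transistor over a grid of
#' input-inducer concentrations at fixed `I2`.  With noise, each grid point
#' reports the mean over `n_mc` seeded realisations of the fluctuation
#' model.  Noise-free curves are strictly increasing in `g1` and
#' non-increasing in `g2` (the repressive cascade inverts).
#'
#' @inheritParams steady_state
#' @param I1_grid Non-empty, sorted vector of inducer-1 concentrations.
#' @param n_mc Number of Monte-Carlo realisations per grid point when
#'   `noise = TRUE`.
#' @return A data frame of class `io_response` with columns `I1`, `g1`,
#'   `g2`; attributes `I2`, `circuit_ids`, `noise`, `n_mc`.
#' @export
io_response <- function(circuit, I1_grid, I2, noise = FALSE, n_mc = 1,
                        seed = NULL) {
  if (length(I1_grid) == 0L)
    gt_stop("`I1_grid` must be non-empty", "gt_argument_error")
  if (is.unsorted(I1_grid) || any(I1_grid < 0))
    gt_stop("`I1_grid` must be sorted and non-negative", "gt_argument_error")
  check_scalar(I2, "I2", 0)
  p <- .circuit_params(circuit)
  if (!noise) {
    st <- .steady_core(p, circuit$c2, circuit$c3, I1_grid, I2)
    g1 <- st$g1; g2 <- st$g2
  } else {
    spec <- circuit$fluctuations
    acc <- with_preserved_seed(seed, {
      reps <- lapply(seq_len(n_mc), function(r) {
        pp <- .perturb_params(p, spec$sd_frac, stats::rnorm(3))
        st <- .steady_core(pp, circuit$c2, circuit$c3, I1_grid, I2)
        vs4 <- spec$vs_scale[4L] * stats::rnorm(length(I1_grid))
        vs6 <- spec$vs_scale[6L] * stats::rnorm(length(I1_grid))
        cbind(pmax(st$g1 + vs4, 0), pmax(st$g2 + vs6, 0))
      })
      Reduce(`+`, reps) / n_mc
    })
    g1 <- acc[, 1L]; g2 <- acc[, 2L]
  }
  structure(data.frame(I1 = I1_grid, g1 = g1, g2 = g2),
            class = c("io_response", "data.frame"),
            I2 = I2,
            circuit_ids = c(c1 = circuit$c1$id, c2 = circuit$c2$id,
                            c3 = circuit$c3$id),
            noise = noise, n_mc = if (noise) n_mc else 0L)
}

#' Map an inducer interval to the input-fluorescence operation range
#'
#' Evaluates the noise-free steady-state input fluorescence `g1` at the two
#' inducer-1 bounds: the input device maps `I1` monotonically to `g1`, so
#' the image of `[I1_low, I1_high]` is `[g1_low, g1_high]`.
#'
#' @inheritParams steady_state
#' @param I1_low,I1_high Inducer-1 bounds, `0 <= I1_low <= I1_high`
#'   (`Inf` allowed for the upper bound).
#' @return Named numeric vector `c(g1_low, g1_high)` (a.u.).
#' @export
input_range_map <- function(circuit, I1_low, I1_high) {
  if (!is.numeric(I1_low) || !is.numeric(I1_high) ||
      length(I1_low) != 1L || length(I1_high) != 1L ||
      is.na(I1_low) || is.na(I1_high) || I1_low < 0 || I1_low > I1_high)
    gt_stop("need 0 <= I1_low <= I1_high", "gt_argument_error")
  p <- .circuit_params(circuit)
  st <- .steady_core(p, circuit$c2, circuit$c3, c(I1_low, I1_high), 0)
  c(g1_low = st$g1[1L], g1_high = st$g1[2L])
}
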