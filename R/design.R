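# Design specifications (amplifier / switch), the Monte-Carlo cost
# functional, the GA search over {c3, I2}, and the look-up-table builder.

#' Amplifier design specification
#'
#' A linear inverting-amplifier target response
#' `y_d(g1) = gain * (g1 - g1_low) + g2_high` on the input operation range
#' `[g1_low, g1_high]`: the output starts at `g2_high` at the lower input
#' bound and falls with slope `gain` (negative for the inverting cascade).
#'
#' @param gain Desired amplification gain (slope, a.u./a.u.), `< 0`.
#' @param g1_low,g1_high Input operation range (a.u.), `g1_low < g1_high`.
#' @param g2_high Output level at `g1_low` (a.u.).
#' @return An object of class `c("amplifier_spec", "design_spec")`.
#' @export
amplifier_spec <- function(gain, g1_low, g1_high, g2_high) {
  check_scalar(gain, "gain")
  if (gain >= 0)
    gt_stop("`gain` must be negative for the inverting transistor",
            "gt_argument_error")
  check_scalar(g1_low, "g1_low", 0)
  check_scalar(g1_high, "g1_high", 0)
  if (g1_low >= g1_high)
    gt_stop("need g1_low < g1_high", "gt_argument_error")
  check_scalar(g2_high, "g2_high", 0)
  structure(list(gain = gain, g1_low = g1_low, g1_high = g1_high,
                 g2_high = g2_high),
            class = c("amplifier_spec", "design_spec"))
}

#' Switch design specification
#'
#' A sigmoidal switching target response
#' `y_d(g1) = L_s + (H_s - L_s) / (1 + (g1/g_t)^hill_order)`: output `H_s`
#' at zero input, `L_s` at saturating input, crossing the midpoint at the
#' transition input `g_t`.
#'
#' @param H_s High output level (a.u.), `> L_s`.
#' @param L_s Low output level (a.u.), `>= 0`.
#' @param g_t Transition-point input fluorescence (a.u.), `> 0`.
#' @param hill_order Steepness exponent of the response (default 2).
#' @param g1_low,g1_high Evaluation range (a.u.).
#' @return An object of class `c("switch_spec", "design_spec")`.
#' @export
switch_spec <- function(H_s, L_s, g_t, hill_order = 2,
                        g1_low = 0, g1_high = 4 * g_t) {
  check_scalar(H_s, "H_s", 0, strict = TRUE)
  check_scalar(L_s, "L_s", 0)
  if (H_s <= L_s) gt_stop("need H_s > L_s", "gt_argument_error")
  check_scalar(g_t, "g_t", 0, strict = TRUE)
  check_scalar(hill_order, "hill_order", 0, strict = TRUE)
  check_scalar(g1_low, "g1_low", 0)
  check_scalar(g1_high, "g1_high", 0)
  if (g1_low >= g1_high)
    gt_stop("need g1_low < g1_high", "gt_argument_error")
  structure(list(H_s = H_s, L_s = L_s, g_t = g_t, hill_order = hill_order,
                 g1_low = g1_low, g1_high = g1_high),
            class = c("switch_spec", "design_spec"))
}

#' Desired I/O response function of a design specification
#'
#' Returns the target response `y_d(g1)` as an R function.  Amplifier specs
#' evaluate only inside their input operation range; switch specs accept any
#' non-negative input.
#'
#' @param spec An [amplifier_spec()] or [switch_spec()].
#' @return A vectorised function of `g1` returning `y_d` (a.u.).
#' @export
desired_response <- function(spec) {
  UseMethod("desired_response")
}

#' @export
desired_response.amplifier_spec <- function(spec) {
  force(spec)
  function(g1) {
    tol <- 1e-9 * max(1, spec$g1_high)
    if (any(g1 < spec$g1_low - tol) || any(g1 > spec$g1_high + tol))
      gt_stop(sprintf("g1 outside the input operation range [%g, %g]",
                      spec$g1_low, spec$g1_high), "gt_domain_error")
    spec$gain * (g1 - spec$g1_low) + spec$g2_high
  }
}

#' @export
desired_response.switch_spec <- function(spec) {
  force(spec)
  function(g1) {
    if (any(g1 < 0))
      gt_stop("g1 must be non-negative", "gt_domain_error")
    spec$L_s + (spec$H_s - spec$L_s) / (1 + (g1 / spec$g_t)^spec$hill_order)
  }
}

#' Search domain for the output stage
#'
#' The discrete-continuous design space: candidate repressor-regulated
#' components for `c3` and an inducer-2 concentration interval, optionally
#' restricted to a finite grid of admissible concentrations.
#'
#' @param library A repressor-regulated [prbs_library()] of `c3` candidates.
#' @param I2_low,I2_high Inducer-2 bounds (inducer units),
#'   `0 <= I2_low <= I2_high`.
#' @param I2_grid Optional sorted vector of admissible concentrations; when
#'   given, searches snap `I2` to its values.
#' @return An object of class `search_domain`.
#' @export
search_domain <- function(library, I2_low, I2_high, I2_grid = NULL) {
  if (!inherits(library, "prbs_library"))
    gt_stop("`library` must be a prbs_library", "gt_argument_error")
  cls <- library$components[[1L]]$regulation_class
  if (cls != "repressor_regulated")
    gt_stop("the c3 candidate library must be repressor-regulated",
            "gt_class_mismatch")
  check_scalar(I2_low, "I2_low", 0)
  check_scalar(I2_high, "I2_high", 0)
  if (I2_low > I2_high)
    gt_stop("need I2_low <= I2_high", "gt_argument_error")
  if (!is.null(I2_grid)) {
    if (length(I2_grid) == 0L || is.unsorted(I2_grid) || any(I2_grid < 0))
      gt_stop("`I2_grid` must be sorted and non-negative", "gt_argument_error")
  }
  structure(list(library = library, I2_low = I2_low, I2_high = I2_high,
                 I2_grid = I2_grid),
            class = "search_domain")
}

#' Genetic-algorithm configuration
#'
#' @param pop_size Population size (`>= 2`).
#' @param generations Number of generations.
#' @param p_crossover Crossover probability in `[0, 1]`.
#' @param p_mutation Per-offspring mutation probability in `[0, 1]`.
#' @param elitism Number of best individuals copied unchanged (`>= 1`
#'   guarantees the best-so-far cost never increases).
#' @param seed RNG seed for the whole search.
#' @param I2_scale `"linear"` or `"log"` encoding of the inducer axis.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 40, generations = 60, p_crossover = 0.8,
                      p_mutation = 0.2, elitism = 2, seed = 1,
                      I2_scale = c("linear", "log")) {
  I2_scale <- match.arg(I2_scale)
  check_scalar(pop_size, "pop_size", 2)
  check_scalar(generations, "generations", 1)
  check_scalar(p_crossover, "p_crossover", 0)
  check_scalar(p_mutation, "p_mutation", 0)
  if (p_crossover > 1 || p_mutation > 1)
    gt_stop("rates must lie in [0, 1]", "gt_argument_error")
  check_scalar(elitism, "elitism", 0)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = as.integer(elitism), seed = seed,
                 I2_scale = I2_scale),
            class = "ga_config")
}

# Achievable g1 interval of the input device (I1 from 0 to saturation).
.achievable_g1 <- function(circuit) {
  unname(input_range_map(circuit, 0, Inf))
}

# Exact inversion of the noise-free map g1 -> I1 for the input device.
# Errors with class gt_infeasible when a requested g1 is outside the
# achievable interval.
.invert_g1 <- function(circuit, g1) {
  p <- .circuit_params(circuit)
  c2 <- circuit$c2
  rng <- .achievable_g1(circuit)
  tol <- 1e-9 * max(1, rng[2L])
  if (any(g1 < rng[1L] - tol) || any(g1 > rng[2L] + tol))
    gt_stop(sprintf(
      "requested input range is not reachable; the input device achieves g1 in [%.6g, %.6g] a.u.",
      rng[1L], rng[2L]), "gt_infeasible")
  # g1 = (m1 / (mu + g_m1)) * p2 / (m1 + mu + g_im1)  =>  p2 target
  scale <- p[["m1"]] / ((p[["mu"]] + p[["g_m1"]]) *
                          (p[["m1"]] + p[["mu"]] + p[["g_im1"]]))
  p2 <- g1 / scale
  x_r1 <- p[["Pc1"]] / (p[["mu"]] + p[["g_r1"]])
  # p2 = Pm + (PM - Pm) / (1 + (x_free/K)^n)  =>  x_free, then I1
  frac <- (c2$P_M - p2) / pmax(p2 - c2$P_m, .Machine$double.xmin)
  frac <- pmax(frac, 0)
  x_free <- c2$K_tf * frac^(1 / c2$n_tf)
  ratio <- pmax(x_r1 / pmax(x_free, .Machine$double.xmin) - 1, 0)
  I1 <- c2$K_I * ratio^(1 / c2$n_I)
  pmin(I1, .Machine$double.xmax)
}

# One realisation of the integrated squared deviation (trapezoidal rule).
.integrate_sq_dev <- function(y, yd, g1) {
  trapz(g1, (y - yd)^2)
}

#' Monte-Carlo cost of a candidate design
#'
#' Builds the circuit with the candidate output component and inducer
#' concentration and computes the expected integrated squared deviation
#' between the achieved steady-state I/O response and the desired response
#' over the spec's input range: `E \int (y_ss(g1) - y_d(g1))^2 dg1`.  The
#' `g1` quadrature grid is uniform and mapped back to `I1` by exact
#' inversion of the noise-free input device; the integral uses the
#' trapezoidal rule; the expectation over the fluctuation model is a seeded
#' Monte-Carlo mean (one parameter draw per realisation).
#'
#' @param circuit_template A [transistor_circuit()] providing `c1`, `c2`,
#'   the context and the fluctuation spec.
#' @param c3_candidate Candidate repressor-regulated [prbs_component()].
#' @param I2 Inducer-2 concentration.
#' @param spec An [amplifier_spec()] or [switch_spec()].
#' @param quadrature_points Number of `g1` grid points (default 33).
#' @param n_mc Monte-Carlo sample count (1 with `noise = FALSE`).
#' @param noise Average over the fluctuation model?
#' @param seed Seed for the Monte-Carlo draws.
#' @return A list of class `cost_value`: `J`, `n_mc`, `se` (standard error
#'   of the mean; 0 when deterministic).
#' @export
design_cost <- function(circuit_template, c3_candidate, I2, spec,
                        quadrature_points = 33, n_mc = 1, noise = FALSE,
                        seed = NULL) {
  .check_class(c3_candidate, "repressor_regulated", "design_cost")
  check_scalar(I2, "I2", 0)
  if (!inherits(spec, "design_spec"))
    gt_stop("`spec` must be a design spec", "gt_argument_error")
  circuit <- transistor_circuit(circuit_template$c1, circuit_template$c2,
                                c3_candidate, circuit_template$context,
                                circuit_template$fluctuations)
  g1_grid <- seq(spec$g1_low, spec$g1_high, length.out = quadrature_points)
  I1_grid <- .invert_g1(circuit, g1_grid)
  yd <- desired_response(spec)(g1_grid)
  p <- .circuit_params(circuit)
  if (!noise) {
    st <- .steady_core(p, circuit$c2, circuit$c3, I1_grid, I2)
    J <- .integrate_sq_dev(st$g2, yd, g1_grid)
    out <- list(J = J, n_mc = 1L, se = 0)
  } else {
    spec_f <- circuit$fluctuations
    Js <- with_preserved_seed(seed, {
      vapply(seq_len(n_mc), function(r) {
        pp <- .perturb_params(p, spec_f$sd_frac, stats::rnorm(3))
        st <- .steady_core(pp, circuit$c2, circuit$c3, I1_grid, I2)
        vs6 <- spec_f$vs_scale[6L] * stats::rnorm(length(I1_grid))
        .integrate_sq_dev(pmax(st$g2 + vs6, 0), yd, g1_grid)
      }, numeric(1))
    })
    out <- list(J = mean(Js), n_mc = as.integer(n_mc),
                se = stats::sd(Js) / sqrt(n_mc))
  }
  structure(out, class = "cost_value")
}

.decode_I2 <- function(u, domain, scale) {
  if (!is.null(domain$I2_grid)) {
    grid <- domain$I2_grid
    return(grid[pmin(pmax(1L, as.integer(round(u * (length(grid) - 1L))) + 1L),
                     length(grid))])
  }
  lo <- domain$I2_low; hi <- domain$I2_high
  if (scale == "log") {
    lo0 <- max(lo, 1e-12 * max(hi, 1))
    exp(log(lo0) + u * (log(hi) - log(lo0)))
  } else {
    lo + u * (hi - lo)
  }
}

#' Genetic-algorithm search for the best {c3, I2} design
#'
#' Minimises the design cost over the mixed discrete-continuous space of a
#' [search_domain()]: each chromosome is a (component index, encoded
#' inducer) pair, evolved by tournament selection, blend crossover on the
#' inducer coordinate, uniform component mutation and Gaussian inducer
#' mutation, with elitism.  Seeded runs are reproducible; with noise, all
#' candidates within a generation share common random numbers.
#'
#' @inheritParams design_cost
#' @param domain A [search_domain()].
#' @param config A [ga_config()].
#' @return A list of class `ga_result`: `component` (the selected
#'   [prbs_component()]), `component_id`, `I2`, `J`, `se`, `history`
#'   (best-so-far cost per generation), `evaluations`.
#' @export
ga_search <- function(domain, circuit_template, spec, config = ga_config(),
                      noise = FALSE, n_mc = 1, quadrature_points = 33) {
  if (!inherits(domain, "search_domain"))
    gt_stop("`domain` must be a search_domain", "gt_argument_error")
  comps <- domain$library$components
  n_comp <- length(comps)
  if (n_comp == 0L) gt_stop("empty candidate library", "gt_argument_error")

  # feasibility of the spec range under the input device, checked once
  invisible(.invert_g1(
    transistor_circuit(circuit_template$c1, circuit_template$c2, comps[[1L]],
                       circuit_template$context,
                       circuit_template$fluctuations),
    c(spec$g1_low, spec$g1_high)))

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_cost <- function(idx, I2, gen_seed) {
    key <- sprintf("%d|%.12g", idx, I2)
    if (!noise && !is.null(cache[[key]])) return(cache[[key]])
    cv <- design_cost(circuit_template, comps[[idx]], I2, spec,
                      quadrature_points = quadrature_points,
                      n_mc = if (noise) n_mc else 1L, noise = noise,
                      seed = gen_seed)
    n_eval <<- n_eval + 1L
    res <- c(cv$J, cv$se)
    if (!noise) cache[[key]] <- res
    res
  }

  # singleton domain: nothing to search
  grid1 <- !is.null(domain$I2_grid) && length(domain$I2_grid) == 1L
  if (n_comp == 1L && (grid1 || domain$I2_low == domain$I2_high)) {
    I2 <- if (grid1) domain$I2_grid[1L] else domain$I2_low
    jv <- eval_cost(1L, I2, config$seed)
    return(structure(list(component = comps[[1L]],
                          component_id = names(comps)[1L],
                          I2 = I2, J = jv[1L], se = jv[2L],
                          history = rep(jv[1L], config$generations),
                          evaluations = n_eval),
                     class = "ga_result"))
  }

  with_preserved_seed(config$seed, {
    pop_idx <- sample.int(n_comp, config$pop_size, replace = TRUE)
    pop_u <- stats::runif(config$pop_size)
    best <- list(J = Inf, se = 0, idx = NA_integer_, I2 = NA_real_)
    history <- numeric(config$generations)

    for (gen in seq_len(config$generations)) {
      gen_seed <- if (noise) config$seed + 7919L * gen else NULL
      I2s <- .decode_I2(pop_u, domain, config$I2_scale)
      fit <- matrix(NA_real_, nrow = config$pop_size, ncol = 2L)
      for (i in seq_len(config$pop_size))
        fit[i, ] <- eval_cost(pop_idx[i], I2s[i], gen_seed)
      ord <- order(fit[, 1L])
      if (fit[ord[1L], 1L] < best$J)
        best <- list(J = fit[ord[1L], 1L], se = fit[ord[1L], 2L],
                     idx = pop_idx[ord[1L]], I2 = I2s[ord[1L]])
      history[gen] <- best$J
      if (gen == config$generations) break

      # tournament selection (size 2)
      pick <- function() {
        a <- sample.int(config$pop_size, 2L)
        if (fit[a[1L], 1L] <= fit[a[2L], 1L]) a[1L] else a[2L]
      }
      n_child <- config$pop_size - config$elitism
      child_idx <- integer(n_child)
      child_u <- numeric(n_child)
      k <- 1L
      while (k <= n_child) {
        pa <- pick(); pb <- pick()
        ia <- pop_idx[pa]; ib <- pop_idx[pb]
        ua <- pop_u[pa]; ub <- pop_u[pb]
        if (stats::runif(1) < config$p_crossover) {
          if (stats::runif(1) < 0.5) { tmp <- ia; ia <- ib; ib <- tmp }
          alpha <- stats::runif(1)
          ua2 <- alpha * ua + (1 - alpha) * ub
          ub <- alpha * ub + (1 - alpha) * ua
          ua <- ua2
        }
        for (child in list(c(ia, ua), c(ib, ub))) {
          if (k > n_child) break
          ci <- as.integer(child[1L]); cu <- child[2L]
          if (stats::runif(1) < config$p_mutation)
            ci <- sample.int(n_comp, 1L)
          if (stats::runif(1) < config$p_mutation)
            cu <- min(max(cu + stats::rnorm(1, sd = 0.15), 0), 1)
          child_idx[k] <- ci; child_u[k] <- cu
          k <- k + 1L
        }
      }
      elite <- ord[seq_len(config$elitism)]
      pop_idx <- c(pop_idx[elite], child_idx)
      pop_u <- c(pop_u[elite], child_u)
    }

    # re-encode the best individual's I2 exactly (grid snap already applied)
    structure(list(component = comps[[best$idx]],
                   component_id = names(comps)[best$idx],
                   I2 = best$I2, J = best$J, se = best$se,
                   history = history, evaluations = n_eval),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> c3 = %s, I2 = %g, J = %.6g (se %.3g), %d cost evaluations\n",
              x$component_id, x$I2, x$J, x$se, x$evaluations))
  invisible(x)
}

#' Exhaustive search over a finite design grid
#'
#' Independent brute-force reference for [ga_search()]: evaluates the cost
#' for every (component, I2) pair on a finite inducer grid and returns the
#' minimiser together with the full cost table.
#'
#' @inheritParams ga_search
#' @param I2_grid Inducer grid; defaults to the domain's grid or 20 points
#'   spanning `[I2_low, I2_high]`.
#' @param seed Seed for noisy evaluations (common random numbers across
#'   candidates).
#' @return A list: `component_id`, `I2`, `J`, and `table` (a data frame of
#'   all evaluated candidates).
#' @export
exhaustive_search <- function(domain, circuit_template, spec,
                              I2_grid = NULL, noise = FALSE, n_mc = 1,
                              quadrature_points = 33, seed = NULL) {
  comps <- domain$library$components
  if (is.null(I2_grid))
    I2_grid <- domain$I2_grid %||%
      seq(domain$I2_low, domain$I2_high, length.out = 20L)
  tab <- expand.grid(component_id = names(comps), I2 = I2_grid,
                     stringsAsFactors = FALSE)
  tab$J <- mapply(function(id, I2) {
    design_cost(circuit_template, comps[[id]], I2, spec,
                quadrature_points = quadrature_points,
                n_mc = n_mc, noise = noise, seed = seed)$J
  }, tab$component_id, tab$I2)
  k <- which.min(tab$J)
  list(component_id = tab$component_id[k], I2 = tab$I2[k], J = tab$J[k],
       table = tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.spec_summary <- function(spec) {
  if (inherits(spec, "amplifier_spec")) {
    list(range = c(spec$g1_low, spec$g1_high),
         label = sprintf("gain=%g", spec$gain))
  } else {
    list(range = c(spec$g1_low, spec$g1_high),
         label = sprintf("H=%g,L=%g,gt=%g", spec$H_s, spec$L_s, spec$g_t))
  }
}

#' Build a design look-up table
#'
#' Runs one GA search per design specification and collects the selected
#' {component, inducer concentration} pairs into a look-up table, one row
#' per spec.  Infeasible specs (input range not reachable by the input
#' device) produce a row with `NA` selections instead of failing the whole
#' table.
#'
#' @inheritParams ga_search
#' @param specs Non-empty list of design specs ([amplifier_spec()] /
#'   [switch_spec()]).
#' @return A data frame of class `lookup_table` with columns
#'   `input_range_low`, `input_range_high`, `gain_or_levels`, `component`,
#'   `inducer_concentration`, `units`, `J`.
#' @export
build_lookup_table <- function(domain, circuit_template, specs,
                               config = ga_config(), noise = FALSE,
                               n_mc = 1, quadrature_points = 33) {
  if (!is.list(specs) || length(specs) == 0L ||
      inherits(specs, "design_spec"))
    gt_stop("`specs` must be a non-empty list of design specs",
            "gt_argument_error")
  units <- domain$library$components[[1L]]$inducer_name
  rows <- lapply(specs, function(sp) {
    info <- .spec_summary(sp)
    res <- tryCatch(
      ga_search(domain, circuit_template, sp, config, noise = noise,
                n_mc = n_mc, quadrature_points = quadrature_points),
      gt_infeasible = function(e) NULL)
    if (is.null(res)) {
      data.frame(input_range_low = info$range[1L],
                 input_range_high = info$range[2L],
                 gain_or_levels = info$label,
                 component = NA_character_,
                 inducer_concentration = NA_real_,
                 units = units, J = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(input_range_low = info$range[1L],
                 input_range_high = info$range[2L],
                 gain_or_levels = info$label,
                 component = res$component_id,
                 inducer_concentration = res$I2,
                 units = units, J = res$J,
                 stringsAsFactors = FALSE)
    }
  })
  structure(do.call(rbind, rows), class = c("lookup_table", "data.frame"))
}

#' Write a look-up table as TSV
#'
#' @param table A `lookup_table` from [build_lookup_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lookup_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a design specification from a JSON config file
#'
#' The file carries a `type` discriminator (`"amplifier"` or `"switch"`)
#' plus the fields of the corresponding spec constructor; a top-level JSON
#' array yields a list of specs.
#'
#' @param path JSON file path.
#' @return A single design spec or a list of them.
#' @export
read_design_spec <- function(path) {
  if (!file.exists(path))
    gt_stop(sprintf("spec file not found: %s", path), "gt_parse_error")
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    gt_stop(sprintf("malformed spec JSON: %s",
                                    conditionMessage(e)), "gt_parse_error"))
  build <- function(x) {
    ty <- x$type
    if (is.null(ty)) gt_stop("spec needs a `type` field", "gt_parse_error")
    x$type <- NULL
    switch(ty,
           amplifier = do.call(amplifier_spec, x),
           switch = do.call(switch_spec, x),
           gt_stop(sprintf("unknown spec type '%s'", ty), "gt_parse_error"))
  }
  if (!is.null(raw$type)) build(raw) else lapply(raw, build)
}
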