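# Nonlinear least-squares identification of promoter-RBS kinetic strengths
# from reporter fluorescence time courses.

#' Construct a fluorescence time course
#'
#' @param times Sampling times (min), strictly increasing.
#' @param values Fluorescence values (a.u.), `>= 0`, same length as `times`.
#' @param replicate Replicate id.
#' @param component_id Optional label of the measured component.
#' @param x_reg Regulator concentration held constant during the
#'   measurement (a.u.; ignored for constitutive components).
#' @param schedule Inducer schedule, a data frame with columns `time` and
#'   `I`: `I[k]` holds from `time[k]` until the next entry.
#' @return A data frame of class `timecourse` with columns `time_min`,
#'   `fluorescence_au`, `replicate`, carrying the metadata as attributes.
#' @export
timecourse <- function(times, values, replicate = 1L, component_id = NULL,
                       x_reg = 0, schedule = data.frame(time = 0, I = 0)) {
  if (length(times) != length(values))
    gt_stop("`times` and `values` must have equal length", "gt_argument_error")
  if (length(times) < 2L || any(diff(times) <= 0))
    gt_stop("`times` must be strictly increasing", "gt_argument_error")
  if (any(!is.finite(values)) || any(values < 0))
    gt_stop("`values` must be finite and non-negative", "gt_argument_error")
  .check_schedule(schedule)
  structure(data.frame(time_min = times, fluorescence_au = values,
                       replicate = replicate),
            class = c("timecourse", "data.frame"),
            component_id = component_id, x_reg = x_reg, schedule = schedule)
}

.check_schedule <- function(schedule) {
  if (!is.data.frame(schedule) || !all(c("time", "I") %in% names(schedule)) ||
      nrow(schedule) == 0L || any(diff(schedule$time) <= 0) ||
      any(schedule$I < 0) || schedule$time[1L] > 0)
    gt_stop("`schedule` must be a data.frame(time, I) starting at time <= 0 with increasing times and I >= 0",
            "gt_argument_error")
  invisible(schedule)
}

#' Read / write time courses as CSV
#'
#' Columns: `time_min`, `fluorescence_au`, `replicate`.  A JSON metadata
#' sidecar `<path>.meta.json` stores the component id, regulator level and
#' inducer schedule; it is read back when present.
#'
#' @param path CSV file path.
#' @return `read_timecourse()` returns a [timecourse()].
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path))
    gt_stop(sprintf("time-course file not found: %s", path), "gt_parse_error")
  df <- utils::read.csv(path)
  need <- c("time_min", "fluorescence_au")
  if (!all(need %in% names(df)))
    gt_stop("time-course CSV needs columns time_min, fluorescence_au",
            "gt_parse_error")
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  schedule <- if (!is.null(meta$schedule))
    as.data.frame(meta$schedule) else data.frame(time = 0, I = 0)
  timecourse(df$time_min, df$fluorescence_au,
             replicate = df$replicate %||% 1L,
             component_id = meta$component_id,
             x_reg = meta$x_reg %||% 0,
             schedule = schedule)
}

#' @rdname read_timecourse
#' @param tc A [timecourse()].
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  meta <- list(component_id = attr(tc, "component_id"),
               x_reg = attr(tc, "x_reg"),
               schedule = attr(tc, "schedule"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

# Exact solution of the reporter cascade for a piecewise-constant production
# rate r(t):  x' = r - a x,  g' = m x - b g, with a = m + mu + gamma_im and
# b = mu + gamma_m.  Marches segment by segment.
.reporter_traj_rates <- function(rates, seg_start, times, a, b, m,
                                 x0 = 0, g0 = 0) {
  g_out <- numeric(length(times))
  x_out <- numeric(length(times))
  seg_end <- c(seg_start[-1L], Inf)
  for (k in seq_along(rates)) {
    r <- rates[k]
    sel <- times >= seg_start[k] & times < seg_end[k]
    tau_pts <- times[sel] - seg_start[k]
    xs <- r / a
    gs <- m * r / (a * b)
    evalf <- function(tau) {
      x <- xs + (x0 - xs) * exp(-a * tau)
      if (abs(a - b) > 1e-9 * max(a, b)) {
        D <- m * (x0 - xs) / (b - a)
        E <- g0 - gs - D
        g <- gs + D * exp(-a * tau) + E * exp(-b * tau)
      } else {
        g <- gs + (g0 - gs) * exp(-b * tau) +
          m * (x0 - xs) * tau * exp(-a * tau)
      }
      list(x = x, g = g)
    }
    if (any(sel)) {
      v <- evalf(tau_pts)
      x_out[sel] <- v$x
      g_out[sel] <- v$g
    }
    if (is.finite(seg_end[k])) {
      v <- evalf(seg_end[k] - seg_start[k])
      x0 <- v$x
      g0 <- v$g
    }
  }
  list(x = x_out, g = g_out)
}

#' Deterministic reporter trajectory of a single component
#'
#' Solves the two-species reporter model (immature protein, mature
#' fluorophore) driven by the component's production rate at a fixed
#' regulator concentration and a stepwise inducer schedule.  The production
#' rate is piecewise constant in time, so the linear cascade is solved
#' exactly segment by segment.
#'
#' @param component A [prbs_component()].
#' @param context A [cell_context()] (uses the x1/g1 reporter branch:
#'   `m1`, `gamma_im_x1`, `gamma_m_x1`).
#' @param times Evaluation times (min).
#' @param x_reg Constant regulator concentration (a.u.).
#' @param schedule Stepwise inducer schedule (`data.frame(time, I)`).
#' @param x0,g0 Initial immature/mature levels.
#' @return A data frame with columns `time`, `x` (immature), `g`
#'   (fluorescence).
#' @export
reporter_trajectory <- function(component, context, times, x_reg = 0,
                                schedule = data.frame(time = 0, I = 0),
                                x0 = 0, g0 = 0) {
  .check_schedule(schedule)
  if (any(times < schedule$time[1L]))
    gt_stop("`times` must lie within the schedule span", "gt_argument_error")
  rates <- vapply(schedule$I, function(I)
    production_rate(component, x_reg, I), numeric(1))
  a <- context$m1 + context$mu + context$gamma_im_x1
  b <- context$mu + context$gamma_m_x1
  v <- .reporter_traj_rates(rates, schedule$time, times, a, b, context$m1,
                            x0, g0)
  data.frame(time = times, x = v$x, g = v$g)
}

#' Identify kinetic strengths by nonlinear least squares
#'
#' Fits the reporter model simulated from a component template (with the
#' cellular context fixed) to a measured fluorescence time course by
#' bounded Levenberg-Marquardt least squares with seeded multi-start.  By
#' default the free parameters are the kinetic strengths (`P_M`, `P_m` for
#' regulated components; `P_c` for constitutive ones), matching their use
#' as library indexes; any subset of the strength parameters may be freed.
#'
#' @param tc A [timecourse()]; its `x_reg` and `schedule` attributes define
#'   the measurement condition.
#' @param component Template [prbs_component()] supplying the regulation
#'   class and the fixed binding parameters.
#' @param context A [cell_context()] with the calibrated cellular rates.
#' @param free Character vector of free parameter names; default `P_M`,
#'   `P_m` (or `P_c` for constitutive templates).
#' @param lower,upper Named bounds for the free parameters (finite).
#' @param init Optional named start values; always included as one of the
#'   starts.
#' @param n_starts Number of seeded multi-start points (log-uniform within
#'   the bounds).
#' @param seed Seed for the multi-start draws.
#' @return A list of class `fit_result`: `estimates` (named), `rss`,
#'   `converged`, `ci` (95% intervals from the local curvature, a matrix),
#'   `n_obs`, `start_rss` (residual trace across starts).
#' @export
identify_kinetics <- function(tc, component, context,
                              free = NULL, lower = NULL, upper = NULL,
                              init = NULL, n_starts = 10, seed = 1) {
  if (!inherits(tc, "timecourse"))
    gt_stop("`tc` must be a timecourse", "gt_argument_error")
  constit <- component$regulation_class == "constitutive"
  if (is.null(free)) free <- if (constit) "P_c" else c("P_M", "P_m")
  allowed <- if (constit) "P_c" else c("P_M", "P_m")
  if (!all(free %in% allowed))
    gt_stop(sprintf("free parameters must be among: %s",
                    paste(allowed, collapse = ", ")), "gt_argument_error")
  y <- tc$fluorescence_au
  times <- tc$time_min
  if (all(y == 0))
    gt_stop("all-zero fluorescence trace: kinetic strengths are not identifiable",
            "gt_identifiability_error")
  if (length(y) < 2L * length(free))
    gt_stop("need at least 2x more data points than free parameters",
            "gt_argument_error")
  if (is.null(lower))
    lower <- stats::setNames(rep(1e-6, length(free)), free)
  if (is.null(upper))
    upper <- stats::setNames(rep(1e5, length(free)), free)
  lower <- lower[free]; upper <- upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    gt_stop("bounds must be finite with lower < upper", "gt_argument_error")

  x_reg <- attr(tc, "x_reg")
  schedule <- attr(tc, "schedule")
  base <- unclass(component)

  resid_fn <- function(par) {
    cand <- base
    for (nm in free) cand[[nm]] <- par[[nm]]
    # keep the Hill form valid when P_m wanders above P_M during a search
    if (!constit && cand$P_M <= cand$P_m) cand$P_M <- cand$P_m + 1e-9
    rates <- vapply(schedule$I, function(I) {
      switch(cand$regulation_class,
             constitutive = cand$P_c,
             repressor_regulated = hill_repression(
               cand$P_M, cand$P_m, x_reg, I,
               cand$K_tf, cand$n_tf, cand$K_I, cand$n_I),
             activator_regulated = hill_activation(
               cand$P_M, cand$P_m, x_reg, I,
               cand$K_tf, cand$n_tf, cand$K_I, cand$n_I))
    }, numeric(1))
    a <- context$m1 + context$mu + context$gamma_im_x1
    b <- context$mu + context$gamma_m_x1
    v <- .reporter_traj_rates(rates, schedule$time, times, a, b, context$m1)
    v$g - y
  }

  # log-uniform multi-start within the bounds
  starts <- with_preserved_seed(seed, {
    u <- matrix(stats::runif(n_starts * length(free)), ncol = length(free))
    lo <- log(pmax(lower, 1e-9))
    s <- sweep(u, 2L, log(upper) - lo, `*`)
    exp(sweep(s, 2L, lo, `+`))
  })
  colnames(starts) <- free
  if (!is.null(init)) {
    init <- pmin(pmax(init[free], lower), upper)
    starts <- rbind(matrix(init, nrow = 1, dimnames = list(NULL, free)),
                    starts)
  }

  best <- NULL
  start_rss <- numeric(0)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.list(starts[i, , drop = TRUE]),
                         lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    start_rss <- c(start_rss, rss)
    if (is.null(best) || rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  if (is.null(best))
    gt_stop(sprintf("no start converged; residual trace: %s",
                    paste(signif(start_rss, 4), collapse = ", ")),
            "gt_convergence_error")

  est <- unlist(best$par)[free]
  n <- length(y); pn <- length(free)
  ci <- matrix(NA_real_, nrow = pn, ncol = 2L,
               dimnames = list(free, c("lower", "upper")))
  se <- tryCatch({
    cov <- 2 * best_rss / max(n - pn, 1L) * solve(best$hessian)
    sqrt(pmax(diag(cov), 0))
  }, error = function(e) rep(NA_real_, pn))
  tq <- stats::qt(0.975, df = max(n - pn, 1L))
  ci[, 1L] <- est - tq * se
  ci[, 2L] <- est + tq * se

  structure(list(estimates = est, rss = best_rss,
                 converged = best$info %in% 1:3, ci = ci, n_obs = n,
                 start_rss = start_rss),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> rss = %.6g over %d points; converged: %s\n",
              x$rss, x$n_obs, x$converged))
  print(cbind(estimate = x$estimates, x$ci))
  invisible(x)
}
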