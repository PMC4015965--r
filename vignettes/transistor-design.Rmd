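---
title: "Designing genetic transistors from promoter-RBS libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing genetic transistors from promoter-RBS libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtdesign)
```

## The circuit and its model

A genetic transistor is a two-stage repressor cascade. A constitutive
promoter-RBS component `c1` continuously produces repressor 1, which
represses component `c2`; inducer `I1` sequesters repressor 1 and so sets
the operating point of the input stage. `c2` produces both repressor 2 and
an input reporter whose mature fluorescence `g1` is the measurable input
signal. Repressor 2 represses component `c3` (relieved by inducer `I2`),
which drives the output reporter read as `g2`. Because the `c3` stage
inverts, the steady-state transfer curve `g1 -> g2` falls monotonically:
over a suitable input range it approximates an inverting linear amplifier,
and for low `I2` it sharpens into a switch.

Each species follows first-order production/loss kinetics. For mature
reporters the loss rate is dilution plus specific degradation
(`mu + gamma_m`); immature reporters additionally mature at rate `m`. The
closed-form steady state is evaluated in cascade order, e.g.
`x_repressor1 = P_c1 / (mu + gamma_repressor1)` and
`g1 = m1 x1 / (mu + gamma_m,x1)`; `steady_state()` returns all six species
and `simulate_dynamics()` integrates the ODEs (deSolve's `lsoda`) from any
initial condition.

Regulated production follows a Hill repression law with competitive
inducer sequestration:

$$p(x, I) = P_m + \frac{P_M - P_m}{1 + (x_\mathrm{free}/K_\mathrm{tf})^{n_\mathrm{tf}}},
\qquad x_\mathrm{free} = \frac{x}{1 + (I/K_I)^{n_I}}.$$

This canonical form reproduces the behaviours the cascade relies on: zero
repressor gives `P_M`, saturating repressor gives the basal `P_m`, and
inducer monotonically relieves repression. The binding parameters
(`K_tf`, `n_tf`, `K_I`, `n_I`) are declared per component in the library
files; the synthetic generators sample them within physiological ranges.
An activator-regulated law (`activator_rate()`) is provided for library
completeness, though the transistor itself uses only constitutive and
repressor-regulated components.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `mu` | 0.02 min⁻¹ | dilution by growth (~35 min doubling) |
| `gamma_repressor*` | 0.01 min⁻¹ | repressor degradation |
| `gamma_im_x*` | 0.01 min⁻¹ | immature reporter degradation |
| `gamma_m_x*` | 0.004 min⁻¹ | mature reporter degradation (stable FP) |
| `m1`, `m2` | 0.05 min⁻¹ | reporter maturation (~20 min) |
| `sd_frac` | 0.05 | fractional parameter deviation |
| `v_intensity` | 1 a.u. min⁻¹ | additive dynamic disturbance |
| `vs_scale` | 0 | additive steady-state disturbance |

Kinetic strengths are in arbitrary fluorescence units per minute; inducer
concentrations carry the inducer's own units (mM for IPTG-type, ng/ml for
aTc-type inducers), and configs must state them explicitly.

## The fluctuation model

Uncertainty in the kinetic parameters is modelled as Gaussian perturbations
`p -> p + sd_frac * p * n(t)` with one noise source per circuit branch
(constitutive input branch, `c2` branch, `c3` branch), so parameters within
a branch fluctuate coherently, plus six additive disturbances. Three
numerical choices the model itself leaves open were fixed as follows:

* **Discretisation.** In `simulate_dynamics(noise = TRUE)` the branch
  noises are resampled every Euler–Maruyama step and scaled by
  `1/sqrt(dt)` (default `dt` = 0.1 min), so the accumulated perturbation
  variance is independent of the step size; the additive disturbances
  enter as Wiener increments.
* **Steady-state noise.** `steady_state(noise = TRUE)` draws the branch
  perturbations once per evaluation — one realisation corresponds to one
  perturbed copy of the circuit — and adds per-species disturbances
  scaled by `vs_scale` (default 0, since the model does not pin their
  variance; they are configurable).
* **Non-negativity.** Concentrations and fluorescences are clipped at zero
  after every stochastic step or draw, and perturbed rate parameters are
  clipped at zero so rates stay physical.

An all-zero `fluctuation_spec()` reduces every stochastic path to the
deterministic one, which the tests assert bit-exactly.

## Design specifications and the cost functional

An amplifier specification asks the transfer curve to follow the line
`y_d(g1) = gain (g1 - g1_low) + g2_high` over the input operation range
`[g1_low, g1_high]`; a switch specification asks for
`y_d(g1) = L_s + (H_s - L_s)/(1 + (g1/g_t)^h)` with steepness `h = 2` by
default. The input range itself is set through the input device:
`input_range_map()` converts an `I1` interval into the achievable `g1`
interval.

A candidate design `{c3, I2}` is scored by the expected integrated squared
deviation

$$J(c_3, I_2) = \mathrm{E} \int_{g_{1,l}}^{g_{1,u}}
\left(y_{ss}(c_3, I_2, g_1) - y_d(g_1)\right)^2 \, dg_1 .$$

Numerical choices: the `g1` grid is uniform (default 33 points) and the
integral uses the trapezoidal rule; the map `g1 -> I1` is inverted
*exactly* — the steady-state input device is a composition of invertible
Hill maps, so the inversion is closed-form rather than interpolated, and a
requested range outside the achievable interval raises a classed
infeasibility error naming that interval. The expectation is a seeded
Monte-Carlo mean over perturbed-circuit realisations; within a GA
generation all candidates share common random numbers so selection
compares like with like.

## The search

The design space is mixed: a discrete component choice and a continuous
(or gridded) inducer concentration. `ga_search()` evolves chromosomes
`(component index, encoded I2)` with tournament selection, blend crossover
on the inducer coordinate, uniform component mutation, Gaussian inducer
mutation, and elitism (default population 40, 60 generations, crossover
0.8, mutation 0.2, elitism 2). The space is small, so these defaults are
deliberately generous; `exhaustive_search()` provides an independent
brute-force oracle on finite grids, and the test suite requires the GA to
attain the exhaustive optimum on 5-component x 20-inducer problems in at
least 9 of 10 seeds (and never to beat it). With elitism at least 1 the
best-so-far cost is non-increasing across generations, which is asserted
as an invariant. Noise-free costs are memoised, so GA runs on gridded
domains typically evaluate each of the ~100 candidates once.

`build_lookup_table()` runs one search per specification and emits the
rows `{input range, gain or levels, component, inducer concentration, J}`
as TSV — the designer-facing product: given a target response, read off
which component to clone and how much inducer to add. Infeasible
specifications yield `NA` rows rather than aborting the table.

## Identification

Library construction ends with estimating kinetic strengths from reporter
time courses. For a component measured at a fixed regulator level under a
stepwise inducer schedule, the production rate is piecewise constant, so
the two-species reporter model (immature protein, mature fluorophore) has
an exact piecewise-analytic solution; `reporter_trajectory()` implements
it and the tests cross-check it against `deSolve` integration.
`identify_kinetics()` minimises the squared deviation between that model
and the measured fluorescence with bounded Levenberg–Marquardt
(`minpack.lm`), using 10 log-uniform seeded starts by default and
reporting the best residual, a convergence flag, and local-curvature 95%
confidence intervals. The loss is on raw fluorescence (no transform), and
by default only the strengths (`P_M`, `P_m`, or `P_c`) are free with the
context rates fixed from calibration — the strengths are the library
indexes. A two-phase schedule (no inducer, then saturating inducer)
makes both strengths identifiable from one trace; an all-zero trace
raises an identifiability error.

## What the synthetic generators emulate — and what they do not

`make_library()` samples kinetic strengths log-uniformly over
5–200 a.u. min⁻¹ (mutagenised promoter-RBS libraries span orders of
magnitude), basal levels at 0.5–5% of maximal, and binding parameters
within physiological ranges; `make_context()` draws growth and degradation
rates around a ~40 min doubling time; `make_timecourse()` applies 5%
multiplicative measurement noise by default. `make_planted_design_problem()`
derives a specification from one component's own noise-free transfer
curve (its secant line, or Hill anchors at its high level and midpoint)
and certifies the global optimum by exhaustive evaluation, giving search
tests a known answer.

These generators reproduce the statistical structure the models assume —
not real measurement artefacts. Autofluorescence background, growth-phase
dependence of the context rates, plate-reader drift, and cell-to-cell
variability beyond the parametric fluctuation model are all absent, so
passing tests certify the methodology (model, cost, search,
identification), not predictions for any particular wet-lab part set.
Real part parameters would enter as measured library JSON files through
the same interfaces.

## Problem sizes and determinism

The test suite runs the steady-state/dynamics consistency check on 50
random circuits (relative tolerance 1e-4 against the closed form), the
Monte-Carlo cost stability check with a 5000-realisation reference, the
noisy identification study over 50 seeds, and GA-versus-brute-force over
10 seeds — sizes chosen so the whole suite completes in well under a
minute while keeping the Monte-Carlo standard errors far below the
tolerances they guard. Every stochastic entry point takes an explicit
seed and restores the caller's RNG state, so workflows are reproducible
end to end; the CLI records the seed and a config hash in a deterministic
provenance sidecar, and identical config+seed runs are byte-identical.

## Known limitations

* The regulation law is a single canonical Hill family; cooperative
  multi-operator promoters whose response is not of this form would need a
  new `regulation_class`.
* The steady-state noise scales (`vs_scale`) have no principled default;
  they are configurable and default to zero.
* `c1` and `c2` are fixed by the input-device choice; only `{c3, I2}` is
  searched, mirroring the intended design procedure (the input device is
  chosen once for maximal input range).
* Inducer units are labels carried through configs, not validated
  dimensionally.
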