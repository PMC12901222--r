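---
title: "TNF-alpha kinetics under infliximab: model, numerics and adaptive dosing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TNF-alpha kinetics under infliximab: model, numerics and adaptive dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifxdyn)
```

## The model

`ifxdyn` simulates four interacting species in the receptor compartment of
an inflammatory bowel disease (IBD) patient:

* `L` — free TNF-alpha (molar), the pro-inflammatory cytokine elevated in
  active Crohn's disease (CD) and ulcerative colitis (UC);
* `r` — the proportion of cell-surface TNF receptors occupied by TNF-alpha
  (dimensionless, between 0 and 1);
* `A` — free infliximab (molar), an anti-TNF monoclonal antibody delivered
  by two-hour intravenous infusions;
* `C` — the TNF–infliximab (antibody–antigen) complex (molar).

Both binding reactions follow mass-action kinetics: TNF-alpha binds free
receptors at rate `k1` and dissociates at `k_m1`; it binds infliximab at
`ka` and dissociates at `k_ma`. Bound receptors are internalized at rate
`eps`; free TNF-alpha, free drug and the complex are cleared at first-order
rates `delta1`, `delta_a` and `delta_c` respectively. The drug input
`omega_a(t)` is a piecewise-constant infusion profile.

The distinguishing modelling choice is *dynamic TNF-alpha production*. In
the plain formulation (`rhs_constant_production()`), production is a fixed
external rate `omega1`; TNF-alpha then rebounds to its equilibrium within
about two weeks of an infusion, too fast to reproduce the sustained benefit
seen clinically. In the dynamic formulation (`rhs_full()`), the production
term is set to the quantity that exactly balances the losses at steady
state, `eps*r*R_tot + delta_c*C + delta1*L`, with the `delta1*L` loss
cancelling. Two consequences:

1. the drug-free steady state is preserved by construction
   (`production_rate_at_equilibrium()` returns the balancing `omega1`,
   2.1315e-14 M/s at the CD baseline);
2. the weighted sum `L + R_tot*r + C` — the total TNF pool `P0` — becomes a
   conserved quantity for *any* drug input, because every route that removes
   free TNF-alpha through receptor or antibody binding is accounted for
   inside the pool.

Eliminating `L = P0 - R_tot*r - C` yields an equivalent three-state system
(`rhs_reduced()`), convenient for analysis; the package integrates either
and the test suite verifies they agree.

### Drug-free equilibria

With no drug, equilibria satisfy a quadratic in `r`,
`a r^2 + b r + c = 0`, with `a = k1*R_tot`,
`b = -k1*(P0 + R_tot) - k_m1 - eps`, `c = k1*P0`, and `L* = P0 - R_tot*r*`.
One can show `f(0) = c > 0` and `f(1) = -(k_m1 + eps) < 0`, so exactly one
root lies in (0, 1) whenever `P0 > 0`; `drug_free_equilibria()` therefore
selects the admissible pair by the test `r*` in [0, 1] and `L*` in
[0, P0] rather than by a sign convention tied to one particular parameter
set. The discriminant is always non-negative
(`b^2 - 4ac >= (k1*P0 - k1*R_tot)^2 + ...`), so the error branch for a
negative discriminant is defensive only; a double root would simply return
the same pair twice.

```{r equilibria}
pre <- ifx_preset("CD")
drug_free_equilibria(pre$params, L0 = 4.35e-11, r0 = 0.0827)
```

The CD preset (`L0 = 4.35e-11` M, `r0 = 0.0827`) relaxes to
`L* = 2.07e-11` M, the reported TNF-alpha level of active CD; the UC preset
(`L0 = 2.75e-11` M) gives `1.407e-11` M, which rounds to the reported
`1.40e-11` M at the precision to which `L0` itself is quoted.

## Parameters and units

All internal computation is in strict SI-molar units (mol/L, seconds); the
clinical framing (mg doses, 2-hour infusions, 4-week intervals, mg/L
thresholds) is converted at the interface. Defaults of `ifx_params()`:

| parameter | meaning | default | units |
|---|---|---|---|
| `k1` | TNF–receptor association | 1.7e7 | 1/M/s |
| `k_m1` | TNF–receptor dissociation | 5.5e-4 | 1/s |
| `R_tot` | total receptor concentration | 1.5e-10 | M |
| `eps` | bound-receptor internalization | 6e-4 | 1/s |
| `delta1` | free TNF-alpha clearance | 1e-5 | 1/s |
| `ka` | TNF–infliximab association | 1e6 | 1/M/s |
| `k_ma` | TNF–infliximab dissociation | 1e-4 | 1/s |
| `delta_c` | complex clearance | 8.5e-7 | 1/s |
| `delta_a` | infliximab clearance | 3.5e-6 | 1/s |

`delta_a` is the patient-specific quantity of interest; plausible values
span [1.5e-6, 5e-6] 1/s and values outside that window warn rather than
error, since the window is an empirical range, not a mathematical
constraint.

Two conventions are not physical parameters but are needed to translate
clinical units (`unit_conventions()`): the infliximab molar mass
(144190 g/mol) together with a 1 L reference volume reproduces the quoted
350 mg/2 h infusion rate of 3.3713e-10 M/s exactly, and the TNF-alpha molar
mass (17000 g/mol) reproduces the 2.6e-13 M to 4.42e-6 mg/L
correspondence. Both are documented assumptions reverse-engineered from
those printed correspondences and can be overridden.

## Numerical integration

The kinetics are stiff: association time scales (`k1*L ~ 1e-3`/s during an
infusion, `ka*A ~ 1` /s) coexist with clearances of order 1e-6/s. We use the
backward-differentiation formulas of `deSolve::ode(method = "bdf")`, the
same family of implicit stiff solvers as MATLAB's `ode15s`.

Numerical choices, made once:

* **Breakpoint restarts.** The infusion rate is discontinuous at every
  infusion start/end. Rather than relying on the solver to notice, the
  integration is restarted at each breakpoint with a constant input on each
  segment, so no discontinuity is ever stepped over.
* **Conservation-exact right-hand side.** `rhs_full()` evaluates
  `dL = -(R_tot*dr + dC)`, which is algebraically identical to the expanded
  form but makes the conservation identity hold to machine rounding at
  every evaluation. Trajectory drift in `L + R_tot*r + C` is checked after
  every run against a tolerance of `1e-6 * P0` and is an error, not a
  warning: it is the integration quality gate.
* **Tolerances.** Relative tolerance 1e-8; absolute tolerances 1e-20 M for
  molar states and 1e-12 for `r`, reflecting state magnitudes spanning
  1e-13 to 1e-4 M. Tiny solver undershoots below zero (within 1e-18) are
  clamped; anything larger is reported (configurable warn/error).
* **Dense sampling.** At least 200 evenly spaced samples per inter-dose
  interval (plus the breakpoints themselves) so that per-cycle peaks and
  pre-dose troughs are resolved without event detection.
* **Degenerate inputs.** An empty schedule integrates the drug-free system;
  a zero pool (`P0 = 0`) stays at the origin; `t_end` must cover the last
  infusion.

The a priori bounds `r <= 1`, `A + C <= max(A0+C0, omega*/min(delta_a,
delta_c))` and `L <= P0` (`theoretical_bounds()`) are asserted along
trajectories in the test suite rather than proved here.

## Dosing protocols and cycle summaries

`cycle_extrema()` splits a run into dosing cycles (dose start to next dose
start) and reports, per cycle, the drug peak `A_max`, the TNF extremes, and
the **trough** `A_min`, defined as the value at the instant immediately
before the next infusion — the quantity measured in therapeutic drug
monitoring (TDM). Drug peaks coincide with TNF-alpha valleys just after
each infusion; drug troughs coincide with TNF-alpha peaks just before the
next one.

The "steady cycle" used for summary figures of trough/peak behaviour is
defined as the final cycle of the standard protocol — 350 mg over 2 h at
weeks 0, 4 and 8, simulated to week 12 — matching the reference simulation
setups; `clearance_sweep()` repeats that protocol over a clearance grid
(default: 36 uniform points across [1.5e-6, 5e-6] 1/s; the grid behind the reference fit is
not stated, so it is configurable). On this
protocol, the 350 mg trough leaves the therapeutic range
(3 mg/L = 2.0806e-8 M) near `delta_a ~ 2e-6` 1/s, and the TNF-alpha peak at
that critical clearance is about 2.6e-13 M; at `delta_a = 5e-6` the
TNF-alpha peak is within 15% of the untreated equilibrium, i.e. the dose
has essentially no effect.

## The inverted Hill clearance model and adaptive dosing

Active inflammation increases intestinal permeability and with it fecal
drug loss, so clearance falls as the disease comes under control. The
trough concentration is the clinical proxy: the sweep induces a
monotone map from trough `A_min` to the clearance that produced it, and an
inverted Hill function fits it well:

$$\delta_a(A_{\min}) = \frac{V}{1 + (A_{\min}/K)^n}$$

with defaults `V = 6.8939e-6` 1/s (clearance as the trough vanishes),
`K = 0.5809e-9` M (half-maximal trough) and `n = 0.2590` (a very shallow
transition). `fit_hill()` re-estimates these by Levenberg–Marquardt least
squares on untransformed clearance residuals, starting from
`V0 = max(delta_a)`, `K0 = geometric mean trough`, `n0 = 0.5` with
positivity bounds — a robust recipe in the shallow-`n` regime; refitting
from this package's own default sweep lands within 25% of those values
(the original sweep grid being unknown, closer agreement cannot be
expected).

`simulate_adaptive_regimen()` closes the TDM loop: the first interval uses
the patient's assumed clearance `delta_a0`; before each subsequent dose the
trough is read and converted by the Hill curve into the clearance held over
the next four weeks.

**Counting convention.** Dose `k` "reaches the therapeutic level" when the
trough at the *end* of interval `k` (four weeks after dose `k`, immediately
before dose `k+1`) first meets the 3 mg/L threshold, and
`doses_to_therapeutic = k`. This choice is deliberate and the counts are
sensitive to it: counting the dose *about to be administered* when the
level is first observed would add one to every entry, and counting any
within-interval crossing (`count_mode = "any_time"`) is far laxer because
post-infusion peaks exceed the trough threshold from the first dose. Under
the stated convention the CD preset with `delta_a0 = 3.5e-6` 1/s reaches
the therapeutic trough after 9 four-weekly 500 mg doses, while 350 mg does
not reach it within a year; the computed 700 mg course at the same
clearance crosses after 5 doses, and 350 mg at `delta_a0 = 2.5e-6` ends the
year at a 2.66 mg/L trough, still below range. The test suite checks that
these counts do not depend on the solver tolerance, so they are properties
of the stated model and convention rather than numerical artifacts.

`doses_to_therapeutic_table()` tabulates the counts over a
clearance-by-dose grid (monotone: more drug never needs more doses, faster
clearance never fewer), and `recommend_dose()` implements the resulting
strategy — start low, measure the four-week trough, estimate clearance via
the Hill curve, and select the smallest candidate dose that reaches range
within the one-year horizon of 13 four-weekly doses.

```{r recommend, eval = FALSE}
recommend_dose(2e-6, candidate_doses = c(350, 500, 700))   # -> 350 mg
recommend_dose(4.5e-6, candidate_doses = c(350, 500, 700)) # -> 700 mg
```

## Scenario files, fixtures and the command line

Scenarios are YAML/JSON files (`load_config()` / `save_config()`) using
clinical units, validated field by field, with `CD`/`UC` presets fixing the
initial conditions (`A0 = C0 = 0`, `r0 = 0.0827`, disease-specific `L0`).
`generate_fixtures()` writes worked examples: both presets, the irregular
induction-style schedule (weeks 0, 2, 6, 10), the standard three-dose
protocol, the one-year adaptive 500 mg regimen, and exact/noisy Hill
datasets (the noisy one seeded and byte-reproducible). A thin command-line
front end (`inst/cli/ifxdyn.R`) exposes `equilibrium`, `simulate`, `sweep`,
`fit-hill`, `adaptive`, `recommend` and `fixtures` over these functions;
CSV/JSON outputs carry both molar and mg/L columns.

## What the simulations do and do not show

The simulated "data" are trajectories of the model itself under the stated
study conditions: literature rate constants, the CD/UC baselines, 2-hour
infusions, 4-week intervals, and deterministic kinetics in a single
well-mixed 1 L compartment. Passing tests therefore demonstrate internal
consistency — conservation, equivalence of formulations, closed-form
equilibria, parameter recovery, monotone dose-response — not clinical
validity. In particular the model omits:

* multi-compartment distribution, bioavailability and body-weight scaling
  (doses are absolute mg; the 5 mg/kg framing is only a convenience
  conversion);
* anti-drug antibodies and other immunogenic elimination routes;
* autocrine amplification of TNF-alpha production;
* inter-individual variability and measurement noise beyond the 1%
  synthetic noise used to exercise the Hill fit;
* any absolute TNF-alpha treatment target — the therapeutic criterion is
  the 3 mg/L drug trough used in TDM practice.

Problem sizes used throughout the package's checks: 12-week three-dose
runs, 52-week thirteen-dose adaptive runs, a 36-point clearance grid, and
50-draw randomized property checks — each simulation takes on the order of
a second.
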