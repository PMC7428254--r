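---
title: "Modelling MGMT-mediated temozolomide resistance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MGMT-mediated temozolomide resistance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosel)
```

## The model

`phenosel` simulates how a population of glioblastoma cells can become
resistant to the alkylating agent temozolomide (TMZ) with no mutation
and no gene regulation — purely through stochastic gene expression and
differential cell death ("phenotypic selection through cell death").

Each of `K` population slots holds one cell with its own volume,
division-volume target and molecule counts.  Two genes are expressed
with *identical* kinetics: the DNA-repair protein MGMT, which protects
against TMZ, and a reference protein REF, which does nothing.  Because
the two genes share every rate, any divergence of `<MGMT>/<REF>` from 1
isolates selection from global expression effects.

**Intracellular kinetics** (per cell, all rates per hour): constitutive
transcription at `b1`, mRNA decay at `d`, translation at `b2` per mRNA,
optional protein decay `d2` (0 by default).  With the best-fit general
parameters the expression is extremely bursty: the mean mRNA count is
`b1/(d + mu) ~ 0.017`, so a cell holds an mRNA only rarely, but each
mRNA translates a very large protein burst.  That burstiness is the
engine of selection.

**Death.**  TMZ damages DNA at rate `kd * [TMZ]`; MGMT repairs (de-
alkylates) at rate `s * MGMT`; an alkylated gene state kills the cell
at `kd2` (1/h by convention).  Because damage and repair are much
faster than expression, the damaged fraction equilibrates to
`kd*[TMZ] / (kd*[TMZ] + s*MGMT)` and the death rate becomes

```
f2 = kd2 * kd*[TMZ] / (kd*[TMZ] + s*MGMT)
```

plus a basal rate `eps` in the data-constrained variant.  `build_network()`
offers both the reduced network (this closed form as one death channel)
and the full network (explicit binary damage state); the full variant
is the small-scale verification oracle for the reduced one, and the
test suite checks their death statistics agree.  The printed units of
`kd` (uM/h) and `s` (1/uM) do not close dimensionally against a
molecule count; the formula is implemented literally, with `kd*[TMZ]`
and `s*MGMT` treated as commensurate, because the best-fit values were
obtained under that reading.  The `tmz = 0, mgmt = 0` corner is defined
as `f2 = 0` (no alkylating agent, no TMZ death).

**Growth and division.**  Volume grows exponentially,
`V(t) = V(0) e^{mu t}`, with `mu = mu0 / (1 + [TMZ]/I50)` once dosing
is active.  A cell divides when it reaches its target
`V_F = a*V_I + b + eta1`, `eta1 ~ N(0, sigma1)` (the noisy linear size
map, default `a = 1`, `b = 15e-13 l`); in bounded mode `V_F` is
confined to `(29.25, 30.75) x 1e-13 l`.  Division splits the volume by
`eta2 ~ N(0.5, sigma2)` and every molecular species binomially with
probability `eta2` to daughter 1.  Daughter 1 keeps the parent slot;
daughter 2 displaces a uniformly random *other* slot (live or dead); a
dead-slots-first policy is available and statistically
indistinguishable (tested).  Death simply empties the slot.  Viability
is `N(t) = M(t)/K`, recovery `N(t_f) - min N(t)`.

**TMZ uptake** (`dose_schedule()`): step (`f4`, instant submersion
after `t_in`), pulse (`f5`, on `(t_in, t_out]`), or sigmoid
(`f3 = dose * t^h / (Q^h + t^h)`, slow uptake used with assay data,
active from the assay clock's `t = 0`).  TMZ is neither degraded nor
diluted.  Growth inhibition is keyed to the instantaneous intracellular
concentration; for step/pulse this coincides with the `t >= t_in`
switch, and for the sigmoid it makes "dosing active" equivalent to
`tmz_at(t) > 0`, the natural reading when dosing starts at seeding.

## Simulation scheme

The multi-scale loop freezes TMZ and volume over a 6-minute outer step,
advances each live cell's reactions inside the window, removes deaths,
grows volumes, and divides cells past their targets.  Within a window
the engine is either the exact Gillespie direct method (SSA) or fixed
tau-leaping (Poisson channel counts per leap; the leap defaults to the
whole 6-minute window and can be subdivided).  If a leap would drive
any count negative the *whole window* is redone with the SSA, so the
approximation never manufactures negative molecules.  Tau-leaping is
the default for population runs: the general model's protein bursts
(tens of thousands of molecules per mRNA per hour) make event-by-event
SSA infeasible at population scale, and the tests verify tau-leap/SSA
moment agreement at the 6-minute leap.  Halving the outer step leaves
population summaries statistically unchanged (tested).  The full
(binary damage state) variant always uses the SSA.

All randomness flows through R's global RNG, so a single `set.seed()`
makes every run — C++ kernels included — bit-reproducible.

## Parameters

Two published best-fit sets ship with the package:

* `params_general()` — the unconstrained ("general") model: `mu0 =
  0.0948/h`, `b1 = 0.0016/h`, `d = 3e-4/h`, `b2 = 5483.75/h`,
  `s = 202.25/uM`, `kd = 1.92 uM/h`, `eps = 0`, `sigma1 = 0.2e-13 l`,
  `sigma2 = 0.05`, `V_I = 15e-13 l`.
* `params_constrained()` — calibrated to the patient-derived line's
  growth and viability assays: `mu0 = 0.01388/h` (doubling time 49.9 h),
  `b1 = 0.00882/h`, `d = 0.07847/h`, `b2 = 9.1027/h`, `s = 96.8167/uM`,
  `I50 = 0.4912 uM`, `eps = 0.00043/h`, `kd = 0.1808 uM/h`, with
  sigmoidal uptake (`Q = 77.6434 h`, `hill = 9.5362`).

**The general model's `I50`.**  The published posterior mode for the
general model's half-inhibition concentration is bimodal: both a very
low and a high value fit the selection objectives, and the low printed
mode (0.0013 uM) implies `mu = mu0/(1 + 800/0.0013) ~ 1.5e-7/h` at a
800 uM dose — growth, and therefore division, stops entirely.  A
population that cannot divide cannot show the reported behaviour under
sustained dosing: viability recovery, a non-zero steady state near 60%
of the population, and the division/death oscillations around it.  We
therefore take the *high* mode as the default, fixed a priori as the
reflection of the low mode about the centre of the log prior
`(e^-10, e^10)`: `I50 = exp(+6.645) = 769.23 uM`.  With it, sustained
800 uM dosing reproduces the reported phenomenology (partial recovery
to a ~60% plateau with ongoing division/death turnover); with the
printed low mode the population decays monotonically to a few percent.
The low mode remains available (`params_general(I50 = 0.0013)`), and
all closed-form tests evaluate the printed arithmetic at it.

**Initial conditions and burn-in.**  The published initial-count table
is not available, so `init_population()` starts every slot live with
volumes uniform on `[V_I, 2 V_I)`, per-cell division targets from the
size map, and counts at the rounded mean-field steady state
(`b1/(d+mu0)` mRNA, `b1 b2/((d+mu0) mu0)` protein, identical for both
genes).  The standard protocols dose at 144 h, and ~14 volume
e-foldings of pre-dose burn-in make the results insensitive to this
choice.

## Statistics and the noise sweep

`summary_stats()` reports the squared coefficient of variation
(`noise = var/mean^2`) and the third standardized moment (skewness; 0
by convention for a constant sample, so sweep tables never carry
indeterminate values).  For constitutive mRNA these have the
birth-death closed forms `noise = 1/lambda`, `skew = lambda^{-1/2}`.

`noise_sweep()` rescales `b1 -> b1/f`, `b2 -> b2*f`, which moves mRNA
noise while pinning the mean-field protein level, with division noise
switched off (`sigma1 = sigma2 = 0`, exact halving, unbounded
deterministic size map) so only expression noise varies.  Two
measurement choices matter:

* The sweep reports the *closed-form* noise/skewness at the mean-field
  mRNA mean as its x-axis (plus empirical snapshot values where
  estimable).  At high factors the mean mRNA is ~1e-4 per cell, so no
  cross-sectional sample at desk-scale `K` can estimate the noise —
  the closed form is exact and monotone in `f`, which is what the
  rank-correlation claims need.
* Ratios and recovery are taken at the final time (288 h under the
  standard step protocol); mRNA statistics at the end of the dose-free
  burn-in.

Two scale effects are worth knowing.  First, at strongly reduced
transcription the post-dose survival of the population hinges on *some*
cell bursting before everyone dies; that rescue rate is `K * b1 / f`
population-wide, so heavily reduced `K` understates recovery at high
factors (the sweep defaults to `K = 2000` and the acceptance checks use
the published 10000).  Second, burst-driven repopulation is slow, so at
the highest factor the 288 h horizon truncates a recovery that is still
in progress — extending the horizon (or starting the sweep from
sub-baseline noise, `f < 1`) restores the positive noise-recovery
relationship that the low-noise regime ("a homogeneous population
either all dies or never dies") makes intuitive.  The test suite pins
the positive relation over `f in {1/64..1}` and documents the saturated
branch above baseline.

The selection ratio of a population whose surviving cells carry MGMT
but not a single REF molecule is reported as `+Inf` (unbounded
upregulation); rank statistics handle this correctly.

## Inference

`abc_rejection()` is plain rejection ABC with a top-`keep` rule: each
error is min-max normalized across the proposals and summed, so no
acceptance thresholds need to be invented; proposals whose simulations
fail or go extinct score `+Inf`.  The three calibration errors are
`E1 = <REF>/<MGMT>` at the final time (selection), `E2 = |1 - N(t_f)|`
(a viable population), and `E3`, the mean squared difference between
simulated viability — rescaled to the dose-0 *simulation*, mirroring
the assay's control normalization — and the replicate-mean assay values
at the assay times, summed over the 0 and 800 uM conditions.  Prior
boxes follow the published tables: the general box is sampled
log-uniformly (its bounds are powers of e and only make sense on the
log scale), the data-constrained box uniformly on the linear scale.
Posterior summaries (`posterior_mode()`, `posterior_correlations()`,
`posterior_sensitivity()` — the diagonal of the inverse posterior
covariance, ridge-regularized and flagged if singular) work on the
sampling scale.

`fit_growth()` compares exponential and logistic growth by ABC model
choice: both models get equal proposal budgets, the loss is the MSE
over *all replicate points* (so replicate variability enters the fit),
and the model probability is each model's share of the pooled top-n.
Priors: `mu ~ U(0, 0.1)/h` (covers the 40-60 h doubling times reported
for glioma lines with a wide margin), `N0` uniform within a factor two
of the seeded count, and the logistic capacity log-uniform over
`(ymax, 1000*ymax)`.  One caveat is structural: the logistic *nests*
the exponential (capacity to infinity), so on purely exponential data
the comparison can only mildly prefer the smaller model — near-even
probabilities there are correct behaviour, not a failure.  Data with
visible saturation flip the comparison decisively (tested).

Inference-time simulations use reduced `K` (default 500) and the
tau-leap engine with SSA fallback.  Identifiability at desk scale: the
viability data constrain `kd` and `eps`; `d`, `s`, `I50` and `b2` are
left effectively unconstrained, and the recovery tests require interval
coverage only for the former pair.

## Synthetic data

`synth_growth()` emulates the 6-day counting assay (seeding 8e4 cells,
daily counts, triplicates, multiplicative Gaussian noise with cv 0.05,
redrawn if non-positive).  `synth_viability()` emulates the WST-1
dose-response assay with the calibrated model itself as generator:
doses {0, 75, 150, 300, 600, 800} uM, times {72, 96, 120, 144} h,
triplicates, percent-of-control normalization against the dose-0 run,
multiplicative noise (cv 0.05) truncated at zero, and a manifest
attribute recording every generator setting.  Finite-`K` slot sampling
is deliberately counted as part of the measurement-noise budget.

What the generator does *not* emulate: plate/edge effects, absorbance
calibration drift, non-multiplicative error, or any biology beyond the
model itself.  A green recovery test therefore establishes that the
pipeline is self-consistent (parameters in, parameters out), not that
the model is correct for any particular cell line.

## Numerical conventions

* Bounded division targets are drawn from the *truncated* normal via
  inverse CDF — identical in law to resample-until-inside whenever the
  interval has mass, and gracefully clamping to the nearest bound when
  the map mean sits many standard deviations outside (as happens for
  daughters born small); `sigma1 = 0` clamps deterministically.
* `eta2` is redrawn until inside (0, 1), preserving the symmetric mean.
* Division is checked once per outer step after the volume update;
  sub-step division timing is not resolved (consistent with the
  frozen-volume hybrid).
* Daughter 2's displacement target excludes the parent slot.
* A window's TMZ concentration is evaluated at the window start.
* `E1` is `+Inf` when mean MGMT is zero, so those draws sort last.

## Known limitations

No promoter switching, explicit DNA replication, mutation, spatial
structure, cell-cycle phases, pharmacokinetic clearance, or MGMT
suicide-enzyme consumption (a first-order `d2` is the only protein-loss
knob).  Exact published posterior modes are not re-derived (stochastic,
budget-dependent); desk-scale runs use `K = 500-2000` against the
published 10000, which widens Monte-Carlo bands — every stochastic test
states its tolerance accordingly.
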