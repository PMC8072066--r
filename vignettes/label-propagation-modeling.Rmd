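---
title: "Modeling heterogeneous HSC label propagation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling heterogeneous HSC label propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hscflux` describes the early hematopoietic hierarchy as a linear chain of
four compartments in upstream-to-downstream order: HSC-U, HSC-D, ST-HSC and
MPP. The flow-cytometric HSC gate (LSK CD150+ CD48-) cannot distinguish the
two HSC subcompartments, so everything compared to data uses the aggregate:
the observed HSC count is $n_U + n_D$ and the observed HSC labeled frequency
the count-weighted mixture of the two hidden frequencies.

Expected counts obey

$$\frac{dn_1}{dt} = -(\alpha_1-\beta_1)\,n_1,\qquad
  \frac{dn_i}{dt} = \alpha_{i-1} n_{i-1} - (\alpha_i-\beta_i)\,n_i ,$$

with $\alpha_i$ the differentiation rate (flux to the next compartment),
$\beta_i = \lambda_i - \delta_i$ the net proliferation rate, and
$\kappa_i = \alpha_i - \beta_i$ the inverse residence time (small $\kappa$
means strong self-renewal). Labeled cells are assumed kinetically identical
to unlabeled cells, so labeled counts $l_{A,i}(t)$ for a labeling design
(Cre driver) $A$ obey the same cascade with initial condition
$l(0) = f(0)\,n(0)$, and the labeled frequency is $f = l/n$. The frequency
form of the dynamics,
$df_i/dt = \alpha_{i-1}(n_{i-1}/n_i)(f_{i-1}-f_i)$ with $df_1/dt = 0$,
makes two facts obvious: a uniform frequency profile is a fixed point for
any rates, and frequencies remain in $[0,1]$.

The package deliberately keeps rates constant in time and restricts
analysis to a 40-week window; aging-related changes in sizes and rates are
out of scope. Time is handled internally in days; summaries also print
per-week values.

### Why a hidden HSC split and no steady state

The classical homogeneous steady-state description (three compartments,
constant sizes, pure relaxation $df_i/dt = \kappa_i(f_{i-1}-f_i)$) forces
every downstream normalized labeled frequency to converge to 1 and cannot
produce (i) a rising labeled frequency inside the HSC gate after a one-time
induction, or (ii) a downstream plateau below 1. Splitting the gate into a
small quiescent upstream pool and an active downstream pool, with
driver-specific initial labeling of the two, produces both behaviors with a
single set of kinetics. `steady_state_model()` implements the homogeneous
description as a comparison baseline, and the package's tests verify it is
the exact special case of the general model under stationary sizes.

## Solvers and numerics

Two independent solution paths are maintained:

* an analytic sum-of-exponentials solution of the linear cascade
  (`closed_form_cascade()`, Rcpp), exact for pairwise-distinct $\kappa$;
* a stiff-capable ODE integrator (`deSolve::lsoda`) with tight default
  tolerances (rtol 1e-9, atol 1e-12), chosen because fitted $\kappa$ values
  span orders of magnitude (`solve_populations()`,
  `solve_labeled_counts()`, `solve_label_frequencies()`).

The two paths cross-check each other in the test suite to 1e-8 relative
error on random instances. Tied $\kappa$ values (a measure-zero set the
optimizer can transiently propose) are perturbed by 1e-9 with a warning on
the user-facing oracle, or rejected outright with `degenerate = "error"`.
The fitting loop evaluates the analytic path with $f = l/n$: with strictly
positive compartment sizes (enforced by the parameter bounds) the ratio is
numerically safe, and it is roughly three orders of magnitude faster than
integration, which is what makes profile-likelihood studies affordable.
The frequency-ODE route is retained as the numerically conservative
alternative and as the cross-check when counts are small.

## Preprocessing pipeline

`load_observations()` reads per-mouse delimited tables (mouse, dataset,
day, compartment, labeled frequency, optional count) and validates ranges
and duplicates. The pipeline then applies, in order:

1. **Time-zero adjustment** (`adjust_time_zero()`): measurement days are
   shifted by the tamoxifen-effect delay, 2 days by default, 1 day for the
   sparse krt18-like design; rows before the effective induction are
   dropped with a warning.
2. **Windowing** (`restrict_window()`): observations beyond 280 days
   (40 weeks, inclusive) are removed, keeping the constant-rate assumption
   tenable.
3. **Per-mouse normalization** (`normalize_observations()`): each mouse's
   ST-HSC and MPP labeled frequencies are divided by the same mouse's HSC
   frequency. Doing this per mouse (rather than per bin) makes the
   normalized stream an honest per-mouse quantity whose within-bin
   variance is a genuine sampling variance.
4. **Pooling** (`pool_timepoints()`): mice are averaged within time bins —
   the eight classical day intervals of the dense design (`tie2_bins()`),
   or one bin per distinct day otherwise. The representative bin time is
   the mean of member observation times; a bin-midpoint alternative is
   selectable. We prefer the mean because bins are occupancy-weighted and
   asymmetric.
5. **Pooled-variance SEMs** (`add_pooled_sem()`): one measurement variance
   per observable stream (compartment x quantity), pooled across bins and
   by default across datasets as
   $s^2 = \sum_g (n_g-1)s_g^2 / \sum_g (n_g-1)$, with per-bin
   $SEM = \sqrt{s^2/n_b}$. This keeps late, sparsely sampled bins honestly
   uncertain instead of letting a lucky small-sample variance shrink them.
   Pooling across datasets is the default reading; `joint = FALSE` pools
   per dataset. Mixing counts and frequencies in one pooled variance would
   be dimensionally meaningless, so streams are always pooled separately.

Noise-free tables (used for self-consistency and identifiability checks)
have zero within-bin variance, so pooled-variance SEMs are undefined;
`add_pooled_sem()` refuses them and such fits use explicit nominal SEMs
(0.005 for raw frequencies, 0.02 for normalized frequencies, 5% of the
mean for counts).

## Inference

`fit_joint()` minimizes the weighted sum of squared residuals over all
datasets. Observables entering the objective are, per bin: the aggregate
HSC labeled frequency and the HSC-normalized ST-HSC and MPP frequencies
(the model side is normalized by the *modeled* HSC frequency at the bin
time, never by noisy data), plus the HSC, ST-HSC and MPP compartment
sizes. Frequencies and counts enter on their natural scales, each
weighted by its pooled SEM.

The parameter vector has a shared block — $\alpha_{1..3}$,
$\kappa_{1..4}$, $n_{0,1..4}$ — and one $f_{0}$ block of four initial
labeled frequencies per dataset. Transforms: log for positive rates and
counts, logit for frequencies, identity for $\kappa_1$, which is the one
rate allowed to be negative by default (the most immature pool may
expand; a switch lifts or imposes the sign restriction). A
$\beta$-parameterization (`parameterization = "beta"`) is provided and
reaches the same optimum — a reparameterization-invariance check in the
test suite.

Optimization is multi-start: data-informed heuristic starts (initial
labeling read off the earliest bins, sizes off the observed counts, a
small set of generic rate regimes including the package's reference
parameter set) plus a seed-controlled Latin-hypercube sample; short runs
screen the candidates, the best are polished, and the final solution is
alternated with a derivative-free Nelder–Mead pass until neither route
improves, which guards against finite-difference stalls in curved
valleys. Everything is deterministic given the seed.

### Uncertainty

`profile_likelihood_ci()` walks each parameter on its transformed scale,
re-optimizing all others (warm-started with linear extrapolation along
the profile path), until the profiled objective crosses the optimum plus
$\Delta = 3.84$ (the 95% chi-square 1-df quantile; the framework does not
prescribe the threshold, this is the conventional choice). The crossing
is located by interpolation on the $\sqrt{\Delta SSR}$ scale, which is
exact for a locally quadratic profile; before accepting a crossing the
point is re-optimized harder (gradient restarts plus a derivative-free
pass) and one step beyond the crossing is probed, since a stalled
re-optimization masquerades as a bump in the profile and would truncate
the interval. A side that reaches the parameter's box edge or
the step budget is reported as unbounded. `prediction_profile_band()`
profiles a model prediction instead of a parameter, by the penalty
method, yielding the extreme predictions compatible with the data;
`labeling_specificity()` profiles the log of the HSC-U:HSC-D initial
labeling ratio per dataset, whose lower bound is the "minimum ratio"
summary, and forms ratio-of-ratios between drivers.

## The synthetic cohort generator

Because the original mouse tables are not redistributable, the package
ships a generator (`generate_cohort()`, `preset_designs()`) that emulates
the studies' statistical structure: cross-sectional cohorts (each mouse
measured once), ~8 effective time points within 40 weeks, unequal mice
per time point, and driver-specific initial labeling of the hidden HSC
subcompartments. The three driver-like presets encode the published-scale
labeling ratios as generator truths (tie2-like 21:1 with low overall
labeling and per-bin mouse numbers 41, 61, 21, 8, 39, 34, 21, 17;
fgd5-like 4:1 with high labeling, 7 mice at each of 8 time points;
krt18-like 30:1 with 18 mice over 6 points and a 1-day offset), plus a
noise-free two-label toy pair labeling HSC-U/HSC-D at (50%, 0%) versus
(50%, 50%).

The reference kinetics (`default_rates()`,
$\alpha = (0.003, 0.14, 0.03, 0.25)$,
$\kappa = (-0.002, 0.0005, 0.037, 0.009)$ per day,
$\delta = (0.002, 0.01, 0.02, 0.02)$ per day,
$n_0 = (400, 2400, 9000, 30000)$) were chosen once to embody the
qualitative biology the model is meant to capture: HSC-U differentiating
about once per 50 cell-weeks and slowly expanding ($\kappa_1 < 0$), an
active HSC-D differentiating roughly weekly, a strongly self-renewing MPP
pool (small $\kappa_4$), HSC-U several-fold smaller than HSC-D, and
compartment sizes near flux balance at induction. The proliferation/death
split ($\lambda/\delta$) is part of the reference set because the
leukemogenesis scenarios act on $\lambda$; death rates of this magnitude
are typical literature-scale values, supplied as configuration rather
than estimated, since label-propagation data do not identify them.

The measurement model is binomial sampling of labeled cells among a fixed
number of analyzed cells per gate (200 for the rarer HSC-gate
compartments, 1000 for MPP) and lognormal multiplicative count noise
(log-SD 0.2). No published error model exists for these data; these
choices produce SEM magnitudes comparable to the published spread and are
fully overridable per design. What passing tests show, therefore, is that
the pipeline and inference behave correctly *under this assumed noise
structure*; real flow-cytometry data add gating drift, batch effects and
inter-mouse biological variability that the generator does not emulate.

## Leukemogenesis scenarios

A mutation is a factor $x \ge 1$ on the proliferation rate $\lambda_i$ of
an origin compartment and all its downstream progeny, so the mutant
lineage follows the cascade with
$\kappa_i^{mut} = \alpha_i - (x\lambda_i - \delta_i)$ for $i \ge s$,
seeded with a single founder cell. Its long-run fate is set by the
dominant eigenvalue $-\min_{i\ge s}\kappa_i^{mut}$: washout when
positive decay everywhere, unbounded growth when some
$\kappa_i^{mut} < 0$. The immortality threshold — the minimal $x$ at
which the mutant MPP share persists — is therefore
$x^* = \min_{i \ge s} (\alpha_i + \delta_i)/\lambda_i$, clamped at 1
(`threshold_closed_form()`), and `find_immortal_threshold()` recovers the
same value by bisection on the dominant decay rate to 1e-6; the literal
infinite-time limit is unreachable numerically, so a long-horizon
simulated slope check backs the criterion in the tests. Because the
minimum runs over a nested set of compartments, the threshold can only
decrease as the origin moves upstream — the hierarchy ordering
$x^*(\text{HSC-U}) \le x^*(\text{HSC-D}) \le x^*(\text{ST-HSC}) \le
x^*(\text{MPP})$ holds for any parameter values.

The reported mutant MPP fraction $p(t) = m_4(t)/n_4(t)$ uses the
wild-type MPP trajectory in the denominator, taken literally from the
defining equations; $p$ can then exceed 1 for expanding clones. A
`include_mutants = TRUE` variant adds $m_4$ to the denominator for a
bounded fraction. Both are reported by the analysis scripts since the
choice is not documented in the source material.

## Problem sizes and known limitations

The recovery study in the acceptance tests runs 50 replicate two-cohort
simulations with profile CIs on the seven kinetic parameters, the
out-of-sample study 20 replicates, and the oracle equivalences 100 random
instances each — sizes chosen so the full suite completes comfortably on
a single CPU while keeping Monte-Carlo error on coverage estimates a few
percent.

Known limitations: no branching topologies or age-dependent rates; no
stochastic birth-death treatment of small clones (a single founder cell
is treated deterministically, so stochastic extinction is ignored and
thresholds are optimistic for small clones); $\lambda/\delta$ splits are
inputs, not estimates; and the two-subcompartment split is a minimal
description — residual heterogeneity inside HSC-U is visible in real data
as a slow labeled-frequency rise that this model attributes entirely to
the U/D exchange. Whether measured "population size" corresponds exactly
to the aggregate modeled here, or was gated further in the original
studies, is not documented; the package assumes the aggregate.
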