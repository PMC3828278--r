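---
title: "Global sensitivity analysis of kinetic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global sensitivity analysis of kinetic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kingsa)
```

## The problem

A kinetic model maps a parameter vector $p$ (rate constants, Michaelis
constants, limiting rates) to systemic behaviour: steady-state
concentrations and fluxes, or the period of an oscillation. The local
sensitivity of an output $y$ to a parameter $p_i$ is the partial
derivative $\partial y / \partial p_i$; to compare across units and
magnitudes the scaled form

$$ C^y_{p_i} \;=\; \frac{p_i}{y}\,\frac{\partial y}{\partial p_i} $$

is used throughout this package. Taken on a parameter that scales a
reaction rate linearly (a limiting rate $V$), the scaled coefficient is
the control coefficient of metabolic control analysis (MCA), and the
full matrices obey the summation theorems: flux-control rows sum to 1,
concentration-control rows to 0.

Local coefficients describe one operating point. The package's purpose
is the *global* question: what values can each coefficient take when all
parameters vary simultaneously within a fractional band $\delta$, each
uniform and independent on $[p_i(1-\delta),\,p_i(1+\delta)]$?
Two complementary strategies are implemented:

* **Monte-Carlo sampling** of the hypercube, recording the full scaled
  sensitivity spectrum at every draw and summarising each coefficient's
  distribution;
* **particle-swarm optimisation (PSO)** of each coefficient, run once to
  minimise and once to maximise it, yielding bounds without
  distributional information.

Their disagreement is informative in both directions — the swarm may
overshoot every sampled extreme, or miss values brute-force sampling
finds — so `compare_bounds_sampling()` reports the comparison instead of
assuming an ordering.

## Finite-difference sensitivities

`scaled_sensitivity()` perturbs one parameter by a relative step
(default 0.1 %, forward difference) and re-evaluates the output,
warm-starting steady-state solves from the unperturbed solution. Forward
differencing is the default because it halves the cost of a spectrum and
matches the perturb-and-measure protocol this analysis style is built
on; it carries an $O(h)$ bias (for $y \propto 1/p$ the measured
coefficient is $-1/(1+h) \approx -0.999$ at $h = 10^{-3}$). A central
mode is available and is what the package's own test oracles use.

`control_coefficients()` deliberately deviates: it uses central
differences at $h = 5\times10^{-4}$ on a multiplicative factor injected
into each rate law (reference value 1, so the factor *is* a limiting
rate for arbitrary kinetics). Two reasons: the summation theorems are
exact properties that a one-sided $O(h)$ bias would visibly violate at
the package's 1e-4 verification tolerance, and the truncation error of
the central form ($O(h^2) \approx 2.5\times10^{-7}$ on coefficients of
order 1) keeps the chain fixture's exact 1, 0, $-1$ control structure
reproducible to 1e-6. Parameters whose rate law is homogeneous of degree
1 (tested numerically by doubling at a nonzero probe state) are tagged
`limiting-rate` on load.

A coefficient is *undefined* rather than an error when the output is
undefined at either evaluation point (no steady state, no oscillation)
or when the operating-point output is exactly 0 (the scaling is
singular). Undefined records carry a reason code and flow through every
aggregation; only a parameter whose *reference* value is 0 raises an
error, since no relative perturbation exists. Period sensitivities are
scaled by the operating-point period, consistent with the definition
above; no analytic period derivatives are attempted.

## Output evaluators

**Steady states** are found by damped Newton iteration (numerical
Jacobian, halving line search) from the reference state or a warm
start, with a fallback to staged relaxation by integration
(LSODA, stages up to $t = 10^5$) followed by a Newton polish. The
residual tolerance is $10^{-9}\,(1 + \max|x_0|)$ on the RHS norm. Note
the division: finite differences amplify this solver noise by $1/h$, so
"exact" structural coefficients are reproducible to about $10^{-6}$,
which is the tolerance the tests use for them. Stability (sign of the
dominant Jacobian eigenvalue) is reported but never used to discard a
sample. Integration uses `deSolve::lsoda` with rtol $10^{-8}$ / atol
$10^{-12}$; integration failures are flagged statuses, not exceptions,
so one pathological parameter set cannot abort a batch.

**Oscillation periods** are measured from a single time course: maxima
of the observed variable are located as $+\!\to\!-$ sign changes of its
*exact* derivative (the RHS evaluated along the trajectory), refined by
the root of a quadratic through the three bracketing derivative values —
so the estimate is decoupled from the output grid, and doubling the
grid changes it by well under 0.1 %. The first half of the window is
discarded as transient (configurable). The period is the mean of the
successive maximum-to-maximum intervals; averaging over several
intervals trades the single-subtraction event protocol for lower
event-location noise. The period is undefined when fewer than 3 maxima
survive the transient, when interval irregularity exceeds a 5 %
coefficient of variation, or when maxima heights drift by more than 5 %
across the window (a damped, not sustained, oscillation — note that a
linearly damped mode keeps a perfectly regular interval, which is why
the amplitude criterion exists at all). For oscillatory outputs the
simulated window should cover at least ~10 periods after the transient;
the default `t_end = 100` suits the shipped fixtures and is a parameter
of `output_spec()` for anything else.

## Sampling design

One RNG seed per *sample index* is derived from the master seed by an
affine counter map modulo $2^{31}-1$. Chunks therefore merely partition
index ranges: results are bitwise independent of chunk size, runs can
be resumed mid-stream (`start` argument), and chunks could execute in
parallel without any shared RNG state. A second consequence: at matched
master seeds the underlying uniforms are identical across bands, so the
hypercubes are nested draw-by-draw and range/exceedance monotonicity in
$\delta$ holds exactly, not just statistically.

Distribution summaries use unit-area histograms (Freedman–Diaconis bin
count with a floor of 50; configurable), the peak as the modal-bin
centre, and the normalised peak height as modal count over *total*
samples including undefined ones. Shapiro–Wilk is computed on the
defined values, deterministically thinned to at most 5000 (the test's
validity range). Undefined samples are excluded from histograms but
always reported as counts — a choice logged in every JSON artifact,
since sustained-oscillation loss at wide bands is common and silently
dropping those samples would bias every summary.

## Pattern classification and robustness

`classify_pattern()` reduces a distribution to qualitative flags:

* *sign span* from the sampled extremes, widened by PSO bounds when
  those are wider (bounds carry no density, so they can never add
  modes); values within $10^{-6}\cdot\max(1,|v|)$ of zero count as zero,
  which keeps solver noise on structurally zero coefficients from
  reading as "mixed sign";
* *multimodality* from peaks of a Gaussian kernel density (Silverman's
  rule) with prominence at least 5 % of the maximum density. The 5 %
  floor recovers the constructed bimodal fixtures without hand-tuning,
  but at small sample sizes ($n \lesssim 10^3$ per band) kernel noise
  can fake a second peak — band ladders should be run with $n \ge 10^3$,
  and the package's own stochastic checks use $10^4$;
* *attains zero* when the density within ±1 % of the range around 0
  exceeds 1 % of the peak density;
* *high magnitude* at a threshold defaulting to $|C| \ge 1$, the
  natural scale of control coefficients (a coefficient of 1 means
  proportional response).

A distribution whose total spread is below $10^{-6}$ relative is treated
as structurally constant (one mode, no zero crossing): spread at that
level is finite-difference noise, not shape.

`robustness_profile()` runs the ladder of bands and reports, per band,
the fraction of parameters attaining the magnitude threshold (sampling
and, optionally, PSO evidence separately), and the *robustness level*:
the smallest band at which any parameter's flags show multiple
coexisting patterns (mixed sign, or multimodal, or zero coexisting with
high magnitude). `Inf` means no pattern split up to the largest band
probed. The default band ladder {0.05, 0.1, 0.25, 0.5} spans "tight
experimental uncertainty" to "order-of-magnitude ignorance"; it is a
user input, not a constant of nature.

## Particle swarm settings

Global-best PSO with uniform initialisation, position clamping with
velocity zeroing on the clamped coordinate, and constriction-factor
coefficients (inertia 0.7298, cognitive = social = 1.4962) — standard,
well-studied defaults for bounded problems; swarm size and iteration
limit are per-model choices (expensive period evaluations warrant small
swarms, cheap steady states large ones). Undefined objective values are
treated as worst-possible fitness so the swarm retreats from non-viable
regions, and the number of such encounters is reported. Each bound is a
pair of independent jobs with seeds derived from the settings seed, so
results do not depend on execution order; the reported bound replays
exactly (to 1e-9) from the stored arg-point, guarding against any
objective/report mismatch.

## The fixture models, and what they do not show

The generators in `R/fixtures.R` exist so that every stage of the
pipeline is testable against an *independent* route:

* `make_irreversible_chain()` — closed-form steady state; all flux
  control on the first step (1, 0, …; concentration controls ±1).
* `make_reversible_chain()` — steady state as a linear system; control
  and response coefficients by implicit differentiation of
  $A s = b$ (exact linear algebra, no finite differences).
* `make_linear_oscillator()` — a pure centre in rate-rule form with
  period exactly $2\pi/\omega$ and scaled period sensitivity exactly
  $-1$; rate rules are used because mass-action centres are structurally
  fragile, and this exercises the raw-ODE code path.
* `make_bimodal_control_toy()` — a supply feeding two saturable
  branches; the closed form $C = a_2/(a_1+a_2)$,
  $a_i = V_i K_i/(K_i+S)^2$, switches between ≈0 and ≈1 with branch
  saturation, so wide sampling yields a genuinely bimodal control
  distribution and narrow sampling a unimodal one.

These fixtures are deliberately low-dimensional and analytically clean.
Passing on them demonstrates the correctness of the machinery —
solvers, differencing, sampling, classification — not the behaviour of
real published models: they have no moiety conservation, no stiffness
gradients across scales, no high-dimensional parameter spaces where
sampling density collapses, and their undefined-sample regions have
simple geometry. SBML import of published models is supported and
tested structurally; checks that depend on specific published model
files run only when those files are present locally.

## Known limitations

* MCA is computed by perturbation, not from the Jacobian/elasticity
  route; for models with conserved moieties the steady-state solver
  relies on Newton/relaxation finding the same conservation class as
  the initial state, which perturbation preserves but does not enforce
  explicitly.
* The SBML subset excludes algebraic rules, delays and events (events
  in files are ignored with a warning; the period machinery is the
  package's own). Unit declarations are taken at face value.
* Period detection assumes the observed variable's maxima are simple
  (one per cycle); period-doubled regimes read as irregular and return
  undefined rather than the doubled period.
* Uniform sampling only; no Latin-hypercube, quasi-random or log-normal
  designs, and no variance-decomposition indices (Sobol, eFAST, PRCC)
  — those answer a different question than the coefficient
  distributions and bounds computed here.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on the fixtures:
summation theorems on ~100 random parameter draws, PSO bounds validated
against a 200×200 exhaustive grid of the reversible chain's exact
response surface, and the branch-point toy sampled at $n = 10^4$ per
band (δ = 0.01 and 0.9) for the pattern-change check — sizes at which
every assertion is stable across seeds while a full run stays within a
few minutes on a single CPU.
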