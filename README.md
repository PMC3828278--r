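# kingsa — global sensitivity analysis of kinetic ODE models

Kinetic models of biochemical networks — metabolic pathways, signalling
cascades, cell-cycle oscillators — rest on parameter values that are
often uncertain. A *local* sensitivity analysis, taken at the published
("physiological") parameter set, tells you how the model behaves at that
one operating point; because these models are nonlinear, the picture can
change completely a short distance away in parameter space. `kingsa`
implements *global* sensitivity analysis for such models, for modellers
who want to know how far their conclusions survive parameter
uncertainty.

## What it computes

For a model output *y* (a steady-state concentration, a steady-state
flux, or an oscillation period) and a parameter *p*, the package works
with the scaled (dimensionless) sensitivity coefficient

    C_p^y = (p / y) · (∂y / ∂p)

approximated by a relative finite difference (default: forward, 0.1 %
perturbation). When *p* is a limiting rate *V* — a parameter that scales
a reaction rate linearly — this is the MCA control coefficient of the
reaction, and the flux-control and concentration-control matrices obey
the summation theorems Σ C^J = 1 and Σ C^S = 0, which the package
verifies to 1e-4.

Global behaviour over the fractional hypercube
`[p·(1-δ), p·(1+δ)]` (each parameter independent, uniform) is
characterised two ways:

* **Sampling**: Monte-Carlo draws of parameter sets, one sensitivity
  spectrum per draw, then unit-area histograms per coefficient with peak
  location, normalised peak height (modal frequency / total samples),
  extremes and a Shapiro–Wilk normality score. Samples for which the
  output is undefined (lost steady state, lost oscillation) are counted
  and reported, never dropped silently.
* **Optimisation**: particle-swarm searches for the lower and upper
  bound of each coefficient over the same hypercube (two independent
  optimisations per coefficient).

On top of both sits a **robustness measure**: the pattern of control of
a coefficient (sign span, multimodality, zero/non-zero, magnitude), per
band δ, and the smallest δ at which multiple patterns coexist. A model
whose control pattern splits at δ = 0.05 is fragile; one that holds a
single pattern past δ = 0.5 is robust.

Models are built programmatically, generated by the shipped fixture
generators (chains, oscillators, a branch-point pathway with switching
control — each with an independent analytic oracle), or read from SBML
Level 2/3 files.

## Worked example

The branch-point fixture is a metabolite fed at constant rate and
drained by two saturable branches. Whether branch 1 runs near
saturation decides whether its limiting rate `V1` controls its own flux
(coefficient near 1) or the flux is pinned by the rest of the system
(coefficient near 0):

```r
library(kingsa)

toy  <- make_bimodal_control_toy()
spec <- output_spec("flux", "branch1")

control_coefficients(toy$model)
#> <control_matrix>
#> Flux control (rows sum to 1):
#>           supply   branch1   branch2
#> supply  1.000000  0.000000  0.000000
#> branch1 0.975293  0.051866 -0.027160
#> branch2 1.862507 -1.810642  0.948134

dom <- parameter_domain(toy$model, 0.9)   # +/-90% hypercube
g   <- run_sampling_gsa(toy$model, dom, spec, n = 2000, seed = 1,
                        parameters = "V1")
d   <- summarize_distribution(g, "V1")
d
#> <sensitivity_distribution> V1: n_ok 1925, undefined 75
#>   range [0.0002497178, 0.9996458], peak at 0.01024368 (height 0.282),
#>   W = 0.6890752
classify_pattern(d)
#> <pattern_flags> positive-only, multimodal (modes 0.0255, 0.969), attains zero
```

At the reference point `V1` has almost no control (0.052, the
`branch1`/`branch1` entry above). Under ±90 % parameter uncertainty the
sampled coefficient becomes bimodal — most parameter sets leave control
near 0, a substantial minority flip it to ≈ 1 — and 75 of 2000 samples
lose the steady state entirely (supply exceeding total branch capacity).
The low Shapiro–Wilk W (0.69) flags the non-Gaussian shape. A narrow
band (δ = 0.01) instead reproduces the local picture: a single peak at
the reference value.

`robustness_profile()` repeats this across a ladder of bands and
reports the first band at which any parameter shows multiple patterns;
`sensitivity_bounds()` adds particle-swarm bounds as a second evidence
source, and `compare_bounds_sampling()` reports which method found the
wider range.

A thin command-line wrapper (`inst/cli/kingsa.R`) exposes the same
drivers:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "kingsa.R", package = "kingsa"))') \
    sample --model bimodal_toy --kind flux --target branch1 \
    --bands 0.01,0.9 --n 2000 --seed 1 --out-dir out/
```

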