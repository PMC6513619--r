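---
title: "Modeling range expansions in heterogeneous environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling range expansions in heterogeneous environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterospread)
```

## The model

`heterospread` implements a generalized Eden model for populations
expanding across a surface whose quality varies from place to place.
Cells occupy sites of a square lattice. Only cells with at least one
empty von-Neumann (4-adjacent) neighbour can divide: growth is
front-limited, as in a microbial colony where nutrients reach only a
thin layer at the rim. In each event one eligible cell is chosen with
probability proportional to its division rate and places a daughter on
a uniformly chosen empty neighbour.

Two ingredients are added to the classical Eden rule:

* **Quenched environmental disorder.** Before growth starts, every
  site is independently declared a *disorder site* with probability
  `rho`. A cell sitting on a disorder site divides at a reduced rate
  `k` (the *transparency*, `0 <= k <= 1`). At `k = 0` the disorder
  sites are impassable obstacles: they can never be colonized, and a
  colony that runs out of accessible open sites is *pinned*. Because
  the accessible region is then exactly the cluster of open sites
  containing the founder, pinned colonies at `k = 0` are
  site-percolation clusters, and expansions fail above the square
  lattice site-percolation threshold (open-site fraction 0.593, i.e.
  obstacle density about 0.407).
* **Mutation with selection.** Each wild-type division produces, with
  probability `mu`, a mutant daughter founding a new clone; mutants
  divide at relative rate `1 + s` and never mutate further. Each
  mutation event gets a unique clone id, so a clone is the founder
  cell plus all descendants (identity by descent -- a clone split into
  patches by obstacles is still one clone).

Time advances by `1 / (sum of eligible rates)` per event, a
deterministic mean-field increment in units of wild-type generation
times. All time-resolved observables in the package can alternatively
use the mean front height (linear geometry) or the lineage generation
count (radial geometry) as their clock, which is what the analysis
protocols below do.

Two geometries are provided: `run_colony()` grows a radial colony from
a single protected founder until `n_target` sites are filled, and
`run_linear()` grows a flat front of width `L` (periodic lateral
boundaries) upward from a fully occupied, protected bottom row. Every
division is logged (mother, daughter, time, genotype, clone id), and
`replay_log()` can rebuild the final state from the log as an
end-to-end consistency check.

### Implementation notes

The event loop is compiled (Rcpp). Mother selection uses rejection
sampling -- a uniform draw from the active list accepted with
probability `rate / rate_max` -- which leaves the embedded jump chain
identical to exact rate-proportional selection. A useful corollary is
that at `k = 1` the trajectory is bit-identical for any `rho` under
the same seed, which the test suite asserts; disorder generation
consumes exactly `L * H` uniforms regardless of `rho` to preserve this
property. The sum of eligible rates for the time increment is tracked
exactly through per-class counts (normal/disorder x wild-type/mutant).

A site is *eligible* if its rate is positive and it has at least one
colonizable empty neighbour; at `k = 0`, obstacle sites are excluded
as daughter targets altogether. Note the discontinuity this implies
between `k = 0` (obstacles never occupied) and `k -> 0+` (occupied,
divide very slowly); it is intended behavior, mirroring the
percolation limit. A small pure-R stepper (`eden_state()`,
`eden_step()`) recomputes the eligible set from scratch each event and
serves as the reference implementation on enumerable fixtures
(`make_fixture()`).

For radial runs the default lattice side is about five times the
homogeneous colony radius `sqrt(n_target / pi)` (inflated further at
high `rho`, where colonies are sparser). A colony touching the border
margin terminates with `terminated_by = "edge"` rather than silently
truncating; ensemble protocols skip such runs.

## Analysis protocols and their tunable choices

### Fronts, interface widths, roughness exponents

`extract_front()` flood-fills the exterior empty region from the
lattice border (obstacles act as barriers at `k = 0`) and returns the
occupied sites adjacent to it; enclosed holes are excluded. For linear
runs, `height_profile()` collapses overhangs with a per-column max
rule, and `interface_widths()` computes the global width `W_G`
(rms height fluctuation) against mean front height, plus the local
width `W_loc(l)` over sliding windows at saturation.

`measure_interface_exponents()` runs an ensemble, averages `W_G^2`
across runs at log-spaced mean-height checkpoints (recorded in
flight, so long runs need not keep their logs), and fits

* the growth exponent `beta` over the central decade of mean height
  before `W_G` reaches 80% of its saturation level (of its final
  level for runs stopped in the growth regime). Expected: about 1/3
  (KPZ) without disorder; about 0.8 (quenched Edwards-Wilkinson) at
  `rho = 0.4, k = 0`.
* the local roughness exponent `alpha_loc` on the run-averaged
  `W_loc(l)` over `l` in `[4, L/8]`. Expected: about 1/2 (KPZ).

Default problem sizes are `L = 256` grown to six times `L^1.5` (well
past the Family-Vicsek crossover) for the homogeneous ensemble, and
`L = 512` grown to mean height 1000 (growth regime; near-critical
saturation would require far larger widths) for the disordered one.
These sizes resolve the exponents to roughly +-0.03 across master
seeds.

`estimate_critical_density()` scans `rho` at `k = 0`, records the
fraction of colonies that span from the center to the lattice border,
and interpolates the logistic 1/2 crossing. At `L = 128` with 100
replicates per density the crossing lands slightly above the
asymptotic percolation value (a finite-size shift of order
`L^{-3/4}`, i.e. a few hundredths at this lattice size).

### Lineages and coalescence

`build_tree()` turns the division log into a parent map with birth
times and depths; leaves are the final front cells.
`lineage_fluctuations()` measures how far lineages wander sideways:
for each front leaf, the reference ray runs from the colony center
through that leaf, and walking the lineage back to the founder the
perpendicular deviation from the ray is recorded at each forward-time
bin; the pooled rms `l_perp(t)` is fitted as `t^xi` over the central
decade of the well-populated bins.

Two design choices deserve explanation, because the obvious
alternatives fail in measurable ways:

* **The forward-time clock is the number of divisions along the
  lineage** (tree depth), not the radial distance. For homogeneous
  colonies the two are proportional and give the same exponent. In
  strongly disordered colonies, however, the front advances
  intermittently -- lineages spend long stretches confined in pinned
  regions while barely gaining radius -- so the radius clock
  compresses their late history and the apparent exponent never
  stabilizes (it slides from about 1 at small radii, where the
  deviation just measures angular spread, to below the asymptote).
  Depth is the clock in which the `l_perp ~ t^{1/z}` scaling law is
  formulated, and in it both conditions show a clean plateau. The
  radius abscissa remains available (`abscissa = "radius"`).
* **A per-lineage bridge standardization.** The leaf-anchored ray
  forces the deviation to vanish at the leaf, so the raw pooled curve
  is systematically flattened at late times, like a Brownian bridge
  relative to a free walk. Each squared deviation is therefore
  divided by `1 - t / t_leaf` (its own lineage's anchor), and bins
  beyond `0.8 t_leaf` are dropped where the factor becomes singular.
  The standardization was validated on the homogeneous control, where
  the exact KPZ value `xi = 2/3` is recovered, and then applied
  unchanged to the disordered condition. The alternative
  least-squares reference ray (`ray = "lsq"`) is offered for
  comparison but absorbs the lineage's coherent angular drift --
  the dominant fluctuation mode -- and underestimates `xi`.

`pair_coalescence()` computes, for (sub)sampled pairs of front cells,
their distance `dx` and the backward time `T2` to their most recent
common ancestor, normalized by the maximal front distance and the
final time; `coalescence_profile()` bins mean `T2` against `dx` and
`persistence_curve()` gives `U(T2)`, the probability that a close pair
(below a configurable `dx` cutoff, default 0.05) has not yet
coalesced. The MRCA search walks both lineages to equal depth and then
up in lockstep; the suite checks it against brute-force path
intersection on small trees.

### Clones

`collect_clones()` groups mutant sites by clone id, flags clones with
at least one site on the final front as *sectors* (the rest are
*bubbles*), and, for clones of area at least 5, measures shape in the
radial frame through the clone centroid: `l_par` is the extent of the
site projections on the center-to-centroid ray, `l_perp` the extent on
the perpendicular, `angle` the principal-axis orientation folded to
`[0, pi/2]`.

`clone_shape_anisotropy()` fits `l_perp ~ l_par^zeta` on log-binned
lengths (median per bin, at least 10 clones per bin). By default only
bubbles enter: a surviving sector's width follows the deterministic
wedge opening of the expansion rather than boundary-fluctuation
scaling, and the few large sectors dominate the top bins badly enough
to push the homogeneous fit far above the KPZ value 2/3.

`fit_bubble_tail()` fits the survival function of bubble areas as a
power law. At reachable colony sizes the survival steepens
continuously toward the finite-size shoulder, and the true scaling
regime is confined to small areas (it widens slowly with `N`); the
default window is areas 2-64, and the reproduction protocol measures
the tail on larger colonies (`N` of 5e5-2e6) than the `N = 1e5` used
for the other clone statistics, precisely because the window is
cleaner there.

### Selection response and the rate of adaptation

`sweep_fmt()` grows seeded ensembles across a grid of selection
coefficients and records the final mutant frequency
`f_MT = (mutant sites) / N`. `fit_selection()` fits the heuristic
parametrization `f_MT(s) = f0 * exp(ks * s)` by (weighted) least
squares in log space -- the form is exactly linear there, so no
nonlinear fitting is needed; `f0` is the neutral diversity and `ks`
the selection efficacy. `rescale_master_curve()` collapses many
conditions onto `exp(ks * s)` and reports the rms log deviation.
The default `s` grid spans -0.15 to +0.2 in steps of 0.05, mirroring
the experimentally accessible range of fitness effects.

`dfe_density()` is the two-sided exponential distribution of fitness
effects with beneficial mean `s_bar` and deleterious-to-beneficial
ratio `R` (deleterious mean `s_bar * R`); mass fractions are
`1/(1+R)` and `R/(1+R)`. `rate_of_adaptation()` evaluates
`integral D(s) * s * f_MT(s) ds` by trapezoid quadrature on the
linearly interpolated sweep (step 0.005), with closed-form exponential
tail corrections holding `f_MT` at its boundary values; it refuses to
extrapolate if more than 1% of the DFE mass lies outside the
tabulated range. For constant `f_MT = c` the integral is analytically
`c * s_bar * (1 - R)`, which the suite checks -- and which already
shows the sign flip: once heterogeneity drives `ks` to zero, any
`R > 1` makes the expansion accumulate load.

### Mutation-rate inference

`simulate_plating()` emulates a 48-replicate fluctuation-style assay:
a Poisson(10) inoculum (zero draws redrawn), seven discrete
generations of doubling (about 10 to about 1000 cells), binomial
mutation per wild-type division, and mutant growth at relative rate
`1 + s` applied as an expected-offspring factor `2^(1+s)` per
generation. Endpoint mutant fractions are the observable; full
birth-time stochasticity is not identifiable from them and is not
modeled.

`ml_infer_mu()` estimates `mu` by simulation-based maximum likelihood:
for each point of a `(mu, s)` grid it simulates an ensemble, estimates
the sampling density by a histogram on `[0, 1]` (empty bins floored at
one count so every observation stays finite), and sums log densities
over the observations; `s` is a free nuisance parameter. The
uncertainty `delta_mu = 1/sqrt(|curvature|)` uses the *profile*
likelihood over `s`, with the curvature from a local quadratic fit
around the maximizer (a plain 3-point stencil is too noisy under
Monte Carlo error, and the fixed-`s` slice understates the
uncertainty). Two resolution choices matter and were set by
measurement: 200 histogram bins (coarse 50-bin histograms leave only a
handful of occupied bins for the small fractions this assay produces
and bias the estimate upward by about 25%), and enough simulations per
grid point (the package default is 5000; the recovery property in the
test suite uses 4000, and accuracy keeps improving toward the 5e4
regime). In the recovery Monte Carlo at truth `mu = 0.003`, `s = 0.3`,
the `+-2 delta_mu` interval covers the truth in at least 90% of
repetitions.

## The workbench

`load_plan()` / `run_plan()` execute named experiments (percolation,
exponents, fmt_sweep, lineages, adapt_rate, infer_mu) from a flat JSON
plan with a mandatory seed, writing headed CSV tables and a JSON
manifest with md5 checksums; rerunning a plan reproduces every file
bit for bit. Seeds fan out deterministically through `fan_seed()`
(a counter scheme, so grids can be extended without disturbing
existing runs). A thin command-line wrapper over the same functions is
installed at `system.file("cli/heterospread", package =
"heterospread")`.

## What the synthetic data do and do not emulate

The generator's defaults are the study conditions throughout:
`N = 1e5`, `mu = 5e-4` for the population-genetic ensembles, 50
colonies for lineage statistics, the `(rho, k)` grid spanning the
percolation transition, and the plating assay's 48 replicates times
seven generations. Uncorrelated site disorder is a deliberate
idealization: real patterned substrates have correlated ridges and
troughs with a characteristic length scale, which changes which clones
"feel" the heterogeneity; with uncorrelated disorder the heterogeneity
acts on all scales down to the lattice constant. Passing tests
therefore demonstrate the model's internal physics (universality
classes, pinning, selection-efficacy collapse), not quantitative
agreement with any particular experimental substrate.

## Known limitations

* Exponent estimates at desk scale carry finite-size systematics:
  effective exponents drift with colony size (most visibly the
  bubble-tail slope), fit windows are stated alongside every fit, and
  tolerances in the test suite are set accordingly.
* The depinning exponent `theta` and the crossover length `l(rho)`
  are not measured; the continuum stochastic PDEs of the interface
  theory are not integrated.
* Only one mutant type per run; no back mutation; 4-neighbourhoods
  only.
* Near `rho_c` with `k = 0` a substantial fraction of seeds pin
  before reaching `n_target`; ensemble functions skip and refill
  these (reported via `n_attempts`), which conditions the ensembles
  on survival -- the same conditioning a fixed-final-size protocol applies
  by growing all populations to equal size.

## A worked example

```{r example, eval = FALSE}
library(heterospread)

cfg <- sim_config("radial", rho = 0.4, k = 0, mu = 5e-4,
                  n_target = 1e5, seed = 1)
res <- run_colony(cfg)
res
mutant_frequency(res)

tree <- build_tree(res)
fl <- lineage_fluctuations(tree)
fl$xi

cl <- collect_clones(res)
head(cl[order(-cl$area), ])
```
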