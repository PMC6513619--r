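# heterospread

Population genetics of range expansions in heterogeneous
environments: a generalized Eden lattice model with quenched disorder,
selection and mutation, plus the analysis stack needed to study what
environmental heterogeneity does to an expanding population.

## The problem

When a population expands across space -- a bacterial colony spreading
over agar, a tumor invading tissue, a species shifting its range --
only the thin layer of individuals at the front reproduces, so genetic
drift is strong and a mutation's fate depends heavily on *where* it
arises. Real environments are not uniform: patches of poor substrate
locally slow or stop ("pin") the front. This package implements a
minimal lattice model of that situation and the measurements that
characterize its consequences, for researchers in spatial population
genetics and the statistical physics of growing interfaces.

The model: cells occupy a square lattice and only cells with an empty
4-neighbour can divide. A division event picks an eligible cell with
probability proportional to its rate and places a daughter on a random
empty neighbour. Disorder sites (density `rho`) reduce their
occupant's rate by a transparency factor `k`; at `k = 0` they are
impassable obstacles, and expansions fail above the site-percolation
threshold (obstacle density about 0.407). Wild-type divisions mutate
with probability `mu`; mutants grow at relative rate `1 + s`. The
final mutant frequency follows `f_MT(s) = f0 * exp(ks * s)`, where the
fitted *neutral diversity* `f0` and *selection efficacy* `ks`
summarize how heterogeneity (rho, k) reshapes the balance of selection
and chance. Interface roughness (Family-Vicsek exponents alpha, beta),
lineage wandering (`l_perp ~ t^xi`), clone-size survival
(`P(A > a) ~ a^(-1/(1+z))`) and pair-coalescence times characterize
the two regimes: KPZ-like smooth growth without disorder, quenched
Edwards-Wilkinson roughening near the pinning transition.

## What is in the package

* `sim_config()`, `run_colony()`, `run_linear()` -- the compiled
  simulator (radial and flat-front geometries, full division logs),
  with `generate_disorder()`, `replay_log()`, and a pure-R reference
  stepper (`eden_state()`, `eden_step()`, `make_fixture()`).
* `extract_front()`, `height_profile()`, `interface_widths()`,
  `fit_power_law()`, `expansion_speed()`,
  `estimate_critical_density()` -- fronts, widths, speeds, the
  pinning threshold.
* `build_tree()`, `lineage_fluctuations()`, `pair_coalescence()`,
  `coalescence_profile()`, `persistence_curve()` -- ancestry of the
  front, lineage-fluctuation exponent, coalescence statistics.
* `collect_clones()`, `clone_size_distribution()`,
  `clone_shape_anisotropy()`, `fit_bubble_tail()`,
  `mutant_frequency()` -- clone analytics.
* `sweep_fmt()`, `fit_selection()`, `rescale_master_curve()`,
  `dfe_density()`, `rate_of_adaptation()`, `adaptation_sweep()` --
  selection response and the DFE-weighted rate of adaptation.
* `simulate_plating()`, `plating_log_likelihood()`, `ml_infer_mu()`
  -- simulation-based maximum-likelihood mutation-rate inference
  from replicate plating counts.
* `load_plan()`, `run_plan()`, `measure_interface_exponents()`,
  `measure_radial_ensemble()` -- reproducible experiment
  orchestration with seed fan-out and checksummed manifests, plus a
  CLI at `system.file("cli/heterospread", package = "heterospread")`.

## A worked example

```r
library(heterospread)

# a homogeneous colony: N = 1e5 cells, neutral mutations at mu = 5e-4
smooth <- run_colony(sim_config("radial", rho = 0, mu = 5e-4,
                                n_target = 1e5, seed = 1))
smooth
#> <eden_result> radial rho=0 k=0 s=0 mu=5e-04: 100000 sites, t=149.7, reached_n
mutant_frequency(smooth)
#> [1] 0.01325
cl <- collect_clones(smooth)
nrow(cl); sum(cl$is_sector); max(cl$x_norm)
#> [1] 45
#> [1] 5
#> [1] 0.00678

# the same population size at the critical obstacle density
rough <- run_colony(sim_config("radial", rho = 0.4, k = 0, mu = 5e-4,
                               n_target = 1e5, seed = 1))
rough
#> <eden_result> radial rho=0.4 k=0 s=0 mu=5e-04: 100000 sites, t=806.8, reached_n
mutant_frequency(rough)
#> [1] 0.99418
```

The contrast is the point: in the smooth colony 45 neutral clones
arose and the largest reached 0.7% of the population, while in the
pinned, near-critical colony a single early clone that happened to sit
on an open expansion path swept to 99% -- chance, not fitness, decides
who expands. Ensemble versions of these measurements
(`measure_radial_ensemble()`, `sweep_fmt()`) quantify the effect:
lineage fluctuations roughen from `xi ~ 2/3` to `~ 0.86`, and the
selection efficacy `ks` collapses to zero as `rho` approaches the
pinning threshold.

```r
est <- estimate_critical_density(k = 0, L = 64,
                                 rho_grid = seq(0.34, 0.47, 0.01),
                                 reps = 40, seed = 99)
round(c(est$rho_c, est$stderr), 3)
#> [1] 0.426 0.003   # quick scan at L = 64; L = 128 lands nearer 0.41
```

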