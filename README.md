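# trxkin — kinetic analysis of time-resolved gas-phase x-ray scattering

When a femtosecond UV pump pulse photolyses a molecule and a hard x-ray
probe pulse scatters off the evolving sample, the percent-difference
scattering map %ΔI(q,t) records the entire reaction: every transient
species α contributes its own scattering signature S_α(q) weighted by its
population F_α(t),

    ΔI_iso(q,t) = γ Σ_α S_α(q) F_α(t),

with γ the optically excited fraction. `trxkin` implements this analysis
end to end for the deep-UV (200 nm) S–S bond rupture of 1,2-dithiane — the
prototype cyclic disulfide behind the photostability question of protein
disulfide bonds — and validates it on synthetic data with the experiment's
statistical structure. It is aimed at ultrafast-scattering practitioners
who want a transparent, testable reference implementation of global
kinetic fitting for pump-probe scattering maps.

The package provides:

* **IAM scattering** (`debye_pattern`, `mixture_pattern`,
  `percent_difference`): rotationally averaged Debye-equation patterns from
  tabulated Cromer–Mann form factors, incoherent fragment mixtures, and
  built-in approximate structures of dithiane, the ring-opened biradical
  and the fragmentation channels (`reference_structures`); XYZ I/O.
* **Reaction kinetics** (`default_dt_network`, `solve_populations`,
  `asymptotic_fractions`): the six-species network of the dithiane
  photoreaction, solved analytically with Gaussian instrument-response
  convolution in closed form.
* **Global fitting** (`global_fit`, `solve_patterns_linear`,
  `estimate_gamma`): multi-start variable projection over the rate
  constants with species patterns solved linearly — either fully free
  (which identifies only the exponential spectrum; the package documents
  this rotational ambiguity) or anchored to theory-simulable patterns,
  which makes all eight rates and γ identifiable from a single map.
* **Anisotropy** (`render_detector_image`, `decompose_iso_aniso`):
  simplified detector images with pump-induced P₂ alignment and their
  isotropic/anisotropic decomposition.
* **Ensembles** (`toy_thermal_pool`, `ensemble_pattern`): ensemble-averaged
  scattering of vibrationally hot species from geometry pools (toy thermal
  sampler or multi-frame XYZ trajectories).
* **Synthetic data** (`scenario_config`, `generate_map`, `run_recovery`):
  seeded synthetic maps at the study conditions with sealed ground truth,
  and the generate→fit→score recovery benchmark.

## Worked example

```r
library(trxkin)

# the reaction network with the published rate constants
net <- default_dt_network()
f <- asymptotic_fractions(net, dt_rates())
round(f, 3)
#>  FA-2    FB
#> 0.383 0.617        # two-particle channel dominates, ~62/38

# a synthetic percent-difference map at the study conditions:
# gamma 4.5%, IRF 238 fs, 0.1-point noise, 60 q-points x 80 delays
cfg <- scenario_config(seed = 1)
map <- generate_map(cfg)

# anchored multi-start global fit (products + hot species fixed to their
# IAM / ensemble-IAM patterns; DT* pattern and all rates free)
fit <- global_fit(map, cfg$network,
                  fit_config(restarts = 20, seed = 2024,
                             anchors = iam_anchor_patterns(cfg)),
                  irf = cfg$irf)
print(fit)
#> <fit_result> chi2 = 4994, 10/20 restarts kept
#>   gamma = 0.04548 +/- 5.7e-09 (anchored)
#>   k1   = 4.791 +/- 7e-06 1/ps   (1/k = 0.2087 ps)
#>   k2   = 1.03  +/- 1.9e-06 1/ps  (1/k = 0.9712 ps)
#>   ...
```

`chi2/N = 1.04` says the model explains the map to the noise level; the
recovered time constants scatter around the generating values (240 fs,
1.05 ps, ...) within the precision one noisy map allows, and averaging over
ten independent maps (see `analysis/06_recovery_benchmark.R`) reproduces
them to a few percent.

The `analysis/` directory holds the numbered narrative drivers:
structures and patterns (`01`), kinetics (`02`), map simulation (`03`),
the global fit (`04`), the anisotropy round trip (`05`) and the recovery
benchmark (`06`). Each writes plain-text tables under `results/`.

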