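# porescale

Finite-size hydropathic scaling analysis of ion-channel pores.

Voltage-gated ion channels are tetramers in which four pore domains (PD,
the S5–S6 helices, P-helices and selectivity filter) are wrapped by four
voltage-sensing domains (VSD, segments S1–S4). How the hydropathic
(hydrophobic/hydrophilic) character of the atomic environment is organized
across *scales* around the conduction pore — from the first hydration shell
out to the protein's outer surface — bears on ion dehydration, gating and
mutational robustness. `porescale` quantifies that organization for a single
protonated structure: it profiles the pore geometry, samples atoms in nested
spheres around pore-axis points, fits sigmoid atom-packing models, and tests
whether the hydropathic imbalance is scale-invariant (power-law) below and
above the packing inflection.

## The model

For a point **p** on the (z-aligned) pore axis with atom centers
**c**ᵢ and van der Waals radii vdWᵢ:

- pore radius `R(p) = min_i(‖c_i − p‖ − vdW_i)`, nearest-atom distance
  `D(p) = min_i ‖c_i − p‖`, outer-surface radius
  `L(p) = max_i(‖c_i − p‖ + vdW_i)`;
- nested sampling spheres `l_α = D + α (L − D)/K_α`, `α = 1…K_α` (default
  `K_α = 800`), with the cumulative atom count `N(p, l_α)` counting centers
  inside each sphere;
- the cumulative hydropathic dipole field
  `h(p, l_α) = Σ_i θ(l_α − ‖c_i − p‖) · HI_i · (c_i − p)` (per-atom
  Kapcha–Rossky-style hydropathic indices HIᵢ, kcal·Å/mol), decomposed into
  the signed axial component `h_z` and the in-plane part `h_xy`;
- the hydropathic imbalance `I = ‖h_z‖ / N` and the atom-packing energy
  `AE = ‖h_z‖ / l_α` (kcal/mol).

Normalized `N` traces are fitted with four growth models — logistic,
Gompertz, modified Gompertz and Richards,
`n_RIC = A {1 + q̃·b·e^(−d l)}^(−1/q̃)` with `b = e^(1+q̃+ds)` and
`d = (t/A)(1+q̃)^(1+1/q̃)` — selected by AIC, with non-parametric bootstrap
confidence intervals. The fit yields the lag end `s`, inflection scale `ξ`
(where the radial distribution function peaks), asymptote onset `o = s + A/t`
(so the maximum packing rate obeys `t = A/os`), and the Richards shape
parameter `q̃`, related to the non-extensive entropic index by `q = 1 − q̃`.
Scale invariance is the bi-phasic power law `I ∝ l^γ_pre` on `(s, ξ]` and
`I ∝ l^γ_post` above `ξ`, detected wherever both log-log Pearson
coefficients exceed a threshold (default 0.97). The composite dipole model
`‖h_z‖ ∼ n_RIC(l) · l^γ` combines both fits and, divided by `l`, yields the
packing-energy model whose maximum on `[ν, ξ]` (ν = PD–VSD crossover scale)
estimates the PD–VSD coupling energy.

## Worked example

Every stage is testable without downloads via the bundled fixture generator,
which plants a Richards packing law and a bi-phasic dipole law
(γ_pre = +2.27, γ_post = −4.36) in a 4-fold-symmetric toy tetramer:

```r
library(porescale)

toy <- sim_channel(n_atoms = 4000, seed = 1, path = "toy_channel.pdb")
ch <- read_channel("toy_channel.pdb", hi_source = "bfactor", hi_noise = FALSE)
ch <- align_channel(ch)
ch <- annotate_segments(ch, toy$segment_map)
ch
#> Channel structure: 4016 atoms, 38025.4 Da
#>   aligned: TRUE  (mass center was [ 0.00, 0.00, 0.00 ])
#>   domains: other=16  PD=872  VSD=3128

tr <- radial_trace(ch, p = c(0, 0, 0), k_alpha = 800)
fit <- select_packing(tr$l, tr$N)
fit
#> Atom-packing fit: richards (converged)
#>    A = 1.005, t = 0.2018, s = 18.15, q_tilde = 0.5812
#>   xi = 20.411, s = 18.147, o = 23.128, os = 4.981  [A]
#>    AIC = -8131.94, MAFE = 0.003958

fit_biphasic(tr, s = fit$s, xi = fit$xi, x_axis = "physical_l")
#> Bi-phasic power-law fit (x = physical_l )
#>   pre  (18.15, 20.41]: gamma = +2.298, beta = -5.955, PC = +0.994 (n=97)
#>   post (20.41, 27.51]: gamma = -4.350, beta = +14.085, PC = -0.999 (n=303)
```

The selected model is the planted Richards family (`q̃` = 0.58 vs the
planted 0.54, i.e. entropic index `q` ≈ 0.42), the inflection sits at
20.4 Å, and the planted dipole exponents +2.27/−4.36 are recovered as
+2.30/−4.35 with |PC| ≥ 0.99 — a scale-invariant, "out"-oriented
(h_z < 0) dipole regime. A whole-pore scan aggregates this point-by-point:

```r
pore_scaling(ch, z_step = 1, z_range = c(-4, 4), k_alpha = 400,
             x_axis = "physical_l")
#> Pore hydropathic-scaling analysis
#>   9 pore points (z in [-4.00, 4.00], step 1.00), k_alpha = 400
#>   packing fits converged at 9/9 points; models: richards=9
#>   ...
#>   scale-invariant region(s): [0.00, 0.00]
#>   |xi - nu| = 3.30 +/- 1.29 A (Spearman +0.40 +0.00)
```

Only the planted pore point (z = 0) passes the PC ≥ 0.97 screen, i.e. the
scan localizes the planted scale-invariant region.

To analyze a real structure, supply a *protonated* PDB file (atom counts
depend on the protonation tool) and a segment map
(see `inst/extdata/navab_segments.tsv` for an approximate NavAb example):

```sh
Rscript inst/cli/porescale.R prepare --pdb channel.pdb --segments segments.tsv --out run/
Rscript inst/cli/porescale.R analyze --run run/ --out results/ --k-alpha 800
```

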