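---
title: "Hydropathic scaling analysis of ion-channel pores: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydropathic scaling analysis of ion-channel pores: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(porescale)
```

`porescale` asks a thermodynamically flavoured question of a single channel
structure: as one grows a spherical "system" of atoms around a point on the
pore axis, how do cumulative hydropathic properties scale with system size?
Extensive behaviour would have them grow linearly with the atom count;
power-law (scale-invariant) behaviour of the *hydropathic imbalance* signals
long-range organization of the hydropathic atomic mixture. This vignette
records the model, its assumptions, the tunable parameters, and the
numerical/design decisions, in the package's own words.

## Input assumptions

The pipeline operates on a **protonated** atomic structure in PDB format.
Hydrogens carry hydropathic indices of their own, so an unprotonated file is
rejected outright. Atom counts (and therefore every cumulative trace) depend
on the protonation tool used upstream; `porescale` performs no protonation
itself. Waters and heteroatoms are excluded by default (`include_het`);
alternate locations collapse to the highest-occupancy conformer.

Three chemistry tables attach per-atom mass, van der Waals radius and
hydropathic index (`chemistry_tables()`): Bondi radii, standard atomic
weights, and a rule-based ±0.5 atomic hydropathic dichotomy (N/O/S/P, ions
and their bound hydrogens polar −0.5; carbons and carbon-bound hydrogens
apolar +0.5; carbonyl, carboxylate, amide and guanidinium carbons polar).
The dichotomy is a reconstruction of the published atomic hydropathicity
scales from their classification rule, not a transcription of any specific
table; every entry can be overridden per element or per (residue, atom) from
R or YAML, which is the supported way to substitute an exact published table.

A weak Gaussian noise χ ~ N(0, 0.001) can be added once per atom to the
indices at load time (`hi_noise`, seedable, default on). Its role is purely
numerical: it keeps the dipole field non-zero at exactly symmetric
configurations while perturbing the imbalance by well under 1% on realistic
index magnitudes (a property the test suite checks).

## Geometry and the pore-axis set

The structure is translated to its mass center and rotated so that the
eigenvector of the mass-weighted inertia tensor with the *smallest* moment —
the long axis of an elongated tetramer — coincides with z. This convention
is a design decision (the choice of axis estimator is not dictated by the
data); an explicit `axis` override is available, and the extracellular →
intracellular orientation of z cannot be inferred from coordinates, so a
`flip` flag resolves it. When the tensor is already diagonal the rotation
reduces to an axis permutation, which makes alignment exactly idempotent.

Pore points are placed on a uniform z-grid (default `z_step` 0.5 Å). The
default extent is the open lumen — the z-range where the pore radius R is
positive — because that is where "pore" is meaningful; both are
configurable. R may be negative at occluded points (e.g. a closed activation
gate) and is reported, not clamped. The PD–VSD crossover scale ν(p) is, by
default, the distance from p to the nearest VSD-labelled atom; an
alternative `"fraction"` mode returns the smallest radius at which VSD atoms
reach a given fraction of the sample. Both are design decisions — the
geometric crossover has no unique definition — and the default was chosen as
the simplest monotone proxy.

## Radial sampling

`K_α` nested spheres interpolate from D(p) (exclusive) to L(p) (inclusive);
the default `K_α = 800` gives sub-0.1 Å scale resolution on a typical
tetramer and matches the resolution at which the packing traces were
designed to be analysed. Boundary convention: an atom exactly on a sphere is
counted inside (θ(0) = 1), which makes the final count exactly the total
atom number. Distances are center-to-point; van der Waals radii enter R and
L but not the sampling metric. One distance sort per pore point plus
cumulative sums produce all traces; the test suite pins this implementation
to an exhaustive per-sphere recount oracle.

Per sphere, the package reports the atom count N, the signed axial dipole
component h_z and in-plane magnitude ‖h_xy‖ (kcal·Å/mol), the hydropathic
imbalance I = ‖h_z‖/N (entries with N = 0 are masked) and the packing
energy AE = ‖h_z‖/l (kcal/mol). Using ‖h_z‖ for ‖h‖ assumes approximate
rotational symmetry about the pore axis — true for a tetramer to a good
approximation, exact for the synthetic fixtures — and the decomposition
identity ‖h‖² = ‖h_xy‖² + h_z² is tested exactly.

## Packing models

Four sigmoids share the growth-curve parametrization (A asymptote; t maximum
packing rate, 1/Å; s lag end, Å): logistic, Gompertz, modified Gompertz
(adds a second rise with parameters w, l_shift) and Richards (adds the shape
parameter q̃ > −1). Richards contains the logistic (q̃ = 1) and Gompertz
(q̃ → 0) as special cases; evaluation switches to the Gompertz limit below
|q̃| < 1e−6, and all exponentials are clamped at ±700 to stay finite.
Inflection points use the closed forms ξ = s + A/(2t) (logistic),
s + A/(et) (Gompertz), s + (1+q̃)/d (Richards); the modified Gompertz root
is found numerically from the second derivative. The shape parameter maps
onto a non-extensive entropic index as q = 1 − q̃, which the fit reports.

Fitting is bounded Levenberg–Marquardt least squares on max-normalized
traces, with multi-start initialization (A₀ = max; s₀ at 10% and 25% of the
rise; t₀ = steepest finite-difference slope; q̃₀ ∈ {0.2, 1, 2}) and soft
bounds A ∈ (0, 1.5], t > 0, s ∈ [0, max l], q̃ ∈ (−0.99, 10]. Multi-start
exists because single-start solvers on Richards-type models are known to
jump between local minima along a pore scan; non-convergence is *flagged*
with diagnostics, never silent. Model selection minimizes
AIC = n·ln(RSS/n) + 2k over the converged candidates. Confidence intervals
use a non-parametric case-resampling bootstrap (percentile, 100 replicates
by default, seedable); a replicate failure rate above 50% triggers a
widened-intervals warning.

**Asymptote onset.** The identity t = A/os ties the maximum packing rate to
the size of the inflection domain os = o − s. We define o by the tangent
construction — the tangent at ξ reaches the asymptote at o = s + A/t —
which makes the identity exact for every model; it is also the construction
under which s is the lag end (the same tangent crosses zero at s). A
threshold variant (`o_method = "threshold"`, smallest l with n ≥ (1−ε)A,
ε = 0.01) is provided for sensitivity checks, but it breaks the identity by
a model-dependent factor (≈1.65 for the logistic), so it is not the default.

## Bi-phasic scaling analysis

The imbalance trace is fitted by ordinary least squares in log-log space on
two segments: (s, ξ] and (ξ, …], each requiring ≥ 3 positive points;
Pearson coefficients of the same pairs measure power-law quality. Two
abscissae are supported because the sphere radius is an *affine*, not
proportional, function of the sphere index: `"alpha_index"` (log α, the
convention for aggregate, figure-level fits) and `"physical_l"` (log l, the
convention in which the composite dipole model is written). The two slopes
differ and both pathways are exposed; per-point exponents reported by the
pipeline use the axis chosen in its configuration.

The post-inflection segment is capped at the last scale where an atom still
enters the sphere: beyond the outermost atom center every cumulative
quantity is constant by definition (the remaining spheres only pad out to
the van der Waals outer surface), so those points would inject a known-flat
artifact into the fit. For a real tetramer the cap trims a sliver (the
outermost van der Waals radius out of an 80+ Å range); for compact synthetic
fixtures it matters, and the planted exponents are only recovered with it.

Scale-invariant regions are maximal contiguous z-runs where
min(|PC_pre|, |PC_post|) ≥ 0.97; the threshold default is the weakest
correlation we would still call "accurately power-law", and it is exposed as
`pc_threshold`. Aggregation across pore points (means with 2.5/97.5
percentile bands of max-normalized traces on the shared index grid; boundary
indices ⟨α_s⟩, ⟨α_ξ⟩, ⟨α_ν⟩, ⟨α_o⟩ as means of per-point nearest indices)
is likewise a design decision: averaging the per-point boundary *indices*
was chosen over locating boundaries on the averaged trace because it keeps
each point's own fit authoritative. The composite dipole model
‖h_z‖ ∼ C·n_RIC(l)·l^γ estimates the proportionality constant per phase by
log-scale least squares (the underlying relation is stated only up to
proportionality) and reports mean absolute relative errors for the pre and
post segments and for extrapolation below the lag end. The coupling energy
is the AE maximum on [ν, ξ].

## The synthetic generator

`sim_channel()` emulates exactly the statistical structure the analysis
assumes, and nothing else: a 4-fold-symmetric, inversion-paired point cloud
on spherical shells whose cumulative count around the packing center follows
a prescribed sigmoid (default: the Richards regime A = 1, t = 0.2,
s = 18.02 Å, q̃ = 0.54 — the selectivity-filter-side parameter regime this
kind of analysis recovers on a real tetramer), with per-atom indices solved
shell-by-shell so that ‖h_z‖(l) = C·N(l)·l^γ with γ_pre = +2.27 below the
packing inflection and γ_post = −4.36 above it, "out" orientation
(h_z < 0), continuous at ξ. Because 90° rotations and negation commute with
decimal rounding, the symmetry survives PDB coordinate precision: the mass
center, the z inertia axis and the cancellation of h_xy are machine-exact
after a write/read round trip. A clear cylindrical lumen (radius 6 Å), a
pole-biased direction distribution (so z is the smallest-moment axis), a
narrow 4-fold ring at the constriction and a mass-balancing counter-ring
complete the geometry. Indices are carried in the B-factor column at 3
decimals (`read_channel(hi_source = "bfactor")`).

What it does **not** emulate: real residue chemistry, steric plausibility,
clash-free packing, a curved pore axis, heterogeneity between subunits, or
crystallographic noise. Passing tests on these fixtures therefore
demonstrate correctness of the *computational chain* (geometry → sampling →
fitting → scaling detection) under the stated statistical conditions, not
agreement with any particular experimental structure. Defaults (4000 atoms,
shell spacing 0.25 Å, radial extent 8–27.5 Å) were chosen once so that every
shell in the rising phase receives atoms (the planted dipole increments must
be realizable by the atoms present) and are the conditions under which the
acceptance properties are evaluated.

## Numerical choices and degenerate inputs

- Constant traces are flagged as degenerate, never fitted.
- Fewer than 8 trace points is an error for fitting; fewer than 3 positive
  points per log-log segment is an error for scaling fits.
- A structure with no hydrogens, an element missing from the tables, an
  ambiguous (degenerate-inertia) axis, overlapping segment-map ranges, and
  an empty [ν, ξ] window are hard, named errors.
- Spearman correlations on fewer than 3 points report NA rather than a
  value; ties use average ranks.
- `k_alpha = 1` runs degrade gracefully (geometry and traces, no fits).
- Fixed seeds make every stochastic step (index noise, fixture geometry,
  bootstrap) bit-reproducible; noise is applied under a local RNG state so
  the caller's RNG is untouched.

## Problem sizes in the test suite

The suite exercises 500–1000-atom random clouds against brute-force oracles
(100 replicates for the sampling equivalence), 2400–4000-atom toy channels
for end-to-end recovery, 100 noisy traces at K_α = 800 for the Richards
calibration (median parameter bias and 95% bootstrap coverage with 100
replicates each), and 200 seeds for power-law recovery — sizes chosen so the
whole suite runs in well under a minute on one core while keeping every
statistical check at its stated strength.

## Known limitations

- The straight principal axis is a proxy; strongly curved or tilted pores
  would need an external pore-finding tool, which is out of scope.
- The bundled hydropathic dichotomy is rule-based; users wanting an exact
  published per-atom scale should supply it via `chemistry_tables()`.
- ν(p) is a geometric proxy with two modes; neither is canonical.
- Aggregate-level exponents depend on the aggregation scheme (documented
  above) and on the index-vs-physical abscissa choice; both are reported in
  the output metadata for that reason.
- Reproducing published numbers for a specific channel requires the same
  protonated structure and segment map; with a different protonation tool,
  atom counts and all cumulative traces shift accordingly.
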