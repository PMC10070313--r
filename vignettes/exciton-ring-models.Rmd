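---
title: "Exciton models of LH2 pigment rings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exciton models of LH2 pigment rings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitonring)
```

## The physical problem

LH2 antenna complexes of purple bacteria hold two concentric rings of
bacteriochlorophyll *a* (BChl): the strongly coupled B850 ring with an
α/β pigment pair per repeating unit, and the weakly coupled B800 ring
with one pigment per unit. Absorption in the near infrared is governed
by Frenkel excitons: delocalized superpositions of the pigments' Qy
excitations. Ring symmetry concentrates nearly all dipole strength in
the degenerate k = ±1 pair, so shifts of that bright state move the
B850 band. The heptameric LH2 of *Mch. purpuratum* absorbs near 830 nm,
blue of the 850–860 nm band of the more common nonameric rings such as
*Rbl. acidophilus* LH2, and this package exists to dissect that kind of
difference into its ingredients: site energies, excitonic couplings,
ring size, charge-transfer (CT) mixing, and disorder.

## The model

### Hamiltonian

The electronic model is the CT-augmented Frenkel exciton Hamiltonian

$$
\hat H = \sum_i^{N_p} \epsilon_i |i\rangle\langle i|
 + \sum_{ij}^{N_p} V_{ij} |i\rangle\langle j|
 + \sum_m^{N_{\rm CT}} \epsilon^{\rm CT}_m |m\rangle\langle m|
 + \sum_{im} \big(V^{\rm CT}_{im}|i\rangle\langle m| + h.c.\big),
$$

with site energies $\epsilon_i$ (cm⁻¹), excitonic couplings $V_{ij}$,
and CT states restricted to adjacent α/β pairs of the B850 ring. CT–CT
couplings are zero, CT states carry no transition dipole and no
rotational strength, and omitting the CT manifold recovers the standard
Frenkel Hamiltonian. `assemble_hamiltonian()` builds the real symmetric
matrix; `diagonalize()` returns ascending eigenvalues with a
deterministic eigenvector gauge (leading significant coefficient
positive) so degenerate pairs are reproducible.

Per-state observables follow the standard exciton expressions:
transition dipoles $\mu_k = \sum_i c_{ki}\mu_i$, dipole strengths
$|\mu_k|^2$, rotational strengths
$R_k = \tilde\nu_k \sum_{i<j} c_{ki}c_{kj}\,
(\mathbf r_i-\mathbf r_j)\cdot(\mu_i\times\mu_j)$, symmetry labels from
the dominant discrete-Fourier component of the per-unit coefficient
pattern (states below 60% dominance are "mixed"), and the inverse
participation ratio $1/\sum_i c_{ki}^4$ as the effective
delocalization length. Two exact sum rules are enforced by tests:
dipole-strength conservation without CT states, and the conservative CD
rule $\sum_k R_k/\tilde\nu_k = 0$.

### Geometry and couplings

Pigment geometry is reduced to centers (the NB/ND midpoint), unit
dipole axes (the NB→ND direction) and a dipole magnitude in Debye,
extracted from PDB structures (`extract_ring_from_structure`, via
bio3d) or built as ideal Cn rings (`build_ideal_ring`). The orientation
factor κ and the point-dipole coupling
$V = C\,\kappa\,\mu_p\mu_q/R^3$ use the vacuum constant
$C = 5034.1\ \mathrm{cm^{-1}\,\AA^3\,D^{-2}}$ with **no screening**:
published LH2 couplings already include polarizable-environment
effects that cannot be recomputed from geometry alone, so screening is
left as an explicit user multiplier rather than a hidden factor.

**Dipole gauge.** In the packaged ring geometries the α and β dipoles
of the B850 ring alternate direction around the ring (the physical
NB→ND alternation). In this gauge, the positive printed
nearest-neighbor coupling magnitudes place the bright k = ±1 pair near
the *bottom* of the exciton band, so stronger couplings red-shift the
bright state — the behavior the mixed-model analysis probes. The weak
second-neighbor αα/ββ couplings are stored signed (negative defaults).
Packaged CT states couple with a (+V, −V) pattern to the two sites of
their pair, the gauge-consistent image of a symmetric physical
coupling, which lets them mix with (and red-shift) the low-energy
bright band.

### Disorder

Static disorder follows the environment/vacuum decomposition
$E^{\rm static}_i = E^{\rm env}_i - E^{\rm vac}_i +
\langle E^{\rm vac}\rangle$: the environment's slow modulation is kept
as static disorder while fast intramolecular fluctuations are removed;
the distribution keeps the mean of $E^{\rm env}$ and the standard
deviation of $E^{\rm env}-E^{\rm vac}$ (`static_site_energy`, with a
Monte-Carlo test of the mean/variance contract).

The synthetic-data generator (`synthesize_md_like_ensemble`) emulates
the statistical structure of per-frame MD/QM output: per-frame site
energies drawn as Normal(class mean, σ_static(class)) and couplings as
base values plus Normal(0, σ_V) on nonzero entries. A second layer of
i.i.d. Gaussian diagonal disorder (`sample_realizations`,
σ_add(class)) stands in for the slow conformational heterogeneity that
MD under-samples. Site-energy and coupling fluctuations are sampled
independently (their joint distribution is not specified by the data
the model emulates); a correlation-matrix hook exists for future use.
Everything is reproducible bitwise from (model, seed), and
`estimate_disorder()` closes the loop by recovering the generating
parameters from an ensemble (tested at σ ∈ {20, 60, 120} cm⁻¹,
n = 2000, within 5%).

What the generator does **not** emulate: non-Gaussian tails, slow
conformational switching (e.g. H-bond breaking that makes B800 site
energies bimodal), frame-to-frame correlation along a trajectory, and
correlated site/coupling fluctuations. Passing tests therefore show
parameter-recovery consistency and correct ensemble statistics, not
fidelity to any particular molecular system.

### Lineshapes

The spectral density is the field-standard composite
$J(\omega) = J_{\rm env} + J_{\rm vib}$: an overdamped Drude–Lorentz
term $2\lambda_{\rm env}\omega\omega_c/(\omega^2+\omega_c^2)$ plus
underdamped Brownian oscillators for intramolecular modes. Each term
contributes its λ to the total reorganization energy, verified by
quadrature. Defaults (λ_env = 80 cm⁻¹, ω_c = 60 cm⁻¹, four vibrational
modes at 560–1520 cm⁻¹) are plain config values; the environmental
part should be treated as a free parameter tuned to observed band
widths.

Homogeneous spectra use the second-order cumulant expansion in the
exciton basis: $g_k(t) = \sum_i c_{ki}^4\, g(t)$ (exchange narrowing;
all Qy sites share one site spectral density, CT coefficients add no
bath coupling), with

$$
g(t) = \frac 1\pi \int_0^\infty d\omega\,
\frac{J(\omega)}{\omega^2}\Big[\coth\!\Big(\frac{\omega}{2k_BT}\Big)
(1-\cos\omega t) + i(\sin\omega t - \omega t)\Big]
$$

and optional lifetime broadening from secular Redfield rates
(`redfield_lifetimes`). This is deliberately one level simpler than
full-cumulant (FCE) lineshape theories that add non-secular and
non-Markovian terms; the choice is documented as an approximation and
an extension point, and no packaged result depends on quantities
sensitive to that difference. Known consequences: no vibronic
sideband intensity borrowing between exciton states and no
non-secular band narrowing.

Absorption weights each state's line by $\tilde\nu\,|\mu_k|^2$; CD
weights it by $R_k$ **without** a second frequency prefactor, because
$R_k$ already carries $\tilde\nu_k$ — double counting would break the
conservative (equal-and-opposite-lobe) structure of exciton CD beyond
the physical $\Delta\tilde\nu/\tilde\nu$ residual.

### Numerical choices

* Units are fixed everywhere: cm⁻¹, Å, Debye, K, fs. Never configurable.
* $g(t)$ is computed by direct quadrature on a grid fine enough to
  resolve the narrowest Lorentzian (dω ≤ γ/6 and ω_c/6, capped at
  1 cm⁻¹); the spectrum by FFT of $e^{-g_k(t)}$ with trapezoidal end
  correction, interpolated onto the requested grid. Time grids that
  alias the highest vibrational mode are rejected with the required dt.
* Default grids: 8 fs × 512 points (≈4 ps, 8 cm⁻¹ FFT resolution),
  output 9000–18000 cm⁻¹ at 5 cm⁻¹. A warning fires if the grid does
  not cover all states carrying ≥1% of the maximal weight ± 5
  homogeneous FWHM (estimated from the overdamped part only, since
  vibrational modes add sidebands rather than quasi-static width).
* Eigenvector gauge: leading coefficient > 1e-6 made positive.
  Degenerate pairs keep LAPACK's basis, gauge-fixed, which is
  deterministic for a fixed input.
* Coupling matrices must be symmetric to 1e-8 cm⁻¹ and are
  symmetrized exactly; CT states may couple only to their adjacent
  pair (validated).
* Ring extraction from PDB orders pigments by azimuth about the
  principal (least-variance) axis of the centers, ties broken by the
  axial coordinate; altlocs resolve to highest occupancy, ties to
  first encountered.

## Parameter bundles and their provenance

`load_bundle("LH2purp")` / `load_bundle("LH2acid")` ship the class
site energies (13724/13630/13634 and 13527/13556/13783 cm⁻¹) and the
printed couplings (inter-dimer 166 vs 298 cm⁻¹, B800–B800 10 vs 30
cm⁻¹). Everything else — intra-dimer, αα, ββ and inter-ring couplings,
all CT energies and couplings, all disorder σ — is a **package
default**, flagged `provenance: default` in the YAML and surfaced via
`bundle$provenance`. Defaults were chosen once to respect the known
qualitative orderings (inter-dimer largest in the nonamer; second
neighbor couplings reduced in the heptamer; inter-dimer CT coupling
strongly reduced but intra-dimer CT enhanced in the heptamer; B850
additional disorder larger than the environmental disorder, B800
environmental disorder largest of all) and are not fitted to any
spectrum. Analyses intended to be quantitative against published
numbers (the mixed-model site substitution, the Table-level site-energy
differences, the 828/859 nm gap) avoid depending on them; analyses that
use them (CT shifts, absolute peak positions, the coupling-substitution
shift) should be read as model behavior, not as reproductions of
published values.

One CT state per adjacent pair is the packaged default; the
`ct_manifold()` container accepts any number per pair (e.g. both
charge-separation directions) when real parameters are available.

## The mixed-model analysis

`mixed_model_shift(a, b, mode)` rebuilds the disorder-free average
B850 Hamiltonian of bundle `a` with selected parameters replaced by
those of `b` and reports the change of the bright-state energy,
operationalized as the dipole-strength-weighted mean of the two
brightest states — robust to the small symmetry breaking that splits
the ideal k = ±1 pair. Because the class-level parameters are scalars,
substitution across different ring sizes is well defined; only
`mode = "full"` compares complete topologies (14 vs 18 B850 sites).
With the packaged bundles the site substitution gives ≈ −135 cm⁻¹,
first-order in character (variation below 1 cm⁻¹ across nearest-
neighbor couplings 100–400 cm⁻¹), site and coupling effects are
additive to better than 1%, and the full comparison gives ≈ −329 cm⁻¹.

## Problem sizes

The packaged analyses are sized for interactive use: ensembles of
30–150 realizations of 21–27 Qy sites (plus 14–18 CT states), 512-point
time grids and ~1800-point frequency grids; the full test suite and the
acceptance script each run in well under a minute. All sizes are plain
arguments and scale up linearly in realizations and grid points.

## Known limitations

* Secular cumulant lineshapes, not FCE: vibronic intensity borrowing
  and non-secular effects are absent.
* Point-dipole couplings are a geometric stand-in; published
  polarizable-embedding couplings should be supplied via bundles when
  quantitative work is intended.
* CT parameters and the unprinted couplings are placeholders (see
  provenance flags); absolute CT shifts and absolute peak positions
  inherit that uncertainty.
* Only the conservative part of exciton CD is modeled: no mixing with
  higher excited states or carotenoid transitions, so nonconservative
  experimental CD shapes cannot be reproduced.
* No fitting machinery: the package computes forward models only.
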