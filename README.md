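# excitonring

Frenkel exciton models of light-harvesting pigment rings, built for
dissecting the optical spectra of LH2-type antenna complexes of purple
bacteria — in particular for asking why the heptameric LH2 of
*Mch. purpuratum* absorbs near 830 nm while nonameric rings like
*Rbl. acidophilus* LH2 absorb near 850–860 nm.

The package is aimed at spectroscopists and modelers who have (or can
posit) excitonic parameters — site energies, couplings, charge-transfer
(CT) states, disorder widths — and want reproducible exciton-level
analyses and spectra from them.

## What it computes

At its core is the CT-augmented exciton Hamiltonian

    H = Σ_i ε_i |i><i| + Σ_ij V_ij |i><j|
      + Σ_m ε^CT_m |m><m| + Σ_im (V^CT_im |i><m| + h.c.)

over the Qy states of the B850 (two pigments per repeating unit) and
B800 (one per unit) bacteriochlorophyll rings, with CT states between
adjacent B850 pairs. From it the package derives:

* **Exciton structure** — energies, transition dipoles and dipole
  strengths, rotational strengths, symmetry (k) labels, inverse
  participation ratios, bright-state energy and band width.
* **Geometry** — ideal Cn rings or rings extracted from PDB structures
  (NB/ND midpoints and axes), center–center distances, orientation
  factors κ, point-dipole couplings `V = 5034.1 κ μ² / R³`, H-bond
  distance series.
* **Disorder ensembles** — the env/vac static-disorder decomposition
  `E_static = E_env − E_vac + <E_vac>`, MD-like synthetic Hamiltonian
  ensembles (Gaussian site-energy and coupling fluctuations, seeded and
  bitwise reproducible), plus estimators that recover the generating
  parameters.
* **Spectra** — absorption and CD per disorder realization from
  second-order cumulant lineshapes in the exciton basis (Drude–Lorentz
  + Brownian-oscillator spectral density, optional Redfield lifetime
  broadening), ensemble averaging, global QM-error shifts, band peak
  readout in cm⁻¹ and nm.
* **Shift decomposition** — "mixed models" that substitute site
  energies, couplings or the whole topology between two parameter
  bundles and report the bright-state shift; paired with/without-CT
  pipelines for the CT contribution.

## Worked example

```r
library(excitonring)
purp <- load_bundle("LH2purp")   # heptamer parameter bundle
acid <- load_bundle("LH2acid")   # nonamer parameter bundle
purp
#> parameter_bundle: LH2purp - 7 repeating units
#> site energies (cm^-1): alpha=13724, beta=13630, B800=13634
#> couplings (cm^-1): intra_dimer=230, inter_dimer=166, alpha_alpha=-40,
#>   beta_beta=-20, b800_b800=10, inter_ring=25
#> 16 parameter(s) are package defaults (see $provenance)
```

Bundle values flagged `published` are transcribed published averages; the
rest are package defaults (see `purp$provenance` and the vignette).

Exciton structure of the average B850 Hamiltonian:

```r
geom <- bundle_geometry(purp, "B850")
st <- diagonalize(average_hamiltonian(purp, "B850"))
st <- k_labels(state_dipoles(st, geom), 7, 2)
head(data.frame(energy_cm1 = round(st$energies, 1),
                dipole_D2 = round(st$dipole_strengths, 1),
                k = st$k_labels), 5)
#>   energy_cm1 dipole_D2  k
#> 1    13220.1      12.4  0
#> 2    13280.1     271.0 ±1
#> 3    13280.1     271.0 ±1
#> 4    13433.2       0.0 ±2
#> 5    13433.2       0.0 ±2
```

The degenerate k = ±1 pair at 13280.1 cm⁻¹ carries ~97% of the dipole
strength — the bright B850 state. Decomposing the heptamer→nonamer
bright-state shift by parameter substitution:

```r
mixed_model_shift(purp, acid, "site")   # swap alpha/beta site energies
#> [1] -134.9
mixed_model_shift(purp, acid, "coup")   # swap B850 couplings
#> [1] -159.9
mixed_model_shift(purp, acid, "full")   # complete models, 14 vs 18 sites
#> [1] -328.8
```

Lower site energies and stronger couplings each red-shift the bright
state by a similar amount, nearly additively; the remainder of the full
difference comes from the larger ring. The CT contribution, from
otherwise identical with/without-CT spectra pipelines:

```r
ct_effect(purp)$b850_shift
#> [1] -95
```

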