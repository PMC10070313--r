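# Parameter bundle: heptameric LH2 of Mch. purpuratum (MD/QM averages).
# provenance "published" = printed value transcribed from published work;
# "default" = package default standing in for supplementary-only or
# unprinted parameters (clearly non-authoritative).
name: LH2purp
ring:
  n_units: 7
  b850_radius: {value: 24.0, provenance: default}     # Angstrom
  b800_radius: {value: 31.0, provenance: default}
  b800_z: {value: -16.5, provenance: default}
  beta_angle_offset: {value: 0.386, provenance: default}   # rad, alpha->beta
  dipole_tilt: {value: 0.15, provenance: default}     # rad out-of-plane
  b800_psi: {value: 2.2, provenance: default}         # rad, B800 azimuth
  dipole_magnitude: {value: 6.3, provenance: default} # Debye
site_energies:        # cm^-1, MD-average Qy site energies
  alpha: {value: 13724, provenance: published}
  beta: {value: 13630, provenance: published}
  B800: {value: 13634, provenance: published}
couplings:            # cm^-1
  intra_dimer: {value: 230, provenance: default}
  inter_dimer: {value: 166, provenance: published}
  alpha_alpha: {value: -40, provenance: default}
  beta_beta: {value: -20, provenance: default}
  b800_b800: {value: 10, provenance: published}
  inter_ring: {value: 25, provenance: default}
ct:                   # CT manifold placeholders (supplementary-only data)
  energy_intra: {value: 15300, provenance: default}
  energy_inter: {value: 15500, provenance: default}
  coupling_intra: {value: 300, provenance: default}
  coupling_inter: {value: 150, provenance: default}
disorder:             # cm^-1; supplementary-only, package defaults
  sigma_static: {alpha: 60, beta: 60, B800: 120, provenance: default}
  sigma_add: {alpha: 160, beta: 160, B800: 60, provenance: default}
  sigma_coupling: {value: 15, provenance: default}
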