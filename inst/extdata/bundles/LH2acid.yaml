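# Parameter bundle: nonameric LH2 of Rbl. acidophilus (MD/QM averages).
# provenance "published" = printed value transcribed from published work;
# "default" = package default standing in for supplementary-only or
# unprinted parameters (clearly non-authoritative).
name: LH2acid
ring:
  n_units: 9
  b850_radius: {value: 26.0, provenance: default}
  b800_radius: {value: 31.0, provenance: default}
  b800_z: {value: -16.5, provenance: default}
  beta_angle_offset: {value: 0.36, provenance: default}
  dipole_tilt: {value: 0.15, provenance: default}
  b800_psi: {value: 2.2, provenance: default}
  dipole_magnitude: {value: 6.3, provenance: default}
site_energies:        # cm^-1, MD-average Qy site energies
  alpha: {value: 13527, provenance: published}
  beta: {value: 13556, provenance: published}
  B800: {value: 13783, provenance: published}
couplings:            # cm^-1
  intra_dimer: {value: 240, provenance: default}
  inter_dimer: {value: 298, provenance: published}
  alpha_alpha: {value: -50, provenance: default}
  beta_beta: {value: -60, provenance: default}
  b800_b800: {value: 30, provenance: published}
  inter_ring: {value: 25, provenance: default}
ct:
  energy_intra: {value: 15300, provenance: default}
  energy_inter: {value: 15500, provenance: default}
  coupling_intra: {value: 250, provenance: default}
  coupling_inter: {value: 350, provenance: default}
disorder:
  sigma_static: {alpha: 60, beta: 60, B800: 120, provenance: default}
  sigma_add: {alpha: 160, beta: 160, B800: 60, provenance: default}
  sigma_coupling: {value: 15, provenance: default}
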