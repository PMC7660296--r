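# Median material properties of candidate silicone variants (uniaxial tensile
# tests at 100% elongation; densities from weighed known volumes).
silicones:
  - name: dragon_skin_fx_pro
    youngs_modulus_kPa: 90.9
    poisson_ratio: 0.51
    density_kg_m3: 1120
  - name: dragon_skin_10_nv
    youngs_modulus_kPa: 185.5
    poisson_ratio: 0.48
    density_kg_m3: 1030
  - name: dragon_skin_10_medium
    youngs_modulus_kPa: 189.4
    poisson_ratio: 0.46
    density_kg_m3: 1210
# Material selected for the testbed membrane and its as-built geometry.
testbed:
  material: dragon_skin_10_nv
  clamped_side_mm: 167
  thickness_mm: 39
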