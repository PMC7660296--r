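# Reported material and geometrical properties of the maternal abdomen layers
# (30-week gestational age) used by the single-layer membrane design model.
# Units are declared per key; loaders convert to SI.
layers:
  - name: fetal_membrane
    youngs_modulus_kPa: 7100
    youngs_modulus_range_kPa: [3200, 13700]
    poisson_ratio: 0.40
    thickness_mm: 0.19
    thickness_range_mm: [0.14, 0.28]
  - name: uterine_wall
    youngs_modulus_kPa: 586
    poisson_ratio: 0.40
    density_kg_m3: 1052
    thickness_mm: 6.90
    thickness_range_mm: [5.0, 10.50]
    radius_mm: 99
    radius_range_mm: [89, 117]
  - name: abdominal_wall
    youngs_modulus_kPa: 21
    youngs_modulus_range_kPa: [13.6, 28.4]
    poisson_ratio: 0.50
    density_kg_m3: 973.61
    density_range_kg_m3: [970.13, 976.75]
    thickness_mm: 31.40
    thickness_range_mm: [7.80, 63.0]
# Published weighted-average row, shipped as the canonical single-layer
# curved-abdomen material (the published aggregation is not exactly
# reproducible from the layer rows above; the printed values are
# authoritative downstream).
weighted_average:
  youngs_modulus_kPa: 151.37
  youngs_modulus_range_kPa: [132, 224]
  poisson_ratio: 0.48
  density_kg_m3: 982.86
  density_range_kg_m3: [980.02, 985.42]
  thickness_mm: 38.49
  thickness_range_mm: [12.94, 73.78]
# Mean radius of curvature of the curved abdomen model; sides equal the
# semicircumference at this radius.
geometry:
  radius_of_curvature_mm: 118.1
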