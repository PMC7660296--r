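# Maximum uterine wall tensile stress by gestational age and the biaxial
# membrane elongations that reproduce it on the testbed. Only the mean
# tensions are used downstream (the reported 25-week elongation range
# duplicates the 20-week range and is treated as unreliable).
tensions:
  - gestation_weeks: 20
    stress_kPa: 11.9
    stress_range_kPa: [5.8, 19.5]
  - gestation_weeks: 25
    stress_kPa: 16.3
    stress_range_kPa: [9.5, 24.2]
  - gestation_weeks: 30
    stress_kPa: 22.8
    stress_range_kPa: [14.2, 33.3]
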