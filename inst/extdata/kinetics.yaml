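# Mannitol osmotic-stress kinetics of the map experiment.
# half_life_min: half-life (min) of the degradable carotenoid pool per
# mannitol concentration (mM); expected amplitude ratio at t minutes is
# floor + (1 - floor) * 2^(-t / half_life). Values chosen so the mean mapped
# 1157 cm-1 intensity first drops below 50% of pre-treatment at 5 min for
# 250 mM and at 15 min for 100 mM.
half_life_min:
  "100": 9
  "150": 5
  "250": 3
floor: 0.1
spatial_cv: 0.12
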