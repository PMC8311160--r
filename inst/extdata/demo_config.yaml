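# Demo run: reduced in vivo design (3 replicates x 3 plants x 6 spectra/day)
# over the three inbred profiles. Completes in well under a minute.
mode: in_vivo_study
seed: 42
genotypes: [CML176, OH28, B73]
design:
  replicates: 3
  plants: 3
  spectra_per_day: 6
  days: [0, 1, 2, 3, 4, 5, 6, 7]
preprocess:
  baseline_order: 7
  sg_window: 15
  sg_order: 3
band: carotenoid_1157
d_start: 0
d_end: 7
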