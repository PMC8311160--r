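# Carotenoid quantification bands. Amplitude = maximum preprocessed intensity
# within center +/- half_window. carotenoid_1524 is the strongest carotenoid
# band but overlaps the anthocyanin band, so it is excluded from degradation
# statistics; carotenoid_1157 is the default quantification band.
bands:
  - {name: carotenoid_1007, center: 1007, half_window: 10, use_for_rates: false}
  - {name: carotenoid_1157, center: 1157, half_window: 10, use_for_rates: true}
  - {name: carotenoid_1524, center: 1524, half_window: 10, use_for_rates: false}
default: carotenoid_1157
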