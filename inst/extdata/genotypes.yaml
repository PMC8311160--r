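# Synthetic leaf-spectrum fixtures: band tables, backgrounds and genotype
# profiles. Amplitudes are detector counts (arbitrary units); centers and
# widths in cm-1 (widths are Lorentzian HWHM). Carotenoid band heights are
# relative to the profile's 1157 cm-1 amplitude (amp0); r_drought is the
# 7-day relative degradation of the preprocessed 1157 band under drought.

carotenoid_bands:
  - {center: 1007, hwhm: 7, rel_amp: 0.45}
  - {center: 1157, hwhm: 8, rel_amp: 1.00}
  - {center: 1524, hwhm: 9, rel_amp: 1.35}

constant_bands:
  green:
    - {label: other,       center: 520,  hwhm: 12, amp: 690}
    - {label: other,       center: 635,  hwhm: 15, amp: 625}
    - {label: chlorophyll, center: 747,  hwhm: 14, amp: 810}
    - {label: other,       center: 917,  hwhm: 16, amp: 750}
    - {label: other,       center: 975,  hwhm: 12, amp: 690}
    - {label: other,       center: 1048, hwhm: 14, amp: 750}
    - {label: chlorophyll, center: 1326, hwhm: 18, amp: 940}
    - {label: other,       center: 1382, hwhm: 14, amp: 810}
    - {label: other,       center: 1440, hwhm: 30, amp: 875}
    - {label: anthocyanin, center: 1530, hwhm: 25, amp: 300}
    - {label: chlorophyll, center: 1606, hwhm: 14, amp: 875}
    - {label: other,       center: 1655, hwhm: 12, amp: 750}
    - {label: other,       center: 1735, hwhm: 14, amp: 625}
  white:
    - {label: other,       center: 520,  hwhm: 12, amp: 420}
    - {label: other,       center: 635,  hwhm: 15, amp: 380}
    - {label: other,       center: 917,  hwhm: 16, amp: 460}
    - {label: other,       center: 975,  hwhm: 12, amp: 420}
    - {label: other,       center: 1048, hwhm: 14, amp: 460}
    - {label: other,       center: 1382, hwhm: 14, amp: 500}
    - {label: other,       center: 1440, hwhm: 30, amp: 540}
    - {label: anthocyanin, center: 1530, hwhm: 25, amp: 80}
    - {label: other,       center: 1655, hwhm: 12, amp: 460}
    - {label: other,       center: 1735, hwhm: 14, amp: 380}

background:
  green: {c0: 800, c1: -150, c2: 60, c3: -40, gauss_amp: 2500, gauss_center: 1050, gauss_sd: 300}
  white: {c0: 500, c1: -90,  c2: 40, c3: -25, gauss_amp: 1200, gauss_center: 1050, gauss_sd: 300}

profiles:
  - {genotype: CML176, tissue: green, amp0: 1100, r_drought: 0.22}
  - {genotype: OH28,   tissue: green, amp0: 900,  r_drought: 0.20}
  - {genotype: B73,    tissue: green, amp0: 700,  r_drought: 0.06}
  - {genotype: lox2,   tissue: green, amp0: 700,  r_drought: 0.10}
  - {genotype: lox4,   tissue: green, amp0: 700,  r_drought: 0.03}
  - {genotype: B73,    tissue: white, amp0: 250,  r_drought: 0.0}
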