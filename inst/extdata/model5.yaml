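# Best-fit four-population expansion history of Primula vulgaris
# (TR-D Turkey, CH-D Switzerland, EN1-D easternmost England, EN6-M
# monomorphic England). Times are years before present; an explicit
# time_units/ne_units tag is required. Sizes not reported with the selected
# model are package calibrations (see the methods vignette).
populations: [TR, CH, EN1, EN6]
ne: [95627, 100000, 20000, 500]
ne_units: diploid
time_units: years
generation_time: 2
mu: 1.23e-8
events:
  - {time: 100,   type: size,  pop: EN6, ne: 8000}    # EN6 contraction ~100 ybp
  - {time: 24000, type: split, pop: EN6, dest: EN1}   # EN1/EN6 split
  - {time: 31000, type: size,  pop: EN1, ne: 3000}    # EN-lineage recovery
  - {time: 48000, type: size,  pop: EN1, ne: 20000}   # EN-lineage contraction
  - {time: 62300, type: size,  pop: CH,  ne: 2000}    # CH bottleneck phase
  - {time: 64000, type: size,  pop: CH,  ne: 20000}   # CH pre-contraction size
  - {time: 65500, type: split, pop: CH,  dest: EN1, ne: 20000}  # CH/EN split
  - {time: 79000, type: split, pop: EN1, dest: TR, ne: 13419}  # TR/Europe split
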