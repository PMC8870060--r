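{
  "brand": "Advanced Bionics 16ch (representative)",
  "default_bands": [
    [248, 310],
    [310, 372],
    [372, 496],
    [496, 620],
    [620, 744],
    [744, 930],
    [930, 1116],
    [1116, 1426],
    [1426, 1736],
    [1736, 2170],
    [2170, 2728],
    [2728, 3410],
    [3410, 4216],
    [4216, 5270],
    [5270, 6510],
    [6510, 8122]
  ],
  "freq_step_hz": 62,
  "min_band_width_hz": 62,
  "deactivated": [],
  "indexing": "apex_first",
  "global_f_min": 248
}
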