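{
  "brand": "Oticon Medical 20ch (representative)",
  "default_bands": [
    [195, 326],
    [326, 457],
    [457, 588],
    [588, 719],
    [719, 850],
    [850, 981],
    [981, 1112],
    [1112, 1243],
    [1243, 1374],
    [1374, 1505],
    [1505, 1636],
    [1636, 1767],
    [1767, 2160],
    [2160, 2684],
    [2684, 3208],
    [3208, 3863],
    [3863, 4649],
    [4649, 5566],
    [5566, 6745],
    [6745, 8055]
  ],
  "freq_step_hz": 131,
  "min_band_width_hz": 131,
  "deactivated": [],
  "indexing": "apex_first",
  "global_f_min": 195
}
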