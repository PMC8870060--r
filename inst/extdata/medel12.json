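{
  "brand": "MED-EL 12ch (representative)",
  "default_bands": [
    [70, 104],
    [104, 156],
    [156, 232],
    [232, 347],
    [347, 517],
    [517, 771],
    [771, 1151],
    [1151, 1717],
    [1717, 2561],
    [2561, 3820],
    [3820, 5698],
    [5698, 8500]
  ],
  "freq_step_hz": 1,
  "min_band_width_hz": 1,
  "deactivated": [],
  "indexing": "apex_first",
  "global_f_min": 70
}
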