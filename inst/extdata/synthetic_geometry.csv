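# synthetic example: CT-style electrode positions for a 12-electrode array
# (not measured from any real scan)
# cochlea_length_mm: 33.0
# orientation: from_apex
electrode,distance_mm
1,6.2
2,7.9
3,9.6
4,11.4
5,13.2
6,15.0
7,16.9
8,18.8
9,20.7
10,22.6
11,24.5
12,26.4
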