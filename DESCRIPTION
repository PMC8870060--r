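Package: eafit
Title: Interactive Evolutionary Optimization of Cochlear-Implant Frequency Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing the frequency-band allocation map (fMAP) of a
    cochlear implant in bimodal listeners with a small-budget interactive
    evolutionary algorithm: constrained frequency-map data structures with
    per-brand quantization grids and minimum band widths, tournament selection,
    locus-wise crossover, Gaussian mutation and elitist survivor selection over
    a fixed three-generation schedule, a simulated bimodal listener (logistic
    psychometric function of weighted octave mismatch, binomial word scoring)
    for automated testing, Greenwood place-frequency mapping of CT-measured
    electrode positions, and summary statistics (including an exact Wilcoxon
    signed-rank test) for word-recognition-score session tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
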