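---
title: "Evolutionary frequency-map fitting: model, constraints and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary frequency-map fitting: model, constraints and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eafit)
```

## The optimization problem

A cochlear implant's frequency allocation map (fMAP) partitions an analysis
range (roughly 0.07–8.5 kHz, brand-dependent) into one contiguous band per
active electrode, apex-first. In bimodal listeners, the factory allocation
interacts with the contralateral acoustic ear: a frequency-place mismatch
between the two inputs can limit binaural fusion and speech recognition in
noise. Adjusting the allocation is a constrained combinatorial search with
a human in the evaluation loop — the only fitness signal is a word
recognition score (WRS) in noise, about ten words per candidate map — so
the evaluation budget is tiny and fixed in advance.

`eafit` treats each fMAP as a real-valued individual (the vector of band
upper edges) and runs a hybrid of a genetic algorithm (locus-wise
crossover) and an evolution strategy (Gaussian mutation of real values),
driven interactively by the listener's scores.

## Constraint system

Three invariants define a valid map against a device profile:

* **Contiguity.** `f_LOW[i] = f_HIGH[i−1]`; the most apical active band is
  pinned at the profile's `global_f_min`. No gaps, no overlaps, ever.
* **Width.** Every band is at least `min_band_width_hz` wide (1 Hz MED-EL,
  62 Hz Advanced Bionics and Cochlear, 131 Hz Oticon Medical).
* **Quantization.** Every edge lies on the fitting grid
  `global_f_min + k · freq_step_hz` (1 Hz MED-EL/Cochlear, 62 Hz Advanced
  Bionics, 131 Hz Oticon Medical).

The search itself only ever manipulates upper edges inside the
*exploration domain* `[default f_LOW, 1.2 × default f_HIGH]` (upper bound
snapped down to the grid). `chain_and_repair()` converts any proposed
upper-edge vector — including the non-monotone vectors crossover produces —
into a valid map: working apex to base, each lower edge is chained, and the
proposed upper edge is clamped into
`[max(f_LOW + min_width, domain lo), domain hi]` and snapped to the grid.

Repair direction is a genuine design choice. We repair apex→base so that
apical (low-frequency) bands are perturbed least: the apical channels are
where bimodal interaction is concentrated and where the optimizer is
expected to act, so the repair operator should not second-guess them. The
operator is deterministic and idempotent, which the test suite checks on
10^4 random vectors across all four shipped profiles.

Deactivated electrodes are removed before the search and their spectral
range is absorbed by chaining over the active electrodes only. When apical
or interior electrodes are deactivated, the next active band widens
downward to cover the gap; the exploration domain is then built on this
re-chained active-array default.

## The evolutionary loop

Defaults (all in `evolution_config()`):

| parameter | default | meaning |
|---|---|---|
| `n_parents` | 4 | random initial maps; also survivor-pool size |
| `children_per_generation` | 3 | children bred per generation |
| `n_generations` | 3 | fixed stop criterion (13 evaluations total) |
| `tournament_size` | 2 | drawn with replacement per tournament |
| `mutation_prob` | 0.2 | per-band Gaussian mutation probability |
| `mutation_sigma_frac` | 0.1 | mutation SD as a fraction of band width |
| `domain_expansion` | 1.2 | headroom factor on default upper edges |

Parents are sampled apex→base: each upper edge uniform on the feasible part
of its exploration interval given the previously sampled edge, then
repaired. Each child is bred by two tournaments within the survivor pool
(the winning individual is the higher-scoring of two drawn with
replacement; ties among the drawn resolve uniformly at random), locus-wise
crossover (each upper edge copied verbatim from one parent, Bernoulli(0.5)
per electrode, configurable mixing ratio), and Gaussian mutation. After a
generation's three children are scored, the survivor pool is recomputed as
the four highest-scoring maps among *everything* generated so far — pools
are therefore drawn from 7, 10, and 13 maps — which makes the scheme
elitist by construction: the running best can never leave the pool, and
the final selected map is never worse than the best random parent.

Three readings of the procedure were genuinely open and are resolved as
follows, each behind a configuration switch:

* **Tournament winner.** The winner is deterministically the
  higher-scoring of the two drawn individuals
  (`tournament_win_prob = 1`); a probabilistic winner is available but is
  not the default, since a 2-tournament with deterministic winner is the
  standard operator.
* **Mutation target.** Mutation nominally touches both edges, but because
  lower edges are defined by chaining, perturbing upper edges alone spans
  the same space of maps and needs no second repair pass; we mutate upper
  edges only. The mutation SD uses the band width of the chained candidate
  itself (`sigma_basis = "current"`); the factory width is available as an
  alternative. The perturbation is applied to the *raw* proposed vector
  (so `mutation_prob = 0` is an exact no-op), while the width that scales
  the SD is measured on the deterministically repaired version, so the SD
  is well defined even when crossover has produced a locally inverted
  vector.
* **Tie-breaks.** Survivor-pool ties at the boundary resolve to the
  earlier generation, then the earlier creation index (reproducible).
  Several maps often share the final top score — in the packaged session
  table this happened in 9 of 27 listeners — and clinically the listener
  chooses by sound quality. `session_best(state, choose = )` implements
  that choice; the batch default keeps the most recently generated of the
  tied maps, on the reasoning that later maps embody more selection.

Sessions are stepwise and event-sourced. Every proposal, score, pool
update and the final selection is appended to a JSONL log together with an
RNG checkpoint; `replay_session_log()` rebuilds the state from any prefix
of the log and `resume_session()` continues on the identical random
stream. This mirrors the clinical reality that a 2-hour fitting is
sometimes abandoned mid-way (the packaged table contains two such
sessions, stopped after 8 and 6 evaluations) and must remain analyzable.

## The simulated listener

Automated tests need a fitness oracle, so the package ships a synthetic
bimodal listener. It hides an ideal map (sampled from the exploration
domain, or supplied) and scores a candidate map in two stages:

1. **Mismatch**: `Σ w_i |log2 Fc_i(map) − log2 Fc_i(ideal)|`, the weighted
   octave distance between per-electrode center frequencies. Weights
   decay geometrically base-ward (factor 0.7, normalized), making the
   oracle most sensitive to apical allocation — the region where bimodal
   listeners integrate with the acoustic ear and where frequency fitting
   is expected to act.
2. **Psychometrics**: recognition probability
   `p = logistic(a − b·mismatch)` with `a = 2.2` and `b = 12` per weighted
   octave; the observed score is `Binomial(n_words, p)` (binomial mode) or
   `round(n_words · p)` (noise-free mode).

The defaults are calibrated to the geometry of the search space, not to
any dataset: on a 12-channel profile with 1.2× headroom the reachable
mismatch ranges over roughly 0–0.35 weighted octaves, and `a = 2.2`,
`b = 12` place that interval on the steep part of the logistic (p ≈ 0.90
at perfect match, i.e. 9/10 noise-free, falling toward chance at the far
edge), so a 10-word test can actually discriminate candidate maps.

What the simulator does *not* emulate is as important as what it does: no
SNR dependence (the test SNR is carried as metadata only), no learning or
fatigue across the session, no channel interaction or loudness effects,
and no claim that a real listener's psychometric function is logistic in
this particular distance. Passing the optimization-gain tests therefore
shows that the loop extracts signal from noisy 10-word scores under the
stated budget — it does not predict the size of any clinical effect, and
the clinical improvement in the packaged table (4.17 → 6.46 out of ten) is
not a quantity the simulator is calibrated to reproduce.

With the shipped defaults, 200 paired seeded sessions give a mean
best-of-session WRS about 1.2 words above the mean best-of-4-random-parents
under binomial scoring (one-sided sign test p ≪ 0.05), and the selected
map's hidden mismatch is on average below the best parent's. In noise-free
mode the selected map is never worse than the best parent on any seed
(elitism) and strictly better in the mean. The test suite runs these at
200 seeds, the constraint property tests at 250 random sessions per
profile and 10^4 repair vectors — sizes chosen to make the binomial
comparisons stable at two digits.

## Tonotopy

`greenwood_frequency()` implements the place–frequency function of the
human cochlea, `F = 165.4·(10^{2.1x} − 0.88)` Hz. The package evaluates it
with `x` the *relative distance from the apex*: `x = 0` gives 19.85 Hz
(apical limit) and `x = 1` gives 20.68 kHz (basal limit), the standard
orientation of the function. Imaging workflows often record electrode
distance from the round window instead; `electrode_geometry()` carries the
orientation explicitly and `flip_orientation()` converts (an involution).
Users should be aware the two conventions are easy to swap silently — a
round-window-measured position fed in as apex-measured inverts the entire
map — which is why orientation is a mandatory field of the geometry input
rather than a default. The inverse mapping `greenwood_position()` is
closed-form (`log10`), so frequency→place→frequency round-trips to machine
precision. No correction for lateral-wall versus basilar-membrane path
length is applied to CT measurements; positions are used as given.

`compare_center_frequencies()` lines up, per electrode, the Greenwood
frequency at the electrode's cochlear place with the center frequencies of
the factory and optimized maps. Center frequency is the geometric mean of
the band edges — the natural summary for logarithmically laid-out channels
(the arithmetic mean is available via `method = "arithmetic"`).

## The session-table statistics

`read_session_table()` loads the packaged 27-listener table (one row per
listener: initial 20-word WRS, fixed SNR, the 13 candidate scores, the
selected map, final 20-word WRS; scores out of ten, so 20-word tests yield
half points). Structural invariants — missing scores only as a trailing
block, the selected map scoring the row maximum — are machine-checked by
`validate_session_table()`.

`summarize_wrs()` reports the sample standard deviation (n − 1) *and* the
standard error of the mean: summaries of such tables are conventionally
printed as "mean ± spread" and the two are easy to conflate (here
SD ≈ 0.97 versus SEM ≈ 0.19 for the initial scores — a 5× difference).
The median is the middle order statistic (14th of 27). On the packaged
table the initial scores have median 4 and range 3–6, and the final
scores median 7 and range 2–9.

`wilcoxon_signed_rank()` is implemented in the package rather than
delegated: zero differences are discarded (Pratt's variant is available),
tied absolute differences are mid-ranked, and for effective n ≤ 12 the
null distribution of `W+` is enumerated exactly over all 2^n sign
assignments — which remains valid under ties, unlike tabulated exact
distributions. Above that, a normal approximation with tie-corrected
variance (`Σr²/4`) and continuity correction is used; the suite checks the
exact branch against an independent brute-force enumeration and against
the reference implementation on tie-free data, and the two branches
against each other at the crossover size. Degenerate input (all
differences zero) yields p = 1 with a warning rather than an error, since
batch pipelines should not crash on a no-change comparison.

## Known limitations

* The loop optimizes frequency allocation only; loudness (T/M levels) is
  deliberately out of scope — co-optimizing it would multiply the search
  space far beyond a 13-evaluation budget.
* The fixed 3-generation schedule is a clinical time-budget constraint,
  not a convergence criterion; nothing in the package estimates whether
  the search has converged.
* The simulated listener is a testing instrument. Its parameters are
  package defaults with a stated rationale, not fitted quantities, and
  conclusions drawn from it transfer to real listeners only qualitatively.
* Shipped device profiles are representative band tables on the correct
  per-brand grids; real factory tables vary by model and coding strategy
  and should be supplied as JSON profiles for clinical use.
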