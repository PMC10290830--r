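---
title: "Gapped n-mer models for core promoter elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gapped n-mer models for core promoter elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapmotif)
library(dplyr)
```

## The problem

Core promoter elements (CPEs) such as the TATA box and the initiator (INR)
are short (6 bp) motifs near the RNA polymerase II transcription start site.
Their sequences vary substantially between promoters, and an open question
for bioinformatic prediction is *which positions of the motif carry the
predictive signal*, and whether positions are statistically independent of
one another — the independence assumption underlying ordinary position
weight matrices (PWMs).

gapmotif approaches this with **gapped n-mer models**: patterns over
`m` (considered) and `k` (ignored) symbols that declare which site
positions a scoring matrix uses. Scoring a 6 bp site under every gapped
model and ranking the models by predictive performance reveals which
positions matter; a separate Monte Carlo test probes pairwise dependence
between positions directly.

## Model catalogs

Two catalogs are supported for 6 bp sites:

* **anchored32** — all patterns of length 1–6 whose first and last symbols
  are considered. Numbering is block-structured: blocks by pattern length
  start at ids 0, 1, 2, 4, 8, 16, and within a block models are ordered by
  the binary value of the interior symbols (`m` = 1). So `mmkkmm` (length
  6, interior `mkkm` = 1001 = 9) is model 16 + 9 = 25.
* **full64** — all 2^6 length-6 patterns, numbered by reading the pattern
  as a binary number (`m` = 1, leftmost symbol most significant):
  `mmmkmk` = 111010 = 58. This catalog removes the anchoring bias at
  positions 1 and 6.

```{r catalogs}
enumerate_models(6, "anchored32") |> filter(model_id %in% c(0, 16, 25, 31))
model_id("mmmkmk", "full64")
```

A model shorter than the site slides across it (a length-1 model has six
frames in a 6 bp site). Masking a site to a model frame replaces every
position not covered by an `m` with `N` — `TCAGTG` under `mmkkmm` becomes
`TCNNTG` — which is how model-specific sequence-logo inputs are built.
`position_inclusion_tally()` counts how often each site position is
considered by a set of models; the default `per_frame` mode adds one per
covering frame, because the sliding window means a short model can cover a
given site position in several frames. A `per_model_union` mode (one per
model, regardless of frames) is kept selectable since either reading of a
"frequency of consideration" is defensible.

## Matrices and the two representations of a gapped model

From an alignment of 6 bp sites the package builds count, probability and
log-odds matrices. Counts take a +1 pseudocount by default so that no
frequency is zero (column sums are then `n + 4`). The background model
splits A/T and G/C mass equally within each pair; the default 0.6/0.4
split reflects the fly genome. Log-odds are base 2 by default; base and
pseudocount are recorded in every exported matrix header because the
downstream numbers are meaningless without them.

Gapped models are deliberately represented two ways:

* **Joint tuple tables** (`gapped_tuple_table()`): for each frame, the
  joint frequency of the nucleotides at the model's considered positions
  over all sites (a table over `4^c` tuples, +1 pseudocount per cell).
  This representation captures *within-frame dependence* between
  considered positions and drives the real-versus-scrambled screen.
* **Background-filled PWMs** (`gapped_pwm()`): considered columns carry
  the log-odds of the site probabilities, ignored columns the background
  (zero log-odds). This position-independent representation drives the
  scanner, mirroring how gapped models are exported to PWM-based search
  tools. Window scores are provably invariant to the letters at ignored
  positions.

The all-ignored pattern `kkkkkk` (full64 id 0) is enumerable for catalog
completeness but rejected by both matrix builders: a scoring matrix with
no considered position is undefined. Screens over the full catalog emit
`NA` rows for it and exclude it from rankings.

## The real-versus-scrambled (RZ) screen

For each model, training sites are scored as the sum over the model's
frames of `log2(freq(tuple) / background_product(tuple))`. Thresholds are
*percentile positions* (default 0, 0.25, 0.5, 0.75, 1) of the
training-score distribution, resolved by a lower nearest-rank rule: the
cutoff is the score of the site whose lower empirical percentile first
reaches the position, and a window is called a binding site when its score
is **at or above** the cutoff (`>=` rather than `>`, so that position 1
still detects the top training site). Position 0 therefore detects every
training site and position 1 only the best one.

Every 6 bp window of every promoter is scored the same way as the training
sites (sum over the model's frames within the window), so the training
percentiles and the scan share one scale. Each promoter is compared with
composition-preserving scrambles of itself — uniform random permutations
of its letters, which conserve single-nucleotide composition exactly — and
the RZ score is

$$RZ = \frac{R}{R + S}$$

with `R` real-sequence hits and `S` (replicate-averaged) scrambled hits:
1 when sites are found only in the real promoters, 0 when only in the
scrambles, 0.5 when balanced. When both counts are zero the score is
reported missing rather than 0.5, to keep "no signal" distinct from
"balanced signal". One scramble per promoter is the default for the
screen; the count is configurable and replicates are averaged.
`classify_models()` takes the top/bottom `k` (default 3) models per
threshold, expanding on ties.

## The scanner: exact p-values, PPV and true hit ratios

At width 6 there are only 4096 windows, so the scanner's null score
distribution is enumerated *exactly*: every window is assigned the product
of its letters' background probabilities, and the tail `P(score >= s)` is
exact for every achievable score. This replaces the approximations of
external PWM-search tools with a strictly defined quantity that a
brute-force oracle can verify bit for bit, and it makes the candidate set
for threshold selection finite: the positive predictive value
`PPV = TP / (TP + FP)` is piecewise constant between achievable tail
values, so `select_p_threshold()` evaluates exactly those (plus 1.0) and
breaks ties toward the most selective p-value. A hit is a true positive
when its window overlaps the annotated element by at least one base
(0-based half-open intervals internally; adjacency is not overlap).
Scanning is forward-strand only, as CPEs are orientation-specific.

Per promoter, the accuracy statistic is

$$\text{true hit ratio} =
  \frac{TP_\text{real}}{\text{all}_\text{real} - \overline{\text{hits}}_\text{scrambled}}$$

with the scrambled average over (by default) 100 composition-preserving
scrambles. When the denominator is not positive the ratio is undefined;
undefined records are excluded from the per-model mean and counted in the
report. Note the ratio can exceed 1 when scrambles also produce hits; it
is a relative, not a bounded, statistic.

`leave_parts_out()` guards against overfitting the matrices to the search
set: each trial randomly splits the records (102 train / rest test by
default), builds all 64 gapped PWMs from the training records' annotated
6-mers, and evaluates every model on the held-out records at a fixed
p-value (default 0.006). Top and bottom 5% model sets (3 of 64) are
recorded per trial, and `trial_set_correlations()` checks consistency
across sets of trials with Pearson correlations.

A consequence of exact p-values worth knowing: at `p = 0.006` a model
with `c` considered positions can only produce hits if the background
probability of its best window is at most 0.006, which with an A/T 0.6
background requires `c >= 4`. Models with three or fewer considered
positions therefore return no hits and an undefined mean ratio at this
threshold; rankings are computed over the defined models.

## The pairwise interdependency test

`pair_dependence_test()` asks, for each of the C(6,2) × 16 = 240
(position pair, nucleotide pair) hypotheses, whether the joint count
observed in the alignment is compatible with positional independence. The
null model draws sets of sites (same size as the alignment, 100,000 sets
by default) with independent positions from a 4 × 6 position probability
matrix — by default the alignment's own pseudocount-free matrix, as a user
would run it. Monte Carlo p-values use the add-one convention
`(1 + #{null >= obs}) / (n_sets + 1)`, so they are never exactly zero; the
two-tailed p-value is the doubled smaller tail capped at 1, and both
one-tailed p-values are reported alongside so over- and under-enrichment
can be read directly. No multiple-testing correction is applied across
the 240 tests; significance flags at 0.05/0.01/0.001 are per-hypothesis.

Two properties of this procedure matter for interpretation, and both are
verified by the package's tests:

* Under the product null the count for one hypothesis is
  Binomial(n, p_i(a) p_j(b)); the simulated null agrees with that closed
  form within Monte Carlo error.
* The test is **valid but conservative**. Count discreteness plus the
  doubled-tail convention already put the achievable size below the
  nominal level, and the plug-in null (estimating the ppm from the tested
  alignment itself) is substantially more conservative still, because the
  null reference tracks the data's own marginal fluctuations: given the
  marginals, the conditional variance of a joint cell count is smaller
  than the unconditional binomial variance by roughly
  $(1-p_i)(1-p_j)/(1-p_ip_j)$, so the empirical type-I fraction at a
  nominal 0.05 lands near 0.007. Reported significances are therefore
  understatements, never overstatements; power against a genuine planted
  coupling of strength 0.3 in 205 sites remains essentially 1 at the
  0.001 level.

## The synthetic-data generators

Three samplers provide ground truth for every stage:

* `sample_sites(ppm, n)` — independent positions from a ppm.
* `sample_sites_coupled()` — mixture forcing: with probability `c` a
  site's two coupled positions are overwritten with the given letters.
  Chosen over log-linear coupling because its joint and marginal
  frequencies have closed forms (`E[joint] = n(c + (1-c) p_i(a) p_j(b))`),
  enabling exact power calculations; `c = 0` is bitwise identical to the
  plain sampler at the same RNG state.
* `sample_promoters()` — i.i.d. background letters with a planted 6-mer
  at a recorded offset. The default geometry emulates 100 bp windows
  spanning −49..+50 around the TSS with the site at 1-based positions
  48–53 (site position 3 on the +1 TSS).

Three fixture matrices ship with the package. `inr_ppm()` (consensus
TCAGTY) and `tata_ppm()` (consensus TATAAA) are stylized CPE-like
matrices; `background_ppm()` is positionally uninformative and is the
null fixture for calibration checks. `coupled_benchmark_ppm()` exists
specifically for the cross-validation recovery benchmark: its signal is
concentrated at positions 2 (A) and 5 (G) — the letters the coupling
forces, so coupling reinforces rather than dilutes the marginals — with
mildly informative flanks. That concentration is the benchmark's premise:
it tests that models *considering* positions 2 and 5 outrank models
*ignoring* both when the data genuinely put the information there. With a
matrix that spreads information evenly across positions the ranking
contrast is not implied and the benchmark would test nothing.

What the generators deliberately do **not** emulate: dinucleotide or
higher-order background structure, GC isochores, multiple or missing
elements per promoter, and alignment errors. Passing the synthetic
benchmarks therefore shows the machinery recovers planted structure under
the stated model, not that real promoter data satisfy that model.

## Numerical and scale choices

* Exact tail probabilities are merged only for bitwise-equal scores;
  window scores computed during scanning use the same accumulation order
  as the enumeration, so p-value lookup is exact rather than
  tolerance-based.
* Thresholds use `>=` throughout (detection at the cutoff), and RZ /
  true-hit-ratio undefined cases are propagated as `NA`, never silently
  coerced.
* Test-suite problem sizes are scaled down from the defaults as the
  package's own choice of desk-scale study conditions: the calibration
  study uses 200 replicate alignments of 205 sites with 5,000 null sets;
  the power study 50 replicates with 10,000 null sets; the
  cross-validation benchmark 120 promoters, 10 trials of a 60/60 split
  with 20 scrambles. The pinned-equivalence fast path
  (`evaluate_models_shared`) makes a full-catalog trial run in about a
  second, so the full published scale (50 trials, 100 scrambles, 100,000
  null sets) remains practical outside the test suite.
* All samplers consume R's RNG; a single `set.seed()` reproduces every
  downstream object bit for bit, including written files.

## Known limitations

* Fixed-length, gap-free site alignments over A/C/G/T only; no IUPAC
  ambiguity codes.
* Forward-strand scanning (reverse-complement support would double the
  enumeration but is not currently exposed).
* The per-window hit count treats overlapping windows as separate hits.
* The interdependency test's plug-in null makes it conservative (see
  above); when the generating matrix is known, pass it via `ppm=` for
  near-nominal calibration.
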