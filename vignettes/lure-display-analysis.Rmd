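---
title: "Scoring polymorphic mantle-lure displays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring polymorphic mantle-lure displays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luredisplay)
```

## The biological problem

Gravid females of the freshwater mussel *Lampsilis fasciola* display a
pigmented mantle lure that mimics prey of their host fish (an aggressive
mimicry: the fish that strikes is infected with parasitic glochidia larvae).
The lure is polymorphic — a common "darter-like" morph and a rarer
"leech/worm-like" morph coexist within populations — while the congener
*L. cardium* carries a single lure type. Three quantitative questions hang off
this system:

1. Do the morphs *behave* differently? Displays are scored from video as
   discrete movement events of the left and the right lure flap, and the
   morphs and the congener are compared on interval, duration and left–right
   synchrony statistics.
2. Is the morph *ratio* stable over decadal time? Historical museum counts
   are compared with contemporary field counts in a 2×2 table.
3. Is the polymorphism consistent with a *single-locus* genetic control?
   Brood phenotype counts are tested against Mendelian expectations.

`luredisplay` implements all three analyses as a tested pipeline, plus a
synthetic-data generator that stands in for the raw video annotations, which
are not deposited in any public archive. The repository is organised as an
analysis workflow: the numbered drivers under `analysis/` run the pipeline
end to end on generated data, and every computation they perform lives in the
package so the tests exercise it directly. For the same reason no standalone
command-line binary is shipped: the drivers, the exported functions and this
vignette are the interface.

## Event model

A scored movement is a closed frame interval `[start_frame, end_frame]` on
one flap: the start is the first frame where mantle contraction is visible,
the end the frame where the lure is back at rest. Frames are 0-based
integers. Recordings default to 120 frames/s with a 20,000-frame analysis
window (2.8 min) starting at frame 5,000 — the window skips camera set-up
disturbance, and every event must fall inside it.

Two conventions are choices rather than published facts and are documented
as such:

* **End frames are inclusive.** The definition of the start frame ("first
  frame where contraction is observed") treats the boundary frame as part of
  the movement; we apply the same reading to the end frame.
* **Starts are strictly increasing within one flap**; one flap cannot begin
  two movements on the same frame. Overlapping bodies (a movement starting
  before the previous one has ended) are accepted with a warning, since
  annotators do score re-contractions of a not-fully-relaxed lure.

## Synchrony classification

Left and right movements are *synchronized* when their start frames differ
by at most a tolerance, default 4 frames (1/30 s at 120 fps), read as an
inclusive bound. The proportion synchronized is

$$
p_{\text{sync}} \;=\;
\frac{n_{\text{sync}}}{\,n_{\text{sync}} + n_{\text{left-only}} +
  n_{\text{right-only}}\,}.
$$

The published protocol does not say how to pair events when several
candidate partners fall inside the tolerance, so the package fixes a
deterministic rule: sweep left events chronologically and match each to the
**earliest** not-yet-matched right event within tolerance; each event is used
at most once; a recording with no movements reports `NA` (no display) rather
than 0 (a display that never synchronized). Because both tracks are sorted
and all tolerance windows have equal width, this greedy rule attains the
maximum possible number of pairs; the test suite verifies it against an
exhaustive maximum-matching oracle on random tracks and checks the
conservation identities
`n_left = n_sync + n_left_only`, `n_right = n_sync + n_right_only`.

Per-individual summaries report, per side, the mean and SD of start-to-start
intervals and the mean start-to-end duration, in seconds. A side with fewer
than two intervals has no defined SD and reports `NA` with a logged note —
never a silent zero. Gait diagrams draw synchronized pairs on a center line
(spanning the union of the two paired events), left-only movements above and
right-only movements below, on a time axis in seconds with frame numbers as
the secondary axis.

```{r gait, fig.width = 8, fig.height = 2.5}
rec <- simulate_display(species_preset("darter_morph"), "example", seed = 4)
plot(gait_diagram(rec))
```

## Group comparisons

Group-level tests default to **left-flap interval summaries** (the same side
the published summary figures use); `side = "right"` or `"pooled"` are
available. The omnibus test is Kruskal–Wallis; pairwise comparisons are
two-sample Wilcoxon rank-sum (Mann–Whitney) tests with Bonferroni adjustment
over the number of pairs (3 for three groups). The field literature
sometimes labels these "Wilcoxon signed-rank" tests, but with independent
groups of unequal size (4 / 15 / 12) a paired test is undefined and the
reported `W = 0` complete-separation statistics are rank-sum statistics, so
the rank-sum test is what this package implements: exact p-values for small
samples without ties, normal approximation otherwise. A degenerate input in
which every value is identical is reported as `H = 0, p = 1` rather than the
`NaN`/`NA` the underlying routines produce.

Because individuals differ in how many movements fall inside the analysis
window, the mixed-model analysis first equalises the per-individual sample
size by **bootstrap resampling**: each individual's interval values are
resampled with replacement to a fixed size (default 1,000), reproducibly
under an explicit seed. The model is then

$$
y_{ij} = \mu + \beta_{g(i)} + b_i + \varepsilon_{ij},
\qquad b_i \sim N(0, \sigma_b^2),
$$

a linear mixed model of interval on lure group with a random intercept per
recording, fitted by REML (`lmerTest`), with Satterthwaite denominator
degrees of freedom for the fixed-effect tests. The random intercept is what
keeps the inference honest under bootstrap inflation: the group comparison is
driven by between-individual variation, and the suite checks that inflating
the bootstrap size tenfold moves the fixed-effect standard errors by less
than 10%. Singular fits (zero between-individual variance, common in
degenerate test inputs) are flagged, with estimates still reported. A
Spearman correlation of mean interval with water temperature is provided to
screen for a temperature confound.

## Polymorphism statistics

**Ratio stability.** The 2×2 morph-by-period table is tested with *both* the
Pearson chi-square **without continuity correction** and the two-sided Fisher
exact test (summing all tables no more probable than the observed one). Both
are reported, clearly labelled, because the field literature mixes the two
conventions for such tables; on the River Raisin counts (48:9 historical vs
23:4 contemporary) the uncorrected chi-square is 0.01 with p = 0.91, and the
morph percentages are 84.2/15.8 and 85.2/14.8.

**Segregation.** The genetic model is one autosomal biallelic locus with
complete dominance. The dam's genotype is given explicitly; the unknown —
possibly multiple — sires are collapsed into a single parameter, the
frequency of the dominant allele among paternal gametes, which is all that
matters under random union of gametes. The expected dominant-phenotype
fraction is $1 - (1 - d)(1 - s)$ with $d$ the dam's transmission probability
(1, ½, 0) and $s$ the sire allele frequency. The observed count of
maternal-morph offspring is tested with an exact binomial test: the
two-sided p sums all outcomes no more probable than the observed one, the
one-sided p is taken in the direction of the observed deviation, and a model
whose expectation of 0 or 1 is contradicted by the data is reported as
"impossible under model" (p = 0) rather than numerically. On the published
33 darter : 17 leech brood from a leech-morph dam, the dominant-leech /
heterozygous-dam model (expected ½ leech) gives a one-sided p of 0.016 and is
rejected at α = 0.05 — the genetic headline of the system.

```{r segregation}
brood <- brood_counts(n_darter = 33, n_leech = 17, dam_morph = "leech")
segregation_test(brood, genetic_model("leech", "Aa", sire_dominant_freq = 0))[
  c("expected_proportion", "p_one_sided", "p_two_sided", "verdict")]
```

## The synthetic-data generator

No behavioral recordings are deposited, so the generator is a first-class
module: it produces data with the statistical structure the analysis
assumes, making every downstream stage testable.

A **driving renewal process** draws inter-movement intervals (gamma by
default — non-negative and right-skewed, matching erratic displays;
lognormal by config) and accumulates them into candidate movement times
inside the analysis window. Each driving movement is then expressed
bilaterally:

* with probability `p_sync`, as a **synchronized pair** — the right start
  offset by a uniform integer jitter in `[-jitter_frames, +jitter_frames]`;
* otherwise, on **one side only** at the driving time (fair coin), with the
  missed partner on the other side displaced to the midpoint of the gap to
  the next driving movement, i.e. out of register.

Each uncoupled draw therefore contributes one left-only *and* one right-only
movement, so with jitter at or below the classifier tolerance and intervals
well above it the expected proportion synchronized has the closed form

$$
E[p_{\text{sync}}] = \frac{p}{2 - p},
$$

which the tests use as a Monte-Carlo oracle (p = 0.5 → 1/3). This
shared-driving design, rather than two independent renewal processes, is
deliberate: it maps the generator's coupling parameter directly onto the
classifier's output scale. Interval draws are clamped below at
`2 * jitter_frames + 2` frames, which guarantees the strictly-increasing
start invariant on both flaps by construction (the clamp affects a fraction
of a percent of draws at the presets and is negligible against the tests'
3-standard-error recovery bands). Durations are drawn independently per
event and truncated to end before the same flap's next movement and inside
the window.

The three **presets** are loosely calibrated to the field estimates: the
congener displays fast (mean interval 0.21 s), regular and fully coupled
(`p_sync = 1`); the darter morph slow (3.2 s), variable and partly coupled;
the leech morph intermediate (1.0 s). Interval SDs (0.05 / 2.0 / 0.7 s),
morph coupling (0.6) and all duration parameters (0.4 ± 0.1 s; congener
0.1 ± 0.03 s) are free parameters — no published dispersion or duration
estimates exist — chosen once to reproduce the qualitative contrast of
regular-synchronized vs erratic-independent displays. The default synthetic
study is 4 congener + 15 darter + 12 leech recordings, matching the
behavioral sample of the motivating study. Broods are simulated by drawing a
maternal allele from the dam's genotype and a paternal allele at the sire
allele frequency, per offspring.

What the generator does **not** emulate: temperature-dependent display
rates (temperature is attached as pure metadata, so the packaged Spearman
screen on synthetic data is a null check), within-display nonstationarity,
kinematic waveforms of the undulation itself, and annotation error. Passing
tests on synthetic data therefore demonstrate that the scoring and inference
machinery is correct under the assumed event-train structure — not that real
displays satisfy that structure.

## Numerical and design choices

* All stochastic functions take an explicit integer seed, restore the
  caller's RNG stream, and are bit-reproducible under the same seed; batch
  functions derive per-recording seeds from one master seed.
* Tie-breaks in matching (earliest available partner) and the inclusive
  tolerance make the classifier fully deterministic.
* The test suite works at deliberately modest problem sizes — a few hundred
  random tracks for matching properties, ~10,000 events for the closed-form
  Monte-Carlo check, 20 seeds × 31 recordings for the mixed-model ordering
  check, bootstrap sizes of 100–1,000 — sizes at which every Monte-Carlo
  band is a 3-standard-error band computed from the run itself.
* Percentages are reported to one decimal, matching the field convention.

## Known limitations

* The greedy matcher is the package's defined behavior; on adversarial
  (non-sorted-window) inputs a maximum matching could in principle differ,
  which is why the exhaustive-matching oracle bound is tested rather than
  assumed.
* The rank-sum exact p-values switch to a normal approximation under ties,
  as in standard implementations; proportion-synchronized comparisons with
  many tied 1.0 values use the approximation.
* The mixed model treats bootstrap replicates as exchangeable within
  individual; it quantifies between-group differences conditional on the
  resampling design, not measurement error of the annotation itself.
* The segregation machinery addresses single-locus models only; paternity
  reconstruction and linkage are out of scope.
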