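# luredisplay

Scoring and population statistics for the polymorphic aggressive-mimicry
mantle lure of freshwater mussels (*Lampsilis fasciola* and its congener
*L. cardium*).

Gravid female *L. fasciola* display a fleshy mantle lure mimicking host-fish
prey; the lure occurs in two heritable morphs ("darter-like" and
"leech-like"). This package turns frame-annotated video scoring of those
displays into statistics, and tests the population genetics of the
polymorphism:

* **Event model** — movement events as closed frame intervals
  `[start_frame, end_frame]` per lure flap, with validated CSV
  readers/writers and the standard 20,000-frame / 120 fps analysis window.
* **Display scoring** — left–right synchronization (starts within a 4-frame
  tolerance, matched greedily in chronological order), per-individual
  interval/duration/synchrony summaries
  (`p_sync = n_sync / (n_sync + n_left_only + n_right_only)`), and gait
  diagrams (synchronized movements on the center line, one-sided movements
  above/below).
* **Group comparison** — Kruskal–Wallis + pairwise Wilcoxon rank-sum tests
  with Bonferroni adjustment, Spearman temperature screen, and a
  bootstrap-fed random-intercept mixed model
  `interval ~ group + (1 | recording)` (REML, Satterthwaite df; 1,000
  resampled intervals per individual).
* **Polymorphism statistics** — 2×2 morph-ratio stability (uncorrected
  Pearson chi-square *and* two-sided Fisher exact, both reported) and exact
  binomial segregation tests of brood counts against single-locus dominance
  models with a sire allele-frequency parameter for unknown/multiple sires.
* **Synthetic data** — a coupled renewal-process generator for bilateral
  event trains (closed form `E[p_sync] = p/(2−p)` links its coupling
  parameter to the classifier output) and single-locus brood simulation, so
  the whole pipeline is testable without video.

## Worked example

The numbered drivers under `analysis/` run the pipeline end to end on a
synthetic study (4 congener, 15 darter-morph, 12 leech-morph recordings),
writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_score.R
Rscript analysis/03_compare.R
Rscript analysis/04_polymorphism.R
```

Step 2 prints the scoring headline — the congener's displays are fully
synchronized and an order of magnitude faster than the morphs':

```
congener proportion synchronized: 1, 1, 1, 1 (expect all 1.0)
morph mean of mean left intervals: darter 3.23 s, leech 1.01 s, congener 0.21 s
```

Step 3 fits the bootstrap-fed mixed model; the fitted group means recover
the generator's interval scales with the between-recording variance absorbed
by the random intercept:

```
  group means (s): L. cardium = 0.208, darter = 3.25, leech = 1.01
  random-intercept variance: 0.03623 s^2; residual: 2.356 s^2
```

Step 4 reproduces the published polymorphism numbers from the printed count
tables: the morph ratio is stable across six decades, and the brood data
reject a dominant leech allele:

```
morph percentages: historical 84.2/15.8, contemporary 85.2/14.8
stability: chi2 = 0.01 (p = 0.91), Fisher exact p = 1.00
dominant_leech_het_dam: expected leech proportion 0.500, one-sided p = 0.0164,
  two-sided p = 0.0328 -> rejected
```

Interactively:

```r
library(luredisplay)
rec <- simulate_display(species_preset("congener"), "c1", seed = 7)
classify_synchrony(rec$left, rec$right, tolerance_frames = 4)
#> <sync_score> sync: 786  left-only: 0  right-only: 0
#>   proportion synchronized: 1.000  (tolerance 4 frames)
plot(gait_diagram(rec))
```

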