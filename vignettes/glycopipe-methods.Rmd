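---
title: "Methods: serum glycopeptide profiling with glycopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum glycopeptide profiling with glycopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Untargeted LC–MS profiling of protease-digested serum glycoproteins yields
tens of thousands of glycopeptide ion peaks per cohort. Only a small,
reliable subset of these is informative for discriminating a disease group
(for example epithelial ovarian cancer sera) from benign gynecologic
controls. `glycopipe` implements the complete path from centroided peak
lists to a validated two-class discriminant model:

1. **Peak extraction** — extracted-ion chromatograms (EICs), smoothing,
   derivative-based peak bounding, trapezoidal area integration;
2. **Drift correction and alignment** — affine retention-time/m-z
   correction against internal-standard anchor peaks, then tolerance-based
   cross-run clustering into a feature table;
3. **QC normalization** — every area is expressed as a ratio to the
   feature's mean area over pooled-QC injections, and inter-/intra-assay
   CVs are computed from the QC replicates;
4. **Feature filtering** — a four-stage cascade (blank comparison, CV,
   signal-to-noise, isotope/adduct/fragment deduplication) with complete
   per-stage accounting;
5. **Discrimination** — unit-variance scaling, PCA overview, OPLS-DA with
   stratified train/test evaluation and 7-fold cross-validated Q2;
6. **Differential statistics** — Welch-test volcano tables and heat-map
   ratio matrices against the control-group average.

Because raw clinical LC–MS data of this kind are rarely shareable, the
package ships a synthetic-cohort generator with complete ground truth;
every stage is tested against that ground truth.

## Peak extraction

An EIC is built per m/z series by single-linkage gap clustering of the
run's ion m/z values: the sorted values are split wherever the gap to the
next ion exceeds `mz_gap` (default 0.02 Da, well inside the 0.06 Da
alignment tolerance). Gap grouping rather than fixed-width binning avoids
the bin-edge artifact in which one feature's ions straddle a boundary and
produce two half-intensity traces — a failure mode that would split
features at alignment. Each trace lives on the run's scan grid with zero
fill; the per-scan m/z is the intensity-weighted mean of member ions.

Traces are smoothed with a Savitzky–Golay filter (window 7 points,
polynomial order 2, both exposed). The derivative is taken by central
finite differences on the smoothed trace — equivalent to the analytic
Savitzky–Golay derivative on a uniform grid up to edge handling, and still
defined on the non-uniform grids of sparse runs (blanks). A point counts
as "zero slope" when `|d| < zero_eps * max|d|` with `zero_eps = 1e-3`,
since exact zeros never occur on floating-point grids. A peak then starts
where the derivative crosses zero-to-positive, tops where it turns
positive-to-negative, and ends where it returns negative-to-zero; a valley
where the slope flips directly from negative to positive closes one peak
and opens the next at the same scan, which makes detection additive under
splitting a trace at an empty valley. Incomplete start/apex/end triples at
trace edges are discarded. The area is the trapezoidal integral from start
to end; on a noiseless sampled Gaussian (grid 0.01 min, peak sd 0.05 min)
the detected area agrees with fine-grid quadrature to well under 1% and
the apex to one grid step (the acceptance script recomputes both).

**Signal-to-noise.** No standard definition exists at the peak-list level,
so the package uses a robust convention: peak height divided by
`1.4826 * MAD` of the trace outside all detected peak spans. A zero noise
estimate (common on clean synthetic traces) yields `S/N = Inf`, which the
downstream filter treats as "keep".

**Drift correction.** Each run's detected peaks are matched to the
internal-standard reference coordinates (five fetuin-like anchors spanning
the elution window in the simulator; the highest matching peak wins) and
`reference = offset + slope * observed` is fit by least squares separately
for retention time and m/z — an affine model, which two or more anchors
determine. Correction transforms coordinates only; areas are untouched.

**Alignment.** All runs' corrected peaks are pooled and sorted by
descending height (ties broken by retention time, m/z, run id — a
canonical order that makes the result independent of run order). Each
peak greedily joins the nearest existing cluster whose centroid lies
within 0.3 min and 0.06 Da and which does not yet contain a peak of the
same run; otherwise it seeds a new cluster. Centroids are running means.
One peak per run per cluster is enforced at attachment time: because
processing is in height order, the taller conflicting peak keeps the
cluster (for same-width chromatographic peaks height and area are
monotone in each other, so this realizes the higher-area preference).
Missing cells stay missing in the feature table and are imputed as half
the feature's minimum observed area only immediately before multivariate
modelling.

## QC normalization and CVs

Pooled-QC sera are injected after every tenth study sample (two pool
arms — a case pool and a benign pool — alternate). Normalization divides
every cell by the feature's mean QC area; features whose QC mean is zero
or undefined are flagged and removed rather than silently divided. QC
columns are retained with their own ratios, so each feature's QC mean is
1 by construction, and the normalization is invariant to rescaling any
feature.

The intra-assay CV of a feature is the worst CV over one pool arm's
repeated injections within one batch; the inter-assay CV is the worst CV
over all of an arm's injections across the sequence. Both arms are
evaluated separately and the maximum is carried forward — the
conservative choice when a single CV threshold gates features. The
`batch` column of the manifest drives the intra/inter distinction; the
simulator exposes the batch count (default 3) because the number of QC
replicates per batch is a design choice, not a property of the method.

## The filter cascade

Stages run in a fixed order, and the report records it, because the
cascade is genuinely order-sensitive (a satellite whose parent was
removed by an earlier stage becomes an orphan the satellite stage cannot
recognize):

| stage | rule | default |
|---|---|---|
| blank | remove if mean(study) < `min_ratio` × mean(blank) | `min_ratio = 5` |
| cv | remove if QC CV **>** `max_cv` (strict) | `max_cv = 50`% |
| sn | remove if representative S/N **<** `min_sn` (strict) | `min_sn = 100` |
| satellite | isotope / adduct / in-source fragment rules below | — |

The blank-comparison threshold of 5× is common untargeted-MS practice
(the comparison itself, not the multiplier, is the established step) and
is exposed in the configuration. Boundary semantics are strict on both
thresholds: a CV of exactly 50% and an S/N of exactly 100 are retained.
Undefined CVs are removed conservatively; an undefined S/N is kept (no
evidence against the feature). The per-feature S/N is the median over the
contributing peaks' trace-level values.

**Satellite rules.** A feature is deleted as an *isotope* when a more
intense feature co-elutes (|ΔRT| ≤ 0.1 min) one isotope spacing below it
(m/z − 1.0033/z for z ∈ {1, 2}, matched within 0.01 Da); as an *adduct*
when a more intense co-eluting feature sits one negative-mode adduct mass
below (+46.0055 formate, +21.9819 sodium−proton, +34.9689 chloride); and
as an *in-source fragment* when a more intense co-eluting feature of
higher m/z tracks it across samples at Pearson r ≥ 0.95. The satellite
tolerances (0.1 min, 0.01 Da) are deliberately tighter than the alignment
tolerances so that genuinely co-eluting independent glycopeptides are not
deleted. The intensity comparisons must use **raw** mean areas: after
QC-ratio normalization every feature's mean is ≈ 1 and carries no
intensity information, so `run_filter_cascade()` takes a `raw_intensity`
vector computed from the pre-normalization table. Flags are evaluated
simultaneously on the stage's input table and removed together, keeping
the stage deterministic and order-free internally.

The report satisfies an accounting identity on every run: each stage's
output count equals the next stage's input count, and removals plus
survivors sum to the initial feature count.

## Scaling, PCA and OPLS-DA

Features are mean-centered and scaled to unit variance; scaling
parameters are estimated on the training set only and reused for test
data. Zero-variance features are dropped with a message (and fold-locally
inside cross-validation, where a feature can be constant in a training
fold).

PCA is computed from the singular value decomposition of the centered
matrix and serves as the unsupervised overview and as a guard against
over-reading the supervised projection.

OPLS-DA encodes the two classes as 0/1 and centers the response. With
`w ∝ X'y` the predictive weight, each orthogonal round computes the
loading `p` of the current predictive score, removes its projection on
`w` (`w_o ∝ p − (w'p/w'w) w`), and deflates `X` by `t_o p_o'` with
`t_o = X w_o`. Two exact consequences are worth noting (both are asserted
by the test suite):

* `X'y` is invariant under the deflation (because `w_o ⟂ w`), so each
  orthogonal score is *exactly* orthogonal to the final predictive score;
* with one response, filtering `a` orthogonal components and fitting one
  predictive component reproduces the fitted values of an ordinary
  `a + 1`-component PLS1 — the classical defining property of the method.

`R2Y = 1 − RSS/TSS` on the training response; `R2X` is the fraction of
the scaled X sum of squares captured by the predictive plus orthogonal
components; `Q2(cum) = 1 − PRESS/TSS` from stratified k-fold
cross-validation with fold assignment round-robin within each class after
a seeded shuffle. The default is `k = 7` (the convention of the standard
chemometrics software this workflow descends from) and one orthogonal
component; `n_ortho = "auto"` instead maximizes Q2 over 0..3. Class calls
threshold the predicted response at 0.5. Q2 > 0.5 is used as the
customary reliability bar. OPLS-DA's known tendency to produce seductive
score-plot separation on null data is surfaced, not hidden: the suite and
the acceptance script both check that label-permuted cohorts yield a
median Q2 ≤ 0.

Train/test splits are class-stratified with per-class training counts
`round(fraction * class size)` (default fraction 0.8). Published designs
sometimes fix counts that no single rounding rule reproduces, so explicit
per-class counts can be supplied. Score plots carry the Hotelling
T² ellipse, `T²crit = 2(n−1)/(n−2) · F(1−α; 2, n−2)`, whose radius
approaches the χ²₂ limit (≈ 2.448 at α = 0.05) for large n.

## Volcano and heat-map statistics

Per feature, the volcano table reports the ratio of group means
(case/control) and a Welch two-sample t-test p-value (the unequal-variance
test is the safer default where group variances differ; the pooled test
is available). Significance requires both `p < 0.05` and a mean fold
outside (0.7, 1.5). A Benjamini–Hochberg FDR column is emitted for
information but does not gate the call, matching the raw-p convention of
this plot. Top features are selected by smallest p, ties broken by larger
|log2 fold|, then id.

Heat-map ratios divide each individual's value by the feature's
control-group mean, so control rows average to 1 by construction, and the
case-column mean of a feature's ratios equals its volcano fold (same
denominator). Cells are binned on a fixed log10-uniform scale: nine bins
spanning 0.1–10 plus two overflow bins (`< 0.1`, `> 10`), symmetric in
log-space around 1.

## The synthetic cohort generator

The generator emulates the study design end to end: 39 case and 45
control sera by default; a pooled-QC injection after every 10 study
samples (pools are the mean of ten randomly chosen study sera per arm
plus fresh measurement noise, so assay CVs are a function of measurement
noise alone); blank injections carrying only noise ions and the internal
standards; and per-feature satellite ions (isotopes at +1.0033/z, the
three negative-mode adducts above, and lower-m/z in-source fragments).
Fragment and other satellite areas track the *measured* parent area
within a tight multiplicative scatter (2%), reflecting that satellites
arise from the same ion current in the same injection — this is what
makes the correlation-based fragment rule identifiable.

True areas are log-normal (between-subject biological scatter, default
sd 0.3 on the log scale) around class means; differential features get a
log2 fold change drawn from `Normal(effect, effect/4)` (truncated at
zero, random sign), so an `effect_log2fc` of 1 means group-mean ratios
around 2. Measurement noise is multiplicative with log-sd
`noise_sd_rel = 0.1`, giving QC replicate CVs near 10% — comfortably
inside the 50% filter, as in a well-behaved assay. Raw runs add
per-injection scale scatter (log-sd 0.1), affine retention-time and m/z
drift per run (offset sd 0.05 min / 0.01 Da plus small slope scatter —
kept inside half the alignment tolerances so ground-truth matching stays
well defined), per-peak jitter, Gaussian elution profiles (sd 0.05 min on
a 0.01 min scan grid), and uniform background noise ions.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: chromatographic tailing and co-elution
shoulders, profile-mode peak shapes, charge-state envelopes beyond the
configured states, real glycan mass ladders, retention-time drift that is
nonlinear within a run, and batch effects beyond injection-scale scatter.
Peak shapes are Gaussian precisely so the analytic area
`height · sd · sqrt(2π)` is available as an oracle.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise the feature-level
statistics at the study scale (84 samples × 2281 features — the scale at
which the multivariate and differential claims are interesting), and the
full raw-run pipeline at the study cohort shape (39 + 45 study runs, QC
every 10, blanks) with 250 simulated glycopeptide features plus
satellites — enough to exercise every code path, chosen so a complete
run stays comfortable on a laptop-class single core. The original
tens-of-thousands-of-peaks scale adds nothing to the properties being
checked.

Other numerical choices: missing values are imputed as half the feature
minimum only at the modelling stage; degenerate traces (all-zero,
monotone) yield no peaks rather than errors; a drift fit with fewer than
two matched standards is an error naming the run; t-tests on essentially
constant data return `NA` p-values rather than failing the whole table;
and all randomness (cohort, splits, folds, permutations) flows from
explicit integer seeds, with derived child seeds kept below 2^31.

## Known limitations

* The satellite rules are geometric and correlation-based; they do not
  use glycan-aware mass differences, and chains (isotope of an adduct)
  are removed only if their direct parent pattern matches.
* QC-ratio normalization removes per-feature assay drift but not
  per-injection scale; no LOESS-style drift regression is attempted
  beyond it.
* OPLS-DA here is strictly two-class with a single predictive component;
  no VIP scores, S-plots or permutation p-values are computed.
* The published reference values for this kind of study (e.g. 2281
  surviving features, R2X 0.21 / R2Y 0.84 / Q2 0.60 on one comparison)
  were computed on undeposited patient data; they are design anchors for
  defaults, not reproducible targets, and the package makes no claim to
  reproduce them numerically.
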