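---
title: "Quantifying developing MEA activity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying developing MEA activity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meadev)
```

`meadev` summarises a multielectrode-array (MEA) recording of cultured
neuronal spiking as an 11-dimensional feature vector and supplies the
statistics used to compare and classify groups of recordings — typically
hippocampal (HPC) versus cortical (CTX) cultures followed across days in
vitro (DIV). This vignette explains the model behind each stage, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the methods literature leaves choices open.

## The data model

A `spike_train` is the strictly increasing vector of multiunit spike times
(seconds) on one electrode over a known interval, by default 0–900 s (the
conventional 15-minute recording). An `mea_recording` bundles one train per
electrode with electrode positions (default: the 59 recording electrodes of
an 8×8, 200-µm-pitch array with corners and the reference electrode
absent), the region of origin (`CTX`/`HPC`), the culture age (DIV) and an
array identifier. Silent electrodes are kept: they carry real information
(a rate of zero) and belong in denominators such as the theta fraction.
`validate_recording()` reports invariant violations as data rather than
raising, so suspect files can be triaged in bulk.

Recordings are stored in an HDF5 layout with the concatenated spike vector
`/spikes`, per-electrode counts `/sCount`, positions `/epos`, labels
`/names`, the array model `/array`, and metadata `/meta/region`,
`/meta/age`. Because archived files do not declare their time unit, the
reader exposes `units = "s"` (default) or `"samples"` with a 25 kHz sample
rate.

## Burst detection (features 2–6)

`detect_bursts()` implements the classical max-interval method in three
phases. Phase 1: scanning the interspike intervals (ISIs), a candidate
burst opens at the first ISI below `max_begin_isi` and extends over every
following ISI below `max_end_isi`; the burst ends at the last spike before
an ISI at least `max_end_isi`. Phase 2: consecutive candidates whose gap
(next start − previous end) is below `min_ibi` are merged. Phase 3:
candidates shorter than `min_duration` or with fewer than `min_spikes`
spikes are dropped. Defaults (0.1 s, 0.25 s, 0.8 s, 0.05 s, 6) are the
standard thresholds for dissociated-culture recordings.

Two conventions are not fixed by the method's standard description and are
therefore explicit options:

* **Interburst interval definition.** The CV of IBI uses the *gap*
  (end→next start) by default, because the gap is the quantity Phase 2
  thresholds; onset-to-onset is available via `ibi_definition = "onset"`.
  For regular bursting the two coincide up to duration jitter.
* **Phase order.** Merging precedes filtering (`merge_before_filter =
  TRUE`), so two sub-threshold candidates separated by a short gap survive
  as one burst; the reverse order is available for sensitivity analysis.

Per-electrode statistics (`burst_statistics()`) are: mean of
spikes/duration over bursts (Hz), bursts per minute, mean duration (s),
fraction of the electrode's spikes inside bursts, and sd/mean of the IBIs.
Undefined is a value: an electrode with no bursts has `NA` (not 0) for the
within-burst rate and duration, and the CV needs at least two IBIs (three
bursts). The array value of each burst feature is the median over
electrodes with at least one burst.

## Network spikes (features 7–9)

Time is divided into `ns_bin = 0.003` s bins and each bin gets the count of
electrodes with at least one spike in it (several spikes on one electrode
count once; the trailing partial bin is dropped to avoid a fractional-bin
rate bias). A network spike is a maximal run of bins whose count *strictly
exceeds* `ns_threshold = 10` — "more than 10" is read literally, and runs
separated by even a single sub-threshold bin stay distinct (no merging;
both choices are configurable contracts, not tunables). Event duration is
run length × bin width; the array values are events/min and the medians of
event peak and duration, `NA` when no event occurred.

## Pairwise correlation (feature 10)

The spike time tiling coefficient of trains A and B with coincidence window
$\Delta t$ is
$$\mathrm{STTC} = \tfrac12\left(\frac{P_A - T_B}{1 - P_A T_B} +
  \frac{P_B - T_A}{1 - P_B T_A}\right)$$
with $P_A$ the proportion of A's spikes within $\pm\Delta t$ of some spike
of B (closed comparison: $|t_a - t_b| \le \Delta t$, fixed for
reproducibility although measure-zero for continuous times) and $T_A$ the
proportion of the recording covered by the union of $\pm\Delta t$ windows
around A's spikes, clipped to the interval. Unlike a binned correlation
coefficient, the tiling construction is insensitive to firing rate and
suits sparse developmental data. Defaults: $\Delta t = 5$ ms; 50 ms and
0.5 ms are customary sensitivity settings.

Degenerate cases are explicit: an empty train gives `NA` (a pair with no
spikes carries no evidence — scoring it 0 would bias sparse, young
recordings), and a denominator of zero (only possible when $P = T = 1$)
contributes a zero term. The array value is the mean over the
$N(N-1)/2$ distinct pairs with defined STTC. Distances are Euclidean in
electrode coordinates; the pipeline reports the mean rather than a
distance model because pairwise correlations in cultured networks show
little distance dependence.

## Theta bursting (feature 11)

An electrode is *theta bursting* when the smoothed density of its
log₁₀-ISIs has a prominent peak between 0.1 and 0.25 s — equivalently, in
the 4–10 Hz band; the two phrasings are exact reciprocals. The density is
the Gaussian kernel estimate with the rule-of-thumb bandwidth
(`bw.nrd0`: $0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$) on a
512-point grid spanning the data range ±3 bandwidths — i.e. R's default
`density()`, pinned by formula so results cannot drift with environment
defaults. Electrodes need `min_isi = 10` ISIs for a usable density;
electrodes below that stay in the denominator of the array fraction (the
fraction is of electrodes on the array, the conservative choice for sparse
recordings) but cannot contribute to the numerator.

**Peak rule.** A qualifying peak is an interior local maximum whose
*topographic prominence* — height above the key col on the best route to
higher ground, or above the global minimum for the tallest peak — is at
least `min_prominence = 0.05` of the density maximum. A bare
interior-maximum rule (prominence 0, available by option) counts sampling
wiggles of the KDE as peaks and false-labels roughly 10% of strongly
bursting non-theta trains; measured wiggle prominences sit below 0.02 of
the maximum while genuine theta peaks exceed 0.2, so 0.05 separates the
regimes with an order of magnitude of margin on both sides. Boundary grid
points never count as peaks.

## The feature vector, group statistics, and classification

`feature_vector()` assembles the 11 features; every undefined value is an
explicit `NA`, and one undefined feature never invalidates the vector.
Downstream ML imputes `NA`s with the training-fold median (computed inside
each split — no leakage), which is the pragmatic choice for young
recordings that lack bursts.

Per (feature, age) cell with both groups present, `comparison_table()`
applies the two-sided Mann–Whitney test: the exact null distribution when
the combined sample is ≤ 20 without ties, otherwise the normal
approximation with midranks, tie-corrected variance and continuity
correction. p-values are Benjamini–Hochberg adjusted; the correction family
pools all feature × age cells (the conservative reading; per-feature
families are an option). Stars: `*` below 0.05, `**` below 0.01, on
adjusted values.

`pca_project()` centres and scales each feature to unit variance before the
eigendecomposition (variance normalisation — the features live on wildly
different scales); zero-variance features cannot be scaled and are dropped
with a warning.

Classification is per age group: a recording's label (CTX/HPC) is predicted
from its 11 features by either

* a **random forest** — 500 bagged CART trees, Gini splitting, `mtry =
  ⌊√11⌋ = 3` features per split, grown to purity; implemented in compiled
  code in this package (no tree package is assumed present) with exact
  bookkeeping of the mean decrease in Gini impurity, which after averaging
  over repeats is normalised so the top feature scores 1; or
* an **RBF-kernel SVM** — C-classification solved by sequential minimal
  optimisation, γ = 1/11, C = 1 (C is unreported in the source analyses; 1
  is the conventional default), features standardised with training-fold
  statistics.

Performance is the mean percentage of correct held-out classifications over
`n_repeats = 500` random splits into ⅔ training and ⅓ test. Splits are
stratified by class — with tens of recordings per age an unstratified split
regularly empties a class from the test set; stratification makes every
split usable and is therefore the default. All stochastic steps take
explicit seeds, with repeat *r* seeded by a fixed arithmetic rule from the
master seed. `incremental_performance()` re-evaluates with the top-*k*
features of a ranking for *k* = 1…11, and `importance_table()` produces the
feature-ranking × age accuracy matrix.

The description of the tree method in the source analyses conflates
boosting with bagging ("trees with boosting (random forests)"); this
package implements a random forest — bagging plus per-split feature
subsampling — which is what the parenthetical names; `ntree = 1` with
`mtry = 11` recovers a single bootstrapped classification tree.

## The synthetic-data generator

`generate_train()` models one electrode as background Poisson firing
superposed on a renewal process of burst events: interburst intervals are
gamma with mean 60/`burst_rate` seconds and coefficient of variation
`ibi_cv` (shape 1/cv², the simplest renewal family with a free CV; cv = 0
degenerates to clockwork bursting). Each burst emits a
Poisson(`spikes_per_burst`) number of spikes with exponential ISIs at
`within_burst_rate`. Theta electrodes instead emit spike *doublets*
recurring at theta intervals (inter-doublet gaps lognormal with median
0.15 s, sdlog 0.1; intra-doublet gaps at `within_burst_rate`), the
complex-spike-like patterning that puts the tallest log-ISI mode inside
0.1–0.25 s. An earlier design drew *all* within-burst ISIs from the 0.15 s
lognormal, but a pure 0.15 s process can never open a max-interval burst
(0.15 > `max_begin_isi` = 0.1), so theta electrodes would only have had
sporadic chance-opened bursts and their CV of IBI would have been thinning
noise rather than the planted value; the doublet model keeps bursts
deterministically detectable while preserving the theta signature.

`generate_recording()` creates array structure with a master/slave scheme:
one master renewal burst schedule per array; each electrode keeps
1 − `shared_fraction` of its private bursts and adopts master bursts with
probability `participation_p` · `shared_fraction`, onsets jittered by
`jitter_sd`. One mechanism thus produces both network spikes and
distance-flat pairwise correlations. Per-electrode random streams are
derived from the master seed by a fixed splitting rule, so enlarging the
array does not reshuffle existing electrodes, and the same seed reproduces
a recording bit for bit.

`preset_profile(region, age_div)` encodes the developmental story used
throughout testing: both regions ramp burst rate, firing and shared
bursting from DIV 7 to 14 and then plateau; relative to CTX at the same
age, HPC presets have a lower `ibi_cv`, a higher shared fraction and
participation, and theta on a majority of electrodes when mature (65% at
DIV ≥ 14, inside the 50–75% range typical of mature hippocampal cultures;
CTX stays at 5%). Two calibration notes, both fixed at design time:

* Parameters *outside* the planted contrasts (background rate, burst rate,
  spikes per burst, within-burst rate, jitter) are identical across regions
  at the same age, so the class signal lives in the three planted
  contrasts. The within-burst rate is 30 Hz: high enough that plain-burst
  ISIs (~33 ms) stay well below the theta band, low enough that the
  unavoidable burst-shape difference between doublet-paced theta
  electrodes (~13 Hz) and plain electrodes is a factor ~2–3 rather than
  ~7.
* An electrode's realised burst train is a thinned union of its private and
  the master schedule, which pushes the measured per-electrode CV of IBI
  towards 1 whatever is planted; the planted CVs (HPC 0.4–0.5, CTX
  1.1–1.3) are therefore wider apart than the target electrode-level
  contrast (~0.75 vs ~0.93 measured).

`simulate_cohort()` adds array-level heterogeneity: each simulated
recording multiplies its rate- and size-like parameters by independent
lognormal factors (sdlog 0.5). Real same-age cultures spread over an order
of magnitude in firing magnitude while the patterning contrasts are
consistent; omitting this made every simulated array a near-replicate,
which no real cohort is.

**What the generator does not emulate** — and hence what a green test does
not establish: no biophysics (no membrane or synapse models), no
development *within* a recording, no electrode-level reliability
differences, no spatial structure beyond the shared-burst process (planted
theta electrodes are assigned, not spatially clustered), and no attempt to
match absolute magnitudes of real data beyond the ordinal relations above.
Green parameter-recovery and classification tests certify the pipeline's
internal consistency on a stated world, not biological realism.

## Numerical and degenerate-input choices

* Tile coverage merges overlapping windows via a running maximum over the
  sorted window ends; coincidence testing uses closed intervals.
* STTC of identical trains is 1; empty trains give `NA`; `P·T = 1` terms
  contribute 0.
* The Mann–Whitney U counts ties as ½; the exact branch doubles the
  smaller tail (capped at 1), which for the symmetric tie-free null equals
  the enumeration definition.
* BH adjustment: `p̃₍ᵢ₎ = min₍ⱼ≥ᵢ₎ min(1, m·p₍ⱼ₎/j)`, returned in input
  order, `NA`s passed through in place.
* KDE bandwidths below 10⁻⁶ (near-constant ISIs) are floored at 10⁻³ so a
  point mass still yields a usable unimodal density.
* Forest vote ties (possible with an even tree count) fall to the first
  class level deterministically.
* Seeds derived from a master seed use fixed affine rules modulo a prime
  below 2³¹, keeping them valid R integer seeds.

## Known limitations

* **Importance ranks under collinearity.** In the synthetic world the
  shared-bursting contrast necessarily also separates classes through the
  network-spike rate (that coupling is the very point of the master/slave
  design), and the theta mechanism leaves a residual within-burst-rate
  gap. With ten recordings per class, five features separate the classes
  essentially perfectly and their normalised Gini importances tie within
  ~3%; the identity of ranks 1–3 is then exchange noise among the tied
  five. The acceptance suite therefore asserts a tie-aware version (the
  three planted contrasts all score > 0.9) and keeps the strict "planted
  trio alone occupies ranks 1–3" test as an expected failure rather than
  weakening it silently.
* **Null classification on finite cohorts.** With a fixed null dataset of
  20 recordings per class, split-averaged held-out accuracy retains
  accidental dataset structure; across master seeds it spans roughly
  44–57% around the 50% ideal. This is a property of finite-sample
  classification, not of the implementation.
* The Mann–Whitney exact branch is limited to combined samples of 20
  without ties; beyond that the tie-corrected normal approximation is
  used, which is standard but approximate for very small tied samples.
* The HDF5 reader trusts `/meta` fields; it validates structure and
  monotonicity but cannot detect semantically wrong metadata.
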