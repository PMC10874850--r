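---
title: "Electrophysiological phenotyping of spike-sorted HD-MEA cultures with meaphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrophysiological phenotyping of spike-sorted HD-MEA cultures with meaphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`meaphys` turns spike-sorted high-density microelectrode array (HD-MEA)
recordings of neuronal cultures into interpretable feature vectors, and uses
those features for phenotype classification, age regression, developmental
statistics and unit-level cell typing. This vignette explains the models and
procedures behind each stage, the parameters that matter, and the choices the
package makes where the underlying methods admit more than one reasonable
definition.

## Data model and quality control

A `mea_recording` holds one culture at one time point: per-unit spike times
(seconds), the spike-triggered multi-electrode mean waveform template (the
unit's electrical footprint), electrode coordinates, and culture metadata
(group label such as genotype, treatment, batch, and age in days in vitro;
weeks are `floor(age_days / 7)`). Readers exist for the phy/Kilosort NPY
layout and for the package's portable JSON + CSV exchange bundle, which
round-trips spike times exactly.

Quality control removes units that fail any of three criteria:

* firing rate above 0.01 Hz over the recording,
* fewer than 2% of inter-spike intervals below the assumed refractory
  period (default 2 ms — the refractory duration itself is a convention, so
  it is a parameter),
* a waveform check requiring a trough of at least 10 µV on the peak
  electrode followed by a positive deflection.

The waveform rule deserves a caveat: "irregular waveform shape" has no
canonical definition across spike sorters, so the package's rule is a
deliberate stand-in — it catches flat and trough-less templates, not every
pathology a curator would. It can be disabled (`check_waveform = FALSE`), and
units with fewer than 2 spikes are dropped with their own reason code so
downstream interval statistics are never computed on degenerate trains.

## The synthetic-culture generator

Every downstream stage is testable without data downloads because the
`simulate` module generates spike-sorted cultures with known ground truth.
The generator emulates, per culture and week:

* **Tonic firing** as a gamma-renewal process per unit. The gamma shape is
  `k = 1 / (1 - regularity)`, so the ISI coefficient of variation is
  `sqrt(1 - regularity)`: `regularity = 0` gives Poisson trains, values near
  1 give clock-like pacemaking. Trains are produced by time rescaling —
  unit-rate gamma renewal in operational time mapped through the inverse
  cumulative intensity — so rate modulation and regularity compose cleanly.
* **Network bursts** as a shared multiplicative envelope: burst onsets from
  a gamma inter-burst-interval process (shape 5 by default, i.e. fairly
  rhythmic bursting), each contributing a peak-normalized double exponential
  (rise 0.3 s, decay 1 s) scaled so the envelope peaks at `burst_gain` times
  the baseline rate. Ground truth records each burst's start, peak and end.
* **Waveforms** as a difference of two Gaussians in time (trough then
  slower positive peak), attenuated exponentially with electrode distance
  over a 17.5-µm-pitch patch. Two archetypes are built in — narrow/small
  versus broad/large — giving unit-level clustering a recoverable truth.
* **Effects**: additive group offsets on any generator parameter (the
  default emulates a synucleinopathy-like phenotype: more bursting, more
  regular firing, higher rates in the mutant group), per-batch lognormal
  rate factors, and per-day developmental slopes anchored at the first
  recording week.
* **Acute pharmacology**: responder units (flagged in ground truth, with
  archetype-specific probabilities) are binomially thinned to a configured
  fraction of their baseline rate, emulating the firing-rate drop of
  D2-receptor-expressing neurons under an agonist.

Defaults describe a 15-minute weekly recording of ~1 Hz units bursting a few
times per minute. What the generator does *not* emulate: electrode drift,
sorting errors (splits/merges), non-stationary waveforms, correlated noise,
or synaptic-level connectivity — so passing tests demonstrate the pipeline's
correctness on clean spike trains, not robustness to sorter artifacts.

All randomness flows from one integer master seed through deterministic
child seeds; no global RNG state is consumed.

## Single-cell features

**Waveform metrics** (eight) are computed on the electrode with the largest
negative template amplitude: trough amplitude, post-trough peak amplitude,
trough-to-peak time, width at half trough depth, pre/post peak asymmetry,
repolarization and recovery slopes, and the peak/trough ratio. The exact
eight-metric set is a standard extracellular collection; the registry is
data-frame based so substituting metrics does not touch the pipeline.

**Spike-time metrics** (four): mean ISI, ISI coefficient of variation (the
regularity measure central to the phenotype), firing rate, and the lag-1
partial autocorrelation of the ISI sequence. Metrics with unmet
preconditions return `NA`, never a silent zero.

**Time-series metrics** (22) are computed on 100-ms-binned activity,
z-scored internally (sample sd throughout the package). The set follows the
canonical time-series feature collections: spectral (peak frequency and its
power, spectral centroid, low-frequency power fraction), autocorrelation
(first 1/e crossing, first ACF minimum, correlation-length change under
differencing), information-theoretic (histogram automutual information,
Gaussian AMI first minimum, Shannon entropy of the 10-bin histogram),
distributional (5- and 10-bin histogram modes, proportion of successive
differences above 0.04 sd), symbolic (tercile transition-matrix covariance
trace, longest above-mean run), fluctuation analysis (rescaled-range and DFA
two-segment breakpoint proportions), forecasting (3-sample mean-forecast
error), embedding (exponential fit to 2-D embedding distances),
time-reversibility, above-mean extreme-event spacing, and the exponential
fit to per-window spectral peaks. Each definition is written out in the
function documentation, and every metric is checked against an independent
literal-definition oracle in the test suite. Where a published description
was ambiguous the package fixes one definition and documents it — e.g. the
"magnitude" of the peak frequency is the periodogram power at that
frequency, and the spectral estimate is the plain periodogram of the
z-scored series with frequencies in cycles per bin.

Degenerate inputs: a constant series returns `NA` for every z-score
-dependent metric; series shorter than 50 bins are rejected. Bins are
left-closed, right-open, anchored at t = 0, with the final partial bin
dropped.

Per-unit features are averaged across units to one culture-level value per
feature, ignoring `NA`s and recording how many units contributed.

## Network features

Population activity is the summed binned spike count of all passing units,
smoothed with a Gaussian kernel (σ = 0.1 s). **Burst detection** thresholds
the smoothed rate at `median + 5 * MAD`, computed per recording, so the
threshold tracks each culture's overall activity as it develops — this is
the package's realization of an activity-adaptive burst detector, with the
median/MAD choice making it robust to the bursts themselves. Intervals are
extended outward to where the rate falls back below the median (capturing
rise and decay phases), merged when closer than 0.1 s, and discarded below
50 ms. Per-recording burst features: rate per minute, mean inter-burst
interval (start to start), mean peak-to-end time, mean duration, mean rise
time, and peak amplitude. Zero bursts yields `NA` features, never zero.

**Connectivity** comes in two flavors. The spike-time tiling coefficient
(STTC) with ±10 ms windows gives a symmetric, rate-robust weight in [-1, 1];
edges are kept above 0.1. The cross-correlogram (CCG) route tests each
ordered pair's short-latency bins (0-10 ms) against surrogates with spikes
jittered uniformly by ±10 ms; an edge is called when the observed maximum
over those bins exceeds the `1 - alpha` quantile of the surrogate maxima.
The max-statistic band (rather than a per-bin band) keeps the per-pair
false-positive rate at `alpha` under the jitter null; jittering preserves
slow rate co-modulation, so the test is robust to the nonstationarity that
bursting cultures guarantee. Graph features are the edge density and the
global efficiency (mean inverse shortest-path length over ordered pairs,
unreachable pairs contributing 0; directed CCG graphs are symmetrized
first). By default the feature pipeline derives density/efficiency from the
STTC graph: the jitter-surrogate CCG over all ordered pairs costs
`O(n_units^2 * n_surrogates)` correlogram evaluations per recording, which
is disproportionate inside a per-recording feature loop; the CCG graph
remains available via `graph_method = "ccg"`.

Network-level time-series features apply the same 22 metrics to the summed
population counts, prefixed `n` versus the single-cell `s`.

## Phenotyping (the ML layer)

The feature matrix is cultures × (weeks × features), week-major, with
feature classes (waveform, spike-time, single-cell time series, burst,
graph, network time series) selectable per analysis. Missing culture-weeks
are imputed with the per-column median of same-group cultures and flagged —
keeping the matrix rectangular without inventing group differences.

Normalization is batchwise z-scoring with parameters estimated on training
rows only; test rows are always transformed with training parameters.
Zero-variance columns map to zero. Batches with fewer than two training rows
fall back to global training parameters with a warning.

Classification is a random forest (500 trees, stratified bootstrap down to
the smallest class) evaluated by leave-one-culture-out cross-validation:
each fold re-estimates normalization without the held-out culture, so no
statistic ever leaks from test to train. Predictor importance is the
out-of-bag permutation importance of the final refit model, reported per
feature or per feature × week. Hyperparameters can be tuned by a seeded
randomized search (tree count, node size, features per split) scored by
inner 5-fold cross-validation; the search is budgeted and deterministic
given the seed.

Age regression uses the same forest machinery on recording-level rows, with
*all* recordings of a culture held out together — a culture's later weeks
must not inform predictions about its earlier ones. The mean absolute error
is reported overall, per true week, and against the predict-the-training-
mean baseline.

A pretrained classifier can be applied to new (e.g. drug-treated) cultures:
the new batches are normalized with their own statistics computed on
control/untreated rows when the batch has any; a batch with no control rows
is normalized on all of its rows and flagged in the output — the choice is
reported rather than hidden because it changes what "shifted toward the
other phenotype" means.

The 2-D embedding is UMAP (15 neighbors, min-dist 0.1, seeded, recorded in
the output metadata), followed by k-means (k = 2) and cluster purity —
the fraction of cultures whose cluster's majority label matches their own.

## Developmental statistics

Per feature, the package fits the linear mixed model
`value ~ 1 + group * time + (1 | culture)` by REML, with sum-to-zero
(effects) coding of group and time in weeks centered at the first observed
week — centering keeps the intercept interpretable as the grand mean at
study start, and effects coding makes the group estimate symmetric under
relabeling. Fixed-effect t-tests use Satterthwaite denominator degrees of
freedom (via `lmerTest`), p-values are Bonferroni-adjusted across features,
and stars are assigned on the adjusted values at 0.05 / 0.01 / 0.001.
Singular random-effect fits are kept but flagged. Whether "time" should be
days or weeks is not fixed by the model; weeks match the recording cadence
and keep slopes of order one.

## Cell typing

Units (rows) are described by waveform features alone or combined with
their activity features (spike-time + single-cell time-series; this is the
package's reading of "waveform plus spike activity"). After column
z-scoring, a k = 15 nearest-neighbor graph feeds seeded Louvain community
detection; clusters are relabeled by descending size with ties broken by
the smallest canonical unit key, so labels are invariant to row order.

The Louvain resolution defaults to 0.5 rather than the textbook 1.0: on a
kNN graph, modularity at resolution 1.0 subdivides even a tight,
well-separated cloud of near-identical units into arbitrary sub-communities,
which is never the wanted granularity for cell typing; 0.5 yields one
community per separated cloud while still splitting genuinely multi-modal
data. Raise the resolution to look for finer structure. Two further guards
handle degenerate inputs: feature columns that are constant up to numerical
noise are dropped before z-scoring (z-scoring would amplify that noise to
unit variance), and a unit cloud with no spread at all returns a single
cluster.

A random-forest cluster classifier (stratified 5-fold CV, OOB permutation
importance, undersized clusters merged into their nearest centroid) predicts
cluster composition for new cultures, with per-culture fractions summing
to one. Perturbation mapping compares matched units before and after acute
drug addition; a unit is a responder when its rate ratio drops below
`1 - decrease_threshold`. The 10% default for "a firing-rate decrease" is a
convention, stated in the output, and deliberately prominent here: the
responder fractions reported downstream move with it.

## Numerical choices and problem sizes

* Sample (n-1) standard deviations everywhere.
* Histogram bins for the entropy/mode/AMI metrics are equal-width over the
  observed range; boundary values use left-closed, right-open intervals
  with the top edge closed.
* The ACF is computed via FFT with zero padding to a highly composite
  length; first-crossing lags are integer bins.
* Ties in spectral argmax resolve to the lowest frequency; ties in
  histogram modes average the tied bin centers.
* The test suite and the acceptance script exercise the full pipeline at a
  deliberately desk-sized study: two groups × 10 cultures × 5 weekly
  recordings, 12 units per culture, 4-minute recordings (burst-detection
  checks use 20 units / 5 minutes; cell-typing checks 2 × 40 units). These
  sizes were chosen so the complete suite runs comfortably on one CPU while
  every statistical check retains power; all of them scale up by
  configuration only.

## Known limitations

* The waveform-irregularity QC rule and the burst-detector adaptation are
  package-defined conventions (documented above), not community standards.
* The CCG edge test is a jitter-surrogate substitute for analytically
  calibrated correlogram tests; it trades power for robustness to rate
  nonstationarity.
* Median imputation of missing culture-weeks is flagged but simple; studies
  with systematically missing late weeks should subset weeks instead.
* The simulator's realism bounds what green tests demonstrate (see above);
  conclusions about sorter-artifact robustness require real recordings.
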