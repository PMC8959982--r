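---
title: "Phase-locking brain networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking brain networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plvnet` turns multichannel resting-state EEG into band-resolved binary
brain networks via the phase-locking value (PLV), extracts node-level graph
attributes from single-layer and multilayer networks, and classifies two
subject groups from those attributes. This vignette explains the models and
the decisions behind the implementation; the README shows the surface API.

## The measurement model

One sample is one 20 s segment of one subject. For a segment, channel pair
$(x, y)$ and band $a$, the connection strength is

$$\mathrm{PLV}_{xy} = \Bigl|\bigl\langle e^{\,i(\theta_x(t) - \theta_y(t))}\bigr\rangle_t\Bigr|,$$

where $\theta_x(t)$ is the instantaneous phase of channel $x$ extracted by a
complex Morlet wavelet centered at the band's midpoint frequency. PLV is 1
for perfectly phase-locked channels, and for $n$ independent uniform phases
its null expectation is $\sqrt{\pi} / (2\sqrt{n})$ — the modulus of a mean
of random unit phasors. Thresholding the PLV matrix (strictly greater than,
default 0.71) gives an undirected binary network whose nodes are the 8
electrodes.

Per node $i$ the package computes degree $d_i$, local clustering
$C_i = \#\text{triangles}_i / \binom{d_i}{2}$, local efficiency
$E_i = \langle 1/l_{jk} \rangle$ over ordered pairs of $i$'s neighbours
with shortest paths inside the neighbour subgraph, and connectivity
robustness $R_i = d_{\mathrm{avg}} / (N - 1)$, the mean degree of the graph
after deleting $i$, scaled by $N - 1$. Multilayer attributes sum these
node-wise across band layers: unweighted ($D_{mi} = \sum_a D_i^a$, "MN") or
weighted by the sample's power-spectral ratio of each layer band
($D_{mi} = \sum_a \partial_a D_i^a$, "IMN"), with
$\partial_a = P_a / \sum_b P_b$ from the Welch–Hamming spectrum of that
same segment.

Assumptions worth keeping in mind: electrodes stand in for regions (no
source localization), volume conduction is not corrected (with 8 widely
spaced electrodes and a phase-sensitive measure its influence is limited but
not zero), and binarization discards all strength information except the
ordering around the threshold.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| bands | δ 0.5–4, θ 4–8, α 8–13, β1 13–20, β2 20–30 | Hz | standard clinical bands |
| broadband filter | 0.1–30 | Hz | removes drift and line/high-frequency content before segmentation |
| retained window | 80 | s | four 20 s segments per subject |
| segments | 4 | — | one segment = one classification sample |
| Welch window / overlap | 2 s / 50% | — | ≥ 1 Hz resolution covering the 0.5 Hz δ edge while averaging ~39 windows per 80 s |
| wavelet width | 7 | cycles | standard Morlet trade-off; bandwidth ≈ $2 f_0 / 7$ stays inside each band |
| PLV edge trim | 1 | s per end | discards wavelet edge effects before averaging phasors |
| threshold | 0.71 | PLV | default edge criterion; `sweep_thresholds()` scans 0.11–0.91 in 0.1 steps |
| multilayer bands | α, β1, β2 | — | the three layers entering MN/IMN |
| selector / k | filter / 20 | — | top-k by two-sample t statistic, refit per fold |
| folds | 10 | — | stratified, without repeated sampling |
| RF trees; boosting rounds; η; depth / leaves | 500; 200; 0.1; 3 / 31 | — | conventional small-data settings, overridable via `params` |

## What the synthetic generator emulates — and what it does not

`generate_subject()` builds each channel as a sum over the five bands of
narrow-band Gaussian processes. Within a band, a channel mixes *per-pair
shared* processes (amplitude weight = the coupling matrix entry) with a
*private* process whose weight keeps the band variance at 1; the group's
band amplitude then scales the band, and white measurement noise
(SD 0.5 relative, 10 µV per relative unit) is added. Coupling 1 on a pair
makes the two channels' band signals identical (PLV 1); coupling 0 leaves
them independent.

The default cohort (2 × 20 subjects, 80 s at 1,000 Hz) plants two group
contrasts: the patient-like group has δ, θ amplitudes ×1.5 and α ×0.6
relative to controls, and α-band coupling on the four homologous pairs
(FP1–FP2, C3–C4, T3–T4, O1–O2) of 0.6 versus 0.95 in controls. Two findings
from calibrating this design with the *full pipeline in the loop* (not on
isolated signal pairs):

* when a channel joins several shared processes, the unit-variance
  renormalization dilutes each pair's effective coupling — which is why the
  α contrast sits on disjoint homologous pairs;
* the common average reference mixes a fraction of every channel into every
  other and costs roughly 0.1 of PLV at high coupling.

With these defaults a coupling of 0.95 measures PLV ≈ 0.8 through the
pipeline and 0.6 measures ≈ 0.3, so at threshold 0.71 only control-group α
networks retain edges. The contrast is therefore *strong by construction*:
passing recovery tests shows the pipeline separates groups when a clean
α-band difference exists, not that real clinical effect sizes (which are
unpublished for this design) are attainable. The generator also omits
artifacts (blinks, EMG), 1/f background structure, head-model volume
conduction, and non-stationarity — so preprocessing is exercised only for
its numerical contracts, not its artifact-rejection value.

## Numerical choices

* **Filtering is zero-phase in the frequency domain** with raised-cosine
  transition bands (0.5 Hz, narrowed near 0 Hz). A forward–backward IIR
  band-pass was the obvious alternative, but a 4th-order Butterworth at a
  normalized edge of 2·10⁻⁴ (0.1 Hz at 1,000 Hz) is numerically unstable in
  double precision; the spectral implementation is unconditionally stable,
  exactly zero-phase (the PLV would be corrupted by phase distortion), and
  meets the stop-band contracts (a 50 Hz tone leaves < 1% RMS).
* **Welch PSD** is implemented directly (Hamming taper, one-sided density
  scaled so the integral matches the variance) since the installed signal
  stack provides no averaged periodogram.
* **Preprocessing order**: average reference → window selection → band-pass
  → z-score. The high-SNR window (ratio of 0.5–30 Hz power to total power,
  1 s stride) must be chosen *before* the band-pass — afterwards the ratio
  is constant — and z-scoring comes last so retained channels have mean 0,
  SD 1 exactly.
* **Ties and degenerate inputs**: edges require PLV strictly above the
  threshold (ties excluded); $C_i$ and $E_i$ are 0 for degree < 2;
  disconnected neighbour pairs contribute $1/l = 0$; the small-world σ is
  computed on the largest component (flagged) against 100 seeded
  degree-preserving rewirings; all-zero band power raises an error rather
  than dividing by zero; classifiers drop zero-variance features and fall
  back to the majority class when nothing varies (a degenerate fit some
  tree implementations handle poorly).
* **Determinism**: every stochastic step (generation, fold assignment, tree
  ensembles, rewiring nulls) derives from an explicit seed; subjects use
  substreams keyed by (seed, group, index) so generation order is
  irrelevant.

## Design choices where the design was open

* **∂ granularity and normalization**: the power ratios are computed per
  subject-segment (each sample gets its own weights) and normalized over
  the three multilayer bands, so IMN weights form a convex combination and
  Eq-style identities hold exactly: unit weights reproduce the plain
  multilayer sum, and equal weights on identical layers reproduce the
  single layer. Normalizing over all five bands instead would only rescale
  the weights per sample; the convex-over-layers choice keeps IMN invariant
  to overall signal scale.
* **PLV per segment, not per 80 s record**: the classifier operates on
  4 segments × subjects, so connectivity is estimated on the same unit that
  is classified.
* **Multilayer baseline uses the same three bands as IMN** (α, β1, β2), so
  the MN/IMN comparison isolates the effect of the spectral weights;
  `cohort_connectivity(multilayer_bands=)` switches to five.
* **Two boosted ensemble members**: both are gradient-boosted tree
  classifiers with log-loss; "lgbm" grows leaf-wise (histogram, ≤ 31
  leaves), "gbst" depth-wise (depth ≤ 3). A survival-model objective would
  be meaningless here — the task has no event times — so the
  survival-boosting member is interpreted as its classification analogue.
* **Sample unit and leakage**: the default design treats each segment as a
  sample (folds stratified over segments), matching the segment-level
  protocol the pipeline mirrors. Because four segments share a subject,
  `group_by_subject = TRUE` keeps a subject's segments in one fold; the
  permutation-null and stationarity checks in the test suite use
  subject-level permutation with subject-grouped folds, the leak-free null
  for this design (segment-level permutation of subject-correlated features
  is biased by within-subject label dependence).
* **KS selection fallback**: if no feature passes p < 0.001, the single
  smallest-p feature is kept so downstream models remain defined; the
  calibration test counts sub-threshold p-values, not the fallback.

## Problem sizes

The test suite exercises module contracts on small cohorts (2–4 subjects
per group, 250 Hz, 8–24 s) and runs the end-to-end recovery, null
calibration, and stationarity checks on one study-scale cohort
(2 × 20 subjects, 1,000 Hz, 80 s, 160 samples), shared across checks via
memoization. Graph-metric correctness is established exactly against a
brute-force oracle on 200 random graphs (N = 4–10, edge densities 0.2, 0.5,
0.8).

## Known limitations

* Eight electrodes give an N = 8 network: the `2 ln N / N` sparsity bound
  (≈ 0.52) is demanding at this size, and σ estimates on sparse 8-node
  graphs are noisy; the diagnostics report flags rather than hard errors.
* The EDF writer quantizes to 16-bit over each channel's observed range;
  round trips are exact only to one quantization step.
* The null expectation $\sqrt{\pi}/(2\sqrt{n})$ applies to independent
  phase samples; narrow-band signals decorrelate at roughly the inverse
  bandwidth, so segment-level PLV of independent channels sits well above
  that bound — comparisons against "no coupling" should use the empirical
  null (as the tests do), not the analytic one.
* Classification accuracies on the synthetic cohort characterize the
  pipeline, not any clinical population; absolute values depend directly on
  the planted effect sizes, which are design choices.
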