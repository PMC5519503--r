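---
title: "Methods: multiscale phase-synchrony networks and regional metabolism"
author: "phasefc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale phase-synchrony networks and regional metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasefc)
```

## The analysis in one paragraph

`phasefc` asks how regional molecular measures — protein synthesis rate
(rCPS, from L-[1-11C]leucine PET, nmol/g/min) and glucose uptake (SUV, from
[18F]FDG PET) — relate to a region's role in the brain's functional
network, and how that role varies with the temporal scale of BOLD
dynamics. Parcellated resting-state BOLD series are decomposed into dyadic
frequency bands; band-limited instantaneous phases give a pairwise
phase-synchrony connectivity matrix at every timepoint; graphs thresholded
for maximal cost-efficiency yield four node metrics (strength, clustering
coefficient, local efficiency, betweenness centrality), computed both on
the time-averaged ("static") connectivity and per timepoint ("dynamic"),
the latter summarized by each node's temporal coefficient of variation
(CV). A repeated-measures GLM with regions as units and scale as the
within-unit factor then tests whether the PET covariates predict the
metric profiles, with Mauchly sphericity testing and Greenhouse-Geisser
correction, followed by per-scale (partial) Pearson correlations under
Bonferroni control.

## Band-limited analytic phase

### Approximate Hilbert wavelet pairs

A meaningful instantaneous phase requires an analytic (positive-frequency)
band-limited signal. Rather than Hilbert-transforming bandpassed data,
the package uses two real orthonormal wavelet filter banks whose wavelets
form an approximate Hilbert pair: running both banks and combining the
outputs as real and imaginary parts yields analytic coefficients per
scale. `designHwpFilters()` implements the common-factor construction:
both scaling filters share `K` zeros at Nyquist and a spectral factor
`Q(z)` obtained by solving the orthonormality (halfband) conditions as a
linear system and taking the minimum-phase spectral factor; they differ by
a degree-`L` maximally flat (Thiran) polynomial versus its time reverse,
an all-pass ratio approximating the half-sample delay that makes
`psi_h + i psi_g` analytic. Design orders 1–4 map to
`(K, L) = (2,1), (3,1), (3,2), (4,2)`; the default order 2 gives 8-tap
filters whose combined wavelet leaves about 0.3% of its energy at negative
frequencies. Both banks are orthonormal to machine precision and share an
identical magnitude response exactly (the delay factor is all-pass), so
the two banks see the same frequency content and differ only in phase.

### Transform, scale labels, and the Nyquist caveat

`modwtPacketDecompose()` runs the undecimated (maximal-overlap) transform
pyramid with circular boundary handling — the standard convention, with
the first `(2^j - 1)(L_f - 1)` coefficients per level flagged as
boundary-affected rather than trimmed. At each level the occupied
low-frequency node is split, so the natural output order is already
frequency-ordered and no Gray-code permutation is needed. For a 1200-volume
acquisition the supported depth is `floor(log2(1200)) + 1 = 11` scales:
ten detail bands plus the final approximation.

Scale labels deserve care. The nominal band printed for scale `j` follows
the convention of indexing dyadic bands from the sampling rate
`fs = 1/TR`: `[fs/2^j, fs/2^(j-1)]`, which for TR = 0.72 s gives
0.69–1.39 Hz at scale 1 — above the Nyquist frequency, as that labelling
convention concedes. The physical passband of the underlying detail level
is one octave lower (`[fs/2^(j+1), fs/2^j]`). `scaleBandTable()` reports
both; all tone-localization tests and the synthetic generator's
scale targeting use the physical passband, while the nominal edges
reproduce the conventional printed table. Scale 1 (nominal band above
Nyquist) and the very slow scales 9–11 (periods approaching the
acquisition length) are computed and flagged for completeness rather than
excluded.

### Phase extraction and decimation

Phase is the elementwise argument of the analytic coefficients; exact
zeros (no defined phase) become 0 with a warning. Because raw
instantaneous-phase estimates fluctuate rapidly, the phase series is
decimated by 4 (configurable) with an anti-aliasing FIR lowpass. The
smoothing acts on the unit-modulus representation `exp(i*theta)`, not on
raw angles, so wrap-around at ±π cannot create spurious transients; the
linear-phase filter (length `8*factor + 1`, cutoff 0.8 of the decimated
Nyquist) is applied forward-backward for zero net phase, then every
fourth sample is kept and the angle re-extracted. Whether to smooth in
the complex domain was a genuinely open choice — smoothing raw angles is
simpler but provably wrong near the seam — and the complex route costs
nothing while being exact for constant phase.

## Pairwise phase synchrony

The connectivity weight between regions x and y at time t is the modulus
of the two-oscillator Kuramoto order parameter,

$$R_{xy}(t) = \left|\tfrac12\left(e^{i\Theta_x(t)} + e^{i\Theta_y(t)}\right)\right| = \left|\cos\frac{\Theta_x(t)-\Theta_y(t)}{2}\right| \in [0, 1].$$

The averaged form of the order parameter is complex; the modulus is taken
because all downstream graph analysis requires nonnegative real weights —
this is the standard order-parameter convention. R depends only on the
phase difference and equals 1 for identical phases, 0 in antiphase and
`sqrt(2)/2` in quadrature. Under fully independent uniform phases the
temporal mean is `E|cos(U/2)| = 2/pi ≈ 0.637`: the *chance floor* of this
connectivity measure, a useful reference when reading static FC matrices.
Static FC is the temporal mean of `R_xy(t)`; no variance-stabilizing
transform is applied. The diagonal is stored as 1 and zeroed before any
graph metric (self-loops excluded).

## Network thresholding and node metrics

Thresholds are chosen by cost-efficiency maximization
(`costEfficiencyThreshold()`): for each candidate cost `k` (default grid
0.05–0.50 in steps of 0.01) the weight cutoff achieving that edge density
is found, the graph is binarized, and the score `E_glob − k` (binary
global efficiency minus wiring cost) is maximized, ties breaking toward
the sparser network. The cutoff — not the cost — is then applied, and the
surviving weights are kept (`applyThreshold()`), so metrics are computed
on weighted graphs. Thresholds may come from the same subject
(`per_subject`), from the mean over an independent group
(`groupMeanThreshold()`, mirroring the design in which thresholds are
estimated in 20 held-out subjects), or be fixed.

The four node metrics follow the Brain-Connectivity-Toolbox conventions;
where the weighted generalization is not unique, one variant is fixed and
stated:

* **Node strength** — sum of incident link weights.
* **Clustering coefficient** — geometric-mean (Onnela) weighted
  triangles over connected triples, on weights max-normalized per graph;
  reduces exactly to the binary textbook definition on 0/1 graphs.
* **Local efficiency** — weighted global efficiency (mean inverse
  shortest path length, edge length `1/w`) of each node's
  neighbour-induced subgraph.
* **Betweenness centrality** — unnormalized shortest-path counts through
  each node, lengths `1/w`, fractional credit over ties.

The reciprocal-weight path length is the standard mapping for
synchrony-type weights (strong synchrony = short distance). Timepoints
whose thresholded graph is empty yield zero metrics and a warning.

## Temporal stability

`temporalCV()` summarizes each node metric's dynamic series as
population-SD/mean. The population (divide-by-n) convention is fixed for
bit-reproducibility; at ~300 decimated timepoints the sample/population
difference is negligible. Series whose mean is below 1e-12 return a
flagged `NA` rather than an unstable ratio. By default the pipeline
excludes boundary-affected timepoints from CVs, since circular-convolution
transients inflate variance estimates; this is configurable. Per-subject
tables are combined by `subjectAverage()` (elementwise mean, `NA`s dropped
with a count).

## Association models

`rmGlm()` fits the repeated-measures ANCOVA with regions as units, scale
as the within factor and one or two z-scored PET covariates (the F
statistics are invariant to the scaling; conditioning improves). The
covariate main effect is the regression on the scale-averaged metric with
denominator df `n_regions − 1 − n_covariates` — 80 for one covariate and
79 for two at 82 regions. The covariate-by-scale interaction comes from
the multivariate regression of the orthonormal scale contrasts, with
Type III (partial) sums of squares — the decomposition is stated because
with two correlated covariates the choice matters. Greenhouse-Geisser
epsilon (`tr(S)^2 / ((k-1) tr(S^2))` on the contrast covariance) corrects
the interaction degrees of freedom; corrected and uncorrected p-values are
both always reported, with the convention that the correction is *applied*
when Mauchly's test rejects at 0.05. The Mauchly chi-square approximation
includes the usual second-order Box term and matches
`stats::mauchly.test` (used only as a cross-check in the test suite, never
as the implementation). Post-hoc per-scale Pearson correlations — partial
with respect to a covariate of no interest when two tracers are supplied —
are Bonferroni-corrected with family size `scales × metrics` (44 for the
standard run), configurable.

The model is calibrated: under a null with no covariate effect (82 regions
× 11 scales), the main-effect type-I error at α = 0.05 is verified to lie
in [0.04, 0.06] over 2000 replicates.

## The synthetic generator: what it emulates and what it does not

`simulateCoupledBold()` integrates Kuramoto phase oscillators (Euler–
Maruyama, internal step TR/10, stability guard `K·deg·dt ≤ 0.5`) on an
all-to-all coupling matrix with planted hubs
(`makePlantedHubNetwork()`: hub-incident edges 3× the base weight, 15%
lognormal jitter), emitting `sin(theta)` plus white observation noise at
TR = 0.72 s for 1200 volumes over 82 regions. Intrinsic frequencies are
drawn uniformly in 0.04–0.08 Hz, so the planted structure concentrates in
a known band (physical passband of scale 4). Defaults were fixed once as
the study conditions:

* `globalCoupling = 0.25`, `phaseNoiseSd = 0.4`: calibrated so the
  network sits in *partial* synchrony — mean pairwise synchrony ≈ 0.8 at
  the intrinsic scale, between the 2/π chance floor and full lock. The
  phase noise is deliberately the synchrony-limiting term: if the
  intrinsic-frequency draw dominated instead, a node's synchrony would
  reflect its luck in the ω lottery rather than its structural coupling.
  At `K = 0` the pipeline recovers the 2/π floor; at strong coupling with
  no noise it locks completely — both limits are tested.
* `noiseSd = 0.3`: a moderately noisy observation of a unit-amplitude
  oscillation.
* No hemodynamic convolution: the generator validates the *pipeline*
  (phase extraction through association statistics), not a biophysical
  forward model; an optional first-order lowpass exists but is off by
  default.

`synthPetVectors()` draws the two tracers by a Gaussian copula so rCPS
correlates with hubness at `rhoHub` and with SUV at `rhoBetween`
(defaulting in examples to 0.63, the empirically observed tracer
correlation this emulates), then maps to positive values on realistic
scales (rCPS ≈ 2 nmol/g/min, SUV ≈ 5).

Passing recovery tests on these data therefore shows that the pipeline
detects planted network structure and PET associations of realistic
magnitude under oscillator dynamics; it does not show robustness to
hemodynamic filtering, head motion, physiological confounds, or
parcellation choices, none of which the generator emulates.

## Numerical choices and degenerate inputs

* Circular MODWT boundaries; boundary-affected coefficients flagged, not
  trimmed; excluded from CVs by default.
* Region order is ascending atlas label everywhere; label 0 is
  background; negative labels are rejected; ROI means are unweighted over
  all labelled voxels.
* Cost-efficiency ties break toward lower cost; binarization at a cutoff
  never resurrects zero-weight (absent) edges.
* A metric profile with no across-scale variance (perfect fit) reports a
  zero interaction F rather than 0/0; a zero within-variance contrast
  covariance reports ε = 1 and W = 1.
* All randomness flows from one top-level seed through `deriveSeed()`
  (fixed affine map, values kept below 2^31).

## Problem sizes used in the shipped validation

The test-suite and acceptance script run the full study geometry — 82
regions × 1200 volumes, 11 scales — for the parameter-recovery suite
(20 simulated cohorts), and 2000 replicates for the type-I calibration;
unit tests use smaller geometries (4–40 regions, 128–600 volumes) chosen
so each property is expressed well away from its decision boundary.

## Known limitations

* The betweenness and efficiency path semantics assume `1/w` lengths; for
  weights other than synchrony in [0, 1] the local-efficiency bound of 1
  no longer holds.
* The repeated-measures model treats regions as exchangeable units, as in
  the population-average analysis it implements; spatial autocorrelation
  between neighbouring regions is not modelled.
* `rmGlm()` supports at most two simultaneous covariates (the analyses it
  serves need one or two).
* The exact filter coefficients of published Hilbert-pair designs vary by
  author; this package fixes one documented common-factor design rather
  than reproducing any specific published coefficient table.
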