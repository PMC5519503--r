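# phasefc

Multiscale phase-synchrony brain networks and their relation to regional
metabolism.

## What this package does

Functional "hub" regions of the brain — nodes with high connectivity
strength and centrality in resting-state networks — are metabolically
expensive, and maintaining their connectivity over time plausibly requires
ongoing protein synthesis. `phasefc` implements the full analysis chain
for testing that idea with region-level PET covariates: regional protein
synthesis rate (rCPS, nmol/g/min, from L-[1-11C]leucine PET) and glucose
uptake (SUV, from [18F]FDG PET) are related to static and *dynamic*
graph-theoretic properties of phase-synchrony functional connectivity
computed from parcellated BOLD time series. It is intended for
neuroimaging researchers working with parcellated resting-state fMRI
(e.g. 82-region Desikan-Killiany + subcortical segmentations at
TR = 0.72 s) and matched regional PET vectors.

The pipeline:

1. **Band-limited analytic phase** — each regional BOLD series is
   decomposed by a maximal-overlap (undecimated) wavelet transform built
   on an approximate *Hilbert wavelet pair* (two orthonormal filter banks
   whose combination h + i·g is near-analytic), giving an instantaneous
   phase Θ(t) in each dyadic frequency band; phases are decimated by 4
   with an anti-aliasing FIR applied to e^{iΘ}.
2. **Pairwise Kuramoto synchrony** — connectivity between regions x, y at
   time t is R_xy(t) = |(e^{iΘx} + e^{iΘy})/2| = |cos((Θx − Θy)/2)| ∈
   [0, 1]; static FC is its temporal mean, dynamic FC the per-timepoint
   matrices.
3. **Cost-efficiency thresholding and node metrics** — the weight cutoff
   maximizing E_glob − cost is selected per graph; node strength,
   clustering coefficient (Onnela weighted), local efficiency and
   betweenness centrality are computed on the thresholded weighted graph,
   statically and per timepoint; temporal stability is each node metric's
   coefficient of variation (SD/mean) over time.
4. **Association statistics** — repeated-measures GLMs with regions as
   units, wavelet scale as the within factor and one or two PET
   covariates (F tests with df2 = n_regions − 1 − n_covariates; Mauchly
   sphericity; Greenhouse-Geisser correction), plus per-scale (partial)
   Pearson correlations with Bonferroni control.

A coupled Kuramoto-oscillator generator with planted hub regions and
copula-linked synthetic PET vectors (`simulateCoupledBold()`,
`synthPetVectors()`) lets the entire pipeline run and validate with no
external data.

## Worked example

Simulate a study-sized synthetic dataset (82 regions, 1200 volumes at
TR = 0.72 s, 4 planted hubs, partial synchrony), run the core chain, and
fit the combined two-tracer association model:

```r
library(phasefc)

spec <- simulationSpec(seed = 7)
roi  <- simulateCoupledBold(spec)
mp   <- multiscalePhase(roi)
mp
#> MultiscalePhase: 11 scales x 82 regions x 300 timepoints (decimated x4)
#>  passbands: 0.3472-0.6944 Hz (scale 1) ... 0-0.0006782 Hz (scale 11)

fc  <- staticFC(mp, scaleIndex = 4)   # passband 0.043-0.087 Hz
fc
#> StaticFC (scale 4): 82 regions, off-diagonal synchrony 0.841 [0.600, 0.989]

thr <- costEfficiencyThreshold(fc)
thr
#> ThresholdSpec (per_subject): weight cutoff 0.8793, cost 0.260, E_glob 0.533, C-E 0.273

str4 <- nodeStrength(applyThreshold(fc, thr))
sort(rank(-str4)[spec$hubIds])        # planted hubs recovered at the top
#> [1] 1 2 3 4

pet <- synthPetVectors(rowSums(spec$couplingMatrix),
                       rhoHub = 0.6, rhoBetween = 0.63, seed = 8)
Y <- sapply(1:11, function(s) {
  f <- staticFC(mp, scaleIndex = s)
  nodeStrength(applyThreshold(f, costEfficiencyThreshold(f)))
})
rmGlm(Y, list(pet$rcps, pet$suv), metric = "node_strength", posthoc = TRUE)
#> AssociationResult for 'node_strength' (covariates: rCPS + SUV)
#>  Mauchly W = 0.0001 (p = 1.59e-115), GG epsilon = 0.2092
#>          effect    beta        F df1 df2          p df1GG df2GG       pGG
#>     rCPS (main)  1.6138  10.4579   1  79  1.784e-03    NA    NA        NA
#>      SUV (main) -0.1603   0.1032   1  79  7.488e-01    NA    NA        NA
#>  scale (within)      NA 187.9933  10 790 3.196e-201 2.092 165.2 2.482e-44
#>    rCPS x scale      NA   5.3443  10 790  1.154e-07 2.092 165.2 4.989e-03
#>     SUV x scale      NA   0.6860  10 790  7.382e-01 2.092 165.2 5.113e-01
#>  post-hoc: 11 per-scale correlations (1 significant after Bonferroni)
```

Reading the output: planted hubs dominate the static strength ranking;
in the combined model the protein-synthesis covariate retains a clear
main effect on node strength (F(1, 79) = 10.46, p = 0.0018, positive
coefficient) while the glucose-uptake covariate — generated here only as
a correlate of rCPS (r ≈ 0.63) with no hub linkage of its own — shows
none. Strong non-sphericity across the 11 scales (Mauchly W ≈ 1e-4) is
handled by the Greenhouse-Geisser-corrected degrees of freedom in the
interaction rows.

Whole runs (all scales, static + dynamic metrics, CV tables, association
models, TSV/JSON artifacts) go through `runPipeline(pipelineConfig(...))`;
a command-line wrapper is installed at
`inst/scripts/run_pipeline.R` (`--bold`, `--atlas`, `--pet-rcps`,
`--pet-suv`, `--scales`, `--seed`, `--out`, ...).

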