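# tectalamina

Laminar segregation analysis of evoked field potentials in the developing
optic tectum.

## The problem

In the tadpole optic tectum, retinal ganglion cell (RGC) axons innervate
the distal lamina of the neuropil and hindbrain-relayed mechanosensory (HB)
axons the proximal lamina, both synapsing onto the same tectal dendrites.
How segregated the two inputs are — and how that segregation changes after
removing one input or blocking NMDA receptors — is measured by recording
evoked extracellular field potentials (FPs) every 10 µm along the
distal–proximal laminar axis and asking *where* the monosynaptic response
lives. This package is for electrophysiologists running that analysis: it
takes time × laminar-position trace matrices (real CSVs or simulated) and
produces normalized spatial profiles, current-source-density maps, sink
locations, overlap indices, fluorescence line-profile metrics, and the
group statistics.

## The core quantities

For each position x (distance from the distal edge), the response amplitude
is the peak deflection from the pre-stimulus baseline within the 4-ms
monosynaptic window; per tectum, amplitudes are normalized so the largest
is 1.0. The current-source density is the discrete second spatial
derivative on a differentiation grid of n·Δx (default 20 µm, with
Δx = 10 µm, n = 2):

    CSD(x, t) = [ V(x + nΔx, t) + V(x − nΔx, t) − 2 V(x, t) ] / (nΔx)²

The major sink is the largest sink-polarity extremum in the chosen time
window. Spatial overlap between the two inputs is Σₓ min(a(x), b(x)) over
normalized profiles; for fluorescence line profiles the analogous overlap
area is Σₓ min(a, b)·Δx. Two-group comparisons are routed by Shapiro–Wilk
normality: unpaired two-tailed t-test when both groups pass, two-sided
Mann–Whitney otherwise.

Because the study this mirrors released no raw recordings, the package
ships a forward model (`simulateRecording()`, `simulateCohort()`): a
compact laminar potential well with an alpha-function time course plus a
co-localized recurrent component, whose second difference is by
construction a sink flanked by balancing sources — so localization and
balance can be validated against known ground truth.

## Worked example

```r
library(tectalamina)

rec <- simulateRecording(conditionPreset("control", "HB", noise_sd = 0.05, seed = 7L))
rec
#> FPRecording: HB-evoked, tectum 'sim7' (control)
#>   500 samples x 16 positions (0-150 um, dx = 10 um), stim at 10 ms
#>   ground-truth sink at 100 um

peakLocation(buildSpatialProfile(rec))
#> [1] 100

csd <- computeCSD(rec)          # 20-um differentiation grid
locateMajorSink(csd)
#> primary sink at 100 um from the distal edge, t = 12.4 ms (|CSD| = 0.00513)
locateMajorSink(csd, "recurrent")
#> secondary sink at 100 um from the distal edge, t = 14.1 ms (|CSD| = 0.00354)

coh <- simulateCohort("control", n_tecta = 10, modalities = "HB", seed = 1L)
peaks <- vapply(coh, function(r) peakLocation(buildSpatialProfile(r)), numeric(1))
summarizeGroup(peaks, label = "control HB FP peak (um)")
#> control HB FP peak (um): mean 103 +/- 3.35 (SEM), n = 10; 95% CI [96.43, 109.6] (normal_z)
```

The HB-evoked sink is recovered at its proximal ground-truth position
(100 µm from the distal edge), the recurrent (secondary) sink co-localizes
with the primary one, and a 10-tectum cohort with 15-µm between-tectum
jitter summarizes to a group mean near the programmed centre.

`runStudy(studyConfig(...))` chains the whole pipeline — simulate or load
cohorts, profile, CSD, fluorescence, statistics — and writes CSV tables,
figures, and a `report.json` holding every number the figures display. A
thin CLI over these functions lives at `inst/scripts/tectalamina-cli.R`
(subcommands `simulate`, `profile`, `csd`, `fluor`, `report`, `all`).

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end study from scratch
(simulated control and DCR cohorts, both modalities, full statistics and
report) and writes its result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
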