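# m6Astoich

Quantitative analysis of RNA-modification stoichiometry, for
epitranscriptomics researchers asking whether a perturbation (knockdown,
inhibitor, knockout) actually changes methylation levels — or whether an
apparent change is within measurement noise.

The core of the package is a calibrated-comparison workflow for direct RNA
nanopore m6A data:

1. **Confidence-filtered pileup.** Per-read modification probabilities are
   classified with a dual threshold τ (default 0.99): modified when
   `p ≥ τ`, canonical when `1 − p ≥ τ`, discarded otherwise. Site
   stoichiometry is `f = n_mod / (n_mod + n_canon)` over the calls that
   pass. Tables are bedMethyl-compatible; sites can be restricted to the
   DRACH motif context.
2. **Coverage calibration.** Two same-condition replicates are paired per
   site across a grid of minimum-coverage thresholds; precision is
   summarised by Bland–Altman **limits of agreement**
   (mean difference ± 1.96 × SD of differences).
3. **Empirical null band.** The control-vs-control limits of agreement
   define the range of per-site Δf explainable by noise. In a
   condition-vs-control comparison, a site is *increased*/*decreased* only
   when its Δf strictly exceeds the band.

Two companion modules cover the flanking analyses: CROWN-seq-style m6Am
quantification at snRNA transcription-start nucleotides (non-conversion
rate `r = n_A / (n_A + n_G)`, per-snRNA paired t-test across conditions)
and DepMap-style dependency counting (probability > 0.5 rule, lineage
subsets) plus MTT viability. A synthetic-data generator reproduces the
statistical structure of all inputs, so the whole pipeline runs and is
tested without any external download.

## Worked example

Simulate two control replicates and a knockdown that raises stoichiometry
by +0.25 at 150 of 3,000 sites, derive the null band from the controls,
and classify the knockdown against it:

```r
library(m6Astoich)

truth <- simulateSiteTruth(3000, seed = 1)
sim <- function(tr, s, lab) pileupCalls(
  simulateNanoporeCalls(truth = tr, cov_mean = 300, seed = s)$calls,
  sample = lab)
ctrl1 <- sim(truth, 2, "ctrl1")
ctrl2 <- sim(truth, 3, "ctrl2")
ctrl1
#> ModSiteTable 'ctrl1' (ctrl1): 3000 sites, tau = 0.99
#>   valid coverage: median 277 [65, 754]; stoichiometry: mean 0.224

band <- nullBand(blandAltman(joinPairedSites(ctrl1, ctrl2,
                                             min_valid_cov = 50)))
band
#> NullBand (estimated): [-0.0606, 0.0609]

kd <- injectEffect(truth, delta = 0.25, sites = 1:150)
treat <- sim(kd$truth, 4, "shKD")
report <- compareConditions(ctrl1, treat, min_valid_cov = 50,
                            null_band = band)
report
#> ComparisonReport
#> FitResult: r = 0.9621 (p = 0), f_B = 0.9842 * f_A + 0.01796, n = 2730
#> Bland-Altman: mean diff = 0.01408, SD = 0.06547, 95% LoA [-0.1142, 0.1424], 94.4% within, n = 2730
#>   labels: increased=236, decreased=107, unchanged=2387
```

Reading the output: replicate noise alone spans ±0.06 at this depth, so
only Δf beyond that is called. 149 of the 150 injected sites are labelled
`increased`; the remaining flags are the few percent of null sites
expected outside a 95% band. A self-comparison (`compareConditions(ctrl1,
ctrl1, ...)`) gives r = 1 and every site `unchanged` — the hallmark of a
perturbation with no effect is that its comparison looks like a replicate
comparison.

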