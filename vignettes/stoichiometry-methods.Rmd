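---
title: "Measuring and comparing RNA modification stoichiometry: models and methods"
author: "m6Astoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing RNA modification stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Astoich)
```

# The measurement model

Direct RNA nanopore sequencing assigns each read, at each candidate
adenosine, a probability `p` that the base is N6-methyladenosine (m6A).
The package's central quantity is **site stoichiometry**: the fraction of
transcript copies methylated at one genomic position. It is estimated by a
confidence-filtered pileup:

* a read's call is **modified** when `p >= tau`, **canonical** when
  `1 - p >= tau`, and discarded otherwise. The dual threshold `tau = 0.99`
  is applied symmetrically to both classes; only calls passing the filter
  ("valid coverage") enter the estimate;
* stoichiometry at a site is `f = n_mod / (n_mod + n_canon)`.

`tau` must exceed 0.5 or the two confident classes would overlap. The
threshold comparison is inclusive (`p` exactly at `tau` passes), and the
denominator excludes filtered calls; counting discarded calls in the
denominator would shrink every estimate toward zero by a factor that
depends on the basecaller's local confidence, not on biology. The
all-reads denominator is available by combining `failCounts()` with the
accessors, but is deliberately not the default.

Replicates are merged by summing per-site counts (`mergeSiteTables()`),
mirroring the merging of replicate alignments before pileup; stoichiometry
is always recomputed from summed counts, never averaged across replicate
ratios, so deeply covered replicates carry proportionally more weight.

Candidate sites can be restricted to the canonical m6A sequence context
with `motifMask()` (IUPAC `DRACH`, strand-aware, reverse-complemented for
minus-strand sites). Coordinates follow the bedMethyl convention: 0-based
half-open on disk, single-base records, explicit strand.

# Coverage calibration and the empirical null

With `n` valid reads, the estimator `f_hat` is binomial:
`Var(f_hat) = f(1 - f)/n`. The difference between two independent
replicate measurements of the same site therefore has standard deviation
`sqrt(2 f (1 - f) / n)`; read depth is the single most important noise
control. The package quantifies this directly from data rather than from
the formula:

1. `joinPairedSites()` pairs sites measured in two same-condition
   samples (inner join, both coverages at or above the floor). Pairs at
   zero in both samples are dropped by default -- they are uninformative
   about agreement and would concentrate at the origin.
2. `blandAltman()` summarises the paired differences by their mean and
   95% **limits of agreement**, `mean +/- 1.96 * SD` (sample SD, `n - 1`
   denominator, the standard Bland-Altman convention).
3. `sweepCoverageThresholds()` repeats this across a grid of coverage
   floors (default 0--200 in steps of 10, plus the conventional working
   points 25 and 50), reporting retained sites, squared Pearson
   correlation (R^2 as the coefficient of determination) and the limits.

The limits of agreement of a control-vs-control comparison are then the
**empirical null band**: the range of per-site stoichiometry differences
explainable by measurement noise alone. `suggestCoverageThreshold()`
flags the smallest floor whose band half-width is within 10% of its
value at the deepest threshold; the choice is surfaced for the analyst to
confirm rather than automated, because the precision/retention trade-off
depends on the biological question (a 50-read floor is the conventional
working point).

# Differential classification

`compareConditions()` composes the join, the Pearson/least-squares
concordance fit (closed forms, two-sided p from the t distribution on
`n - 2` df), the Bland-Altman summary and the difference-distribution
summary, and labels each site against a supplied `NullBand`:
**increased** when `delta` strictly exceeds the band's upper limit,
**decreased** when strictly below the lower limit, otherwise
**unchanged**. Strict inequality implements "beyond baseline
variability"; a difference exactly on the limit is not evidence of
change. The band is used as-is, including any offset of its mean
difference from zero -- recentring it would silently remove a real
between-run bias from the null, so an off-centre band is better surfaced
than hidden.

Classification here is deliberately descriptive (a noise band, not a
per-site hypothesis test with multiplicity correction): the question it
answers is whether any site moves beyond reproducibility, not the exact
false-discovery rate of a hit list.

Two special modes warn loudly: a coverage floor below 50 (the relaxed
10-read mode used to rescue sparse genes) and a `"borrowed"` null band
(when a condition has a single replicate and no own control-vs-control
null exists). Log2 fold changes are undefined when either stoichiometry
is zero; the default policy drops such pairs from the log2FC summary and
reports the count, since any pseudocount choice (available via
`pseudocount`, e.g. 0.01) changes the tail of the distribution.
`crossMethodCompare()` applies a shared stoichiometry floor (default
0.05) to both methods before comparison, because chemical reference
datasets typically omit sites below that level and an asymmetric filter
would bias the fit.

# m6Am at transcription-start nucleotides

For N6,2'-O-dimethyladenosine (m6Am) at snRNA transcription-start
nucleotides, quantification follows conversion-chemistry logic: after
chemical conversion, unmethylated 2'-O-methyladenosine reads as G while
m6Am stays A. Reads are converted in silico before alignment
(`convertReadsInSilico()`: read 1 A-to-G, read 2 T-to-C), and
`tssNonconversion()` counts bases at annotated TSS positions over
qualifying reads -- read 1 only, no 5' soft-clip, mapped 5' end exactly
at the annotated nucleotide. The **non-conversion rate**
`r = n_A / (n_A + n_G)` estimates m6Am stoichiometry; bases other than
A/G are tallied but excluded from the denominator, as they reflect
sequencing error rather than conversion state. TSSs under 50 informative
reads are excluded.

With conversion efficiency `c < 1`, `E[r] = f + (1 - f)(1 - c)`;
`correctForConversion()` inverts this (clamped to [0, 1]) but is off by
default -- the quantification workflow reports raw rates, and the
correction is an explicit, optional step because `c` must be estimated
externally. Condition comparisons (`perSnrnaConditionStats()`) average
replicate rates within condition per snRNA, then run a paired t-test
across snRNAs on the per-snRNA differences (`n - 1` df, two-sided); a
zero-variance difference vector returns `NA` with a warning instead of an
infinite statistic. Each annotated `gene_id` is treated as one pairing
unit; collapsing multicopy snRNA families further is left to the
annotation, since family membership is an annotation property, not a
property of the counts.

# Dependency counting and viability

DepMap-layout matrices (first column cell-line id, one gene per column,
headers `"SYMBOL (ENTREZID)"`) are parsed by gene-symbol prefix with an
exact-match fallback. A line is dependent when its dependency probability
is **strictly greater than 0.5**; lines with a missing value are excluded
from numerator and denominator alike, which is why per-gene denominators
differ within one release. Lineage subsets (e.g. AML lines) are explicit
identifier lists from a lineage map file rather than hard-coded names,
because lineage annotations change between releases. MTT viability is
`100 * mean(treated) / mean(control)` per timepoint, scale-invariant in
the absorbances.

# The synthetic-data generator

Every stage is testable without downloads because the generator emulates
the statistical structure the analysis assumes:

* **truth**: per-site stoichiometry from `pi0 = 0.3` point mass at zero
  plus `Beta(1.2, 2.5)` -- a low-skewed, long-right-tailed distribution
  qualitatively matching observed m6A stoichiometries; no attempt is made
  to fit a real distribution;
* **coverage**: negative binomial, default mean 100 and size 10;
* **basecaller**: a read yields a confident call with probability
  `q = 0.95`, wrong with probability `eps = 0.002`; emitted probabilities
  are uniform within the band the classifier maps them to (above `tau`,
  below `1 - tau`, or between). Downstream logic depends only on the
  band, so uniform draws keep the model minimal and analytic;
* **conversion counts**: `n_A ~ Binomial(cov, f + (1 - f)(1 - c))` with
  base-error leakage into other bases; default conversion efficiency
  0.99, coverage 1000, 3 replicates, and 28 snRNA-like TSSs with low
  baseline stoichiometries `Beta(1.5, 10)`;
* **dependency matrices**: designated dependent lines at probability
  `U(0.8, 1)` and effect `N(-1, 0.1)`; others `U(0, 0.3)` and `N(0, 0.1)`.

All draws come from one `set.seed(seed)` stream in a fixed, documented
site-major order, so outputs are reproducible bit-for-bit given the seed.

What the generator does **not** model -- and hence what green tests do
not certify about real data: sequence-context-dependent basecaller error,
alignment and demultiplexing artifacts, isoform-overlapping sites,
transcript-abundance shifts between conditions, poly(A)/read-length
effects, and UMI or PCR duplication structure. Conclusions about real
perturbations still require the replicate-derived null from the actual
experiment.

# Problem sizes and numerical choices in the shipped checks

The test-suite and acceptance-script experiments use 2,000--5,000
synthetic sites, coverage means 80--300, 10 repetitions for
median-based monotonicity checks, and 28 snRNAs at coverage 1,000--10,000
-- sizes at which binomial expectations hold to a few percent while a
full run stays comfortably interactive. For the threshold-sweep
experiment specifically, coverage is drawn with dispersion size 1.2
(heavier-tailed than the generator default of 10) so that a 0--200 sweep
grid is populated at its deep end, as it is in real transcriptome data
where coverage spans orders of magnitude.

Other numerical conventions: thresholds and coverage floors are
inclusive; band exceedance is strict; ECDFs are right-continuous step
functions; a sweep row with fewer than 3 pairs reports `NA` statistics
with a warning rather than a fabricated fit; duplicate reads at a site
are an error, not silently deduplicated, because they indicate an
upstream demultiplexing fault.

# Known limitations

* Stoichiometry is per genomic site, aggregated over isoforms.
* The classifier is a noise band, not a calibrated per-site test; with
  thousands of sites, a few percent of null sites will always lie outside
  the band.
* Between-site differences in true variance make the pooled
  Bland-Altman band slightly anti-conservative for high-variance
  (mid-stoichiometry, low-coverage) sites and conservative for
  low-variance ones; the per-site difference distribution is a scale
  mixture, so slightly more than 5% of null sites can fall outside
  `mean +/- 1.96 * SD`.
* Conversion-efficiency correction assumes a single scalar efficiency
  shared across TSSs.
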