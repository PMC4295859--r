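# doseTrend

Dose–time trend screening for chemotherapy-induced gene-expression
changes in endothelial cells, with the downstream candidate-selection,
enrichment, qRT-PCR and plasma-biomarker statistics that turn a screen
into validated biomarker candidates.

## Who this is for

Bleomycin- and cisplatin-based chemotherapy damages the vascular
endothelium, and plasma biomarkers of that damage (such as GDF-15, vWF
and hsCRP) can be nominated from the transcriptional response of
cultured endothelial cells exposed to an ordered dose ladder. This
package implements that analysis end to end for anyone running or
re-analyzing such screens: microarray-style preprocessing, the trend
statistics, multi-setting candidate selection, gene-set enrichment with
a permutation null, qRT-PCR relative quantification, and longitudinal
plasma statistics — plus synthetic-data generators so the whole pipeline
is testable without any external download.

## The statistic at the core

For one gene at one time point, with ordered group scores `l_j` (dose
rank 1/2/3 for control/IC50/IC90) and midranks `r_j` of the pooled
expression values (N samples), the Cuzick trend statistic is

    T = Σ l_j r_j
    E[T] = (N+1)/2 · Σ l_j
    Var[T] = (N+1)/12 · (N Σ l_j² − (Σ l_j)²) · tie-correction
    Z = (T − E[T]) / √Var[T]

The acute screen sums the standardized scores over the sampling times,

    ΣZ = Z(6 h) + Z(24 h) + Z(48 h),

so only genes trending in a consistent direction with increasing dose
at every time point rank high; under the null ΣZ has mean 0 and
variance 3. Genes are ranked by ΣZ (acute) or by two-sample t-test
p-value (chronic, IC10 vs control at day 30); each setting's
dual-direction top-50 list feeds an overlap selection in which genes
present in ≥ 3 of 4 exposure settings become candidates. Gene-set
enrichment uses the running-sum enrichment score with a gene-label
permutation null and the NES-ratio FDR, reported at FDR ≤ 0.10 and
p ≤ 0.025.

## Worked example

Candidate selection on the bundled published top-50 lists (the four
exposure settings of the HMEC-1 bleomycin/cisplatin screens, GEO series
GSE62523):

```r
library(doseTrend)
settings <- c("bleomycin_acute", "bleomycin_chronic",
              "cisplatin_acute", "cisplatin_chronic")
paths <- vapply(settings, function(s)
  doseTrendData(paste0("top50_", s, ".tsv")), character(1))
lists <- readGeneLists(paths, settings = settings)
report <- overlapSelect(lists, m = 3)
report
#> OverlapReport: 173 genes across 4 lists; m = 3
#>   candidates (count >= 3): AREG, ATF3, GDF-15
```

The three genes found in at least three of the four settings are AREG,
ATF3 and GDF-15 — the screen's validated candidates. Their directions
differ between acute and chronic exposure (they rise acutely and fall
chronically), which `directionConcordance(report, lists)` makes
explicit.

The trend statistic itself, on six expression values over the dose
ladder (two samples per dose):

```r
cuzickTest(c(7.1, 7.4, 8.2, 8.0, 9.1, 9.3), c(1, 1, 2, 2, 3, 3))
#>  Cuzick test for linear trend (normal p)
#> data:  c(7.1, 7.4, 8.2, 8, 9.1, 9.3)
#> T = 50, p-value = 0.03251
```

Here T = 50 against an expectation of 42 gives Z = 8/√14 ≈ 2.14, the
largest score attainable at this replication; over three time points a
perfectly consistent gene reaches ΣZ ≈ 6.41 (`maxSigmaZ(2)`).

A full simulated screen — spiked trend genes, hybridization averaging,
per-time-point trend tests, ΣZ ranking:

```r
sim <- simulateAcute(acuteDesign(n_genes = 500, n_trend_genes = 25,
                                 seed = 7))
tr <- acuteSigmaZ(averageHybridizations(sim$experiment))
head(trendTable(tr)[order(trendTable(tr)$rank), ], 3)
#>       gene    Z_t6   Z_t24   Z_t48 sigma_Z direction
#> 90  G00090 2.13809 2.13809 2.13809 6.41427        up
#> 103 G00103 2.13809 2.13809 2.13809 6.41427        up
#> 134 G00134 2.13809 2.13809 2.13809 6.41427        up
```

All 25 spiked genes land in the correct-direction half of the top-50
list at the default effect size. `runPipeline(runConfig(seed))` chains
simulation, trend ranking, overlap selection and enrichment into one
deterministic run with a JSON manifest.

## Scope notes

Published per-gene ΣZ values, per-set FDR values and patient-level
statistics are not reproducible from code alone — they depend on the
deposited raw arrays, a 2009-era pathway catalog, the original GSEA
software internals and non-public clinical data. The package instead
guarantees the statistical machinery: oracle-exact small-sample tests,
null calibration, and signal recovery on generators that emulate the
study designs. See the methods vignette
(`vignettes/dose-trend-screening.Rmd`) for the full account.
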