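# epiTurnover

Non-invasive measurement of epidermal protein turnover from oral
heavy-water (²H₂O) labeling and serial tape stripping, with application to
psoriasis: lesional plaque keratin surfaces within days and is almost
entirely newly synthesized, while uninvolved skin turns over on a two- to
three-week timescale. The package takes a dosing schedule (or measured
saliva enrichments) and per-site tape-strip mass-isotopomer measurements
and returns, per skin site, the label appearance lag and replacement rate,
plus the accompanying spectral-count proteomics summary and transepidermal
water loss (TEWL) contrasts.

## The model

Deuterium from body water is incorporated into the C–H positions of
alanine during protein synthesis. The readout on derivatized, protein-bound
alanine is **EM1** — the molar fraction of molecules one mass unit above
monoisotopic, in excess of natural abundance. Fractional synthesis of the
protein pool sampled at day *t* is the precursor–product ratio

```
f(t) = EM1(t) / EM1max(p̄(t))
```

where p̄(t) is the time-averaged body-water enrichment up to *t* (from a
one-compartment simulation of the dosing protocol, or interpolated saliva
measurements, which take precedence) and EM1max is the EM1 of a
hypothetically 100%-newly-synthesized population at that enrichment,
computed from a binomial labeling model over 4 alanine C–H sites convolved
with natural isotope abundances. The model is calibrated so that
EM1max(p)/p → 2.7 at low enrichment, the empirical body-water-to-alanine
amplification. The stratum corneum is treated as a conveyor: per site,

```
f(t) = 0                   for t ≤ τ        (basal-to-surface transit lag)
f(t) = 1 − exp(−k (t − τ)) for t > τ        (surface replacement rate k)
```

and (τ, k) are estimated by least squares (τ grid search, 0.25-day step,
with bounded 1-D minimization over k and a seeded bootstrap for percentile
CIs). Spectral-count tables are summarized by the abundance index
(total peptide count / molecular weight × 10³) and the keratin-derived
fraction of counts; TEWL duplicate readings are summarized descriptively
with per-subject lesional-minus-non-lesional contrasts.

## Worked example

```r
library(epiTurnover)

amplification(defaultLabelingModel())
#> [1] 2.700001
em1Max(0.01)         # plateau EM1 at 1% body-water enrichment
#> [1] 0.02626892

# a synthetic four-subject cohort with the study's design, then the full
# analysis: curves -> fractional synthesis -> per-site conveyor fits
bundle <- simulateCohort(nSubjects = 4, seed = 7)
res <- analyzeCohort(bundle, config = fitConfig(nBoot = 0))
res$fitTable[1:4, c("site_id", "lesional", "tau", "k", "flags")]
#>      site_id lesional   tau         k flags
#> 1   S01_les1     TRUE  4.25 0.5453356
#> 2   S01_les2     TRUE  6.00 6.6510596
#> 3 S01_uninv1    FALSE 17.00 0.1340396
#> 4 S01_uninv2    FALSE 18.75 0.1548856
res$comparison$groups
#>   lesional n tauMedian tauMin tauMax   kMedian      kMin       kMax
#> 1    FALSE 8     15.75  12.75  18.75 0.1582622 0.1340396  0.2019379
#> 2     TRUE 8      5.75   3.00   7.75 2.0863104 0.5421554 10.1776260
```

Lesional lags (median 5.75 d here) sit well below uninvolved lags (median
15.75 d), and lesional replacement rates are an order of magnitude faster
— the kinetic signature of active plaque. `flags` marks sites where the
design limits identifiability (no observed rise, saturated rise, or a
single point on the rise).

The packaged single-patient spectral-count tables reproduce the published
summaries:

```r
tab <- readSpectralCounts(system.file("extdata", "tapestrip_uninvolved_counts.tsv",
                                      package = "epiTurnover"), "uninvolved")
keratinFraction(tab)[c("keratinCounts", "totalCounts", "percentRounded")]
#> $keratinCounts [1] 342   $totalCounts [1] 349   $percentRounded [1] 98
head(scRecords(rankByAbundance(tab))[, c("proteinName", "abundanceIndex")], 3)
#>   proteinName abundanceIndex
#> 1  Keratin 10           1.55
#> 2   Keratin 1           1.44
#> 3   Keratin 2           1.01
```

98% of uninvolved-skin spectral counts derive from keratins, and Keratin
10 heads the abundance ranking at index 1.55 (91 counts / 58,827 Da ×
10³).

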