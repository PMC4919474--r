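# ldscreen

Analysis of quantitative high-throughput (qHTS) phenotypic screens for
cellular lipid storage, and the downstream stages such a campaign feeds.

## The problem

In a qHTS lipid-storage screen, every compound in a large library is
tested as a multi-point titration against a cell line loaded with free
fatty acid, reading out lipid-droplet (LD) signal *per cell* alongside a
cell-number counter-screen. Hits are then called not from single points
but from fitted dose–response curves, graded by *curve class* — complete
sigmoid (CC 1), partial sigmoid missing the saturating asymptote (CC 2),
single-concentration activity (CC 3), inactive (CC 4) — and triaged by
efficacy, potency, cytotoxicity and the presence of structurally similar
active compounds. Follow-up stages characterize the surviving chemotypes:
RNA-Seq signature clustering, cross-species activity concordance over
derivative panels, whole-animal triglyceride statistics with a
pharmacogenetic epistasis rule (does the drug still act in a mutant of
the suspected target pathway?), and direct enzyme-inhibition IC50s.

`ldscreen` implements this full chain for analysts of such screens, with
seeded synthetic-data generators carrying ground truth so every stage is
testable end to end without any external downloads.

## The core model

Percent activity is normalized per plate against control medians,

    a = 100 (x − m_neutral) / (m_neutral − m_positive),

(0 = untreated, −100 = positive-control inhibition), and each compound's
titration a(c) is fit with the four-parameter logistic

    f(c) = top + (bottom − top) / (1 + (EC50 / c)^h),

by bounded Levenberg–Marquardt with deterministic grid initialization.
Curve classes are assigned from fit acceptance (r², flat-model F test,
multi-point activity), realized efficacy, and asymptote realization;
quality tiers add the cytotoxicity and structural-series filters. The
statistics downstream are the field's standard ones: Spearman replicate
QC, Welch t DE calls, Z-score k-means signatures, Wilcoxon signed-rank
burden comparison, hypergeometric set enrichment with BH adjustment,
one-way ANOVA with Bonferroni post-hoc tests.

## Worked example

```r
library(ldscreen)

# a 200-compound synthetic screen: 7-point titrations (46 uM -> ~3 nM,
# 1:5), controls on every plate, 10%-of-span noise, 5% cytotoxic
sim <- simulate_screen(n = 200, noise_frac = 0.1, toxic_frac = 0.05,
                       seed = 7)
res <- run_screen_pipeline(sim$wells, sim$fingerprints)
res$summary
#> qHTS screen summary: 200 compounds
#>   high-quality inhibitors: 39
#>   high-quality activators: 11
#>   low-quality inhibitors:  43
#>   low-quality activators:  12
#>   inactive:                95
```

The totals partition the 200 compounds: high quality means a
non-cytotoxic complete curve (or a supported partial curve with efficacy
≥ 50), low quality the remaining actives, inactive the CC 4 calls.
Per-compound calls, fit parameters and the thresholds used are written by
`write_reports(res, "out/")`.

A single titration, generated at a 90 nM EC50 and refit:

```r
ts <- simulate_titration(top = 0, bottom = -100, ec50 = 90e-9, slope = 1,
                         noise_sd = 0)
fit_hill(ts)
#> Hill fit: EC50 = 90 nM, slope = 1, top = -1.08e-07, bottom = -100
#>   r2 = 1.0000, p(flat) = 0, n = 7

fit_ic50(simulate_enzyme_assay(ic50 = 27e-9, noise_frac = 0))$ic50 * 1e9
#> [1] 27
```

The `analysis/` directory holds the narrative workflow — `01` simulates
the screen, `02` classifies and scores it against truth, `03` runs the
expression stages (cutoff 1.04, replicate QC, DE, signature clusters,
enrichment), `04` the epistasis calls and the enzyme IC50 — writing its
tables under `results/`.

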