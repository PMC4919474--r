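---
title: "Methods: quantitative HTS analysis of lipid-storage screens"
author: "ldscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative HTS analysis of lipid-storage screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ldscreen` implements the computational chain of a quantitative
high-throughput (qHTS) phenotypic screen for inhibitors of cellular lipid
storage, together with the downstream stages such a campaign feeds:
transcriptomic signature analysis, cross-species structure–activity
concordance, whole-animal triglyceride (TAG) statistics with a
pharmacogenetic epistasis rule, and enzyme-inhibition IC50 estimation.
This vignette is the package's account of the models, the tunable
parameters, the numerical choices, and the limits of what its synthetic
data can show.

## The screen model

Each well reports two raw signals: a lipid-droplet (LD) fluorescence
channel and a cell-number channel. The phenotypic readout is LD signal
per cell, `ld_signal / cell_signal`; wells without measurable cell signal
are unevaluable and propagate as missing points rather than errors.
Per plate, the solvent (DMSO) wells define the neutral level and a
full-inhibition reference compound defines the positive level; medians are
used (robust to outlier wells; the MAD is retained for QC). Percent
activity is the affine normalization

$$a = 100\,\frac{x - m_\mathrm{neutral}}{m_\mathrm{neutral} - m_\mathrm{positive}},$$

so 0 is the untreated level and −100 the positive-control level.
Inhibition is negative, activation positive; direction is inferred
downstream from the sign, so the convention is internal. The cell channel
is normalized as percent change from the plate's neutral cell-signal
median — equivalently the same affine formula with "no cells" as the
reference level — so that a cytotoxicity cutoff of −50 means half the
cells are gone.

Titrations follow a geometric dilution design, by default 46 µM down in
1:5 steps over 7 points (floor ≈ 2.9 nM ≈ "3 nM"). The point count is a
configurable parameter: descriptions of such campaigns sometimes count six
concentrations, but a 46 µM → 3 nM range at 1:5 implies seven, which is
the default here. Replicate wells at the same (compound, concentration)
collapse to their median.

## Dose–response fitting

Responses are fit with the four-parameter logistic (Hill) model

$$f(c) = \mathrm{top} + \frac{\mathrm{bottom} - \mathrm{top}}
{1 + (\mathrm{EC}_{50}/c)^{h}},$$

by least squares in log10-concentration space, optimizing
(top, bottom, log10 EC50, log h) so the slope stays positive. Bounds:
asymptotes within ±200 percent, log10 EC50 within two decades of the
tested range, slope in [0.1, 5]. The slope cap matters: an unbounded
slope lets a "sigmoid" reproduce a single-concentration step exactly,
which would defeat the curve-class taxonomy below; 5 is at the upper end
of slopes seen in well-behaved pharmacology.

Initialization is deterministic — a coarse grid over candidate EC50s
(25 log-spaced values spanning the bounds) and slopes (0.5, 1, 2), with
the two asymptotes solved in closed form at each grid point (the model is
linear in them given the occupancy weights), then bounded
Levenberg–Marquardt refinement. There are no random restarts; fits are
exactly reproducible. Optimizer failure is recorded (`converged = FALSE`),
never raised. EC50s outside the tested range are reported with an
`extrapolated` flag rather than clipped — sub-nanomolar potencies below a
3 nM floor are real and recoverable from the curvature of the top points,
but should be read with that flag in mind.

Concentration dependence is tested with the extra-sum-of-squares F test
against a flat (mean-only) model, F(3, n−4). For a bounded nonlinear
alternative this test is *conservative* under the null (measured rejection
at nominal 0.05 is about 0.01), which is the safe direction for an
acceptance gate: it never inflates the count of concentration-dependent
calls. Degenerate inputs follow conventions: zero residual variance under
both models gives p = 1.

One outlier point may be masked: the point whose residual exceeds
`z_max = 3` robust standard deviations (MAD scale with a 0.5-percent
absolute floor) is removed and the curve refit. A robust scale is
necessary — with seven points the ordinary RSS-based standardized residual
is bounded by √3 and could never reach 3 — and the absolute floor keeps
machine-precision residuals on noiseless curves from being flagged.

## Curve classes and triage

The qHTS taxonomy grades concentration–response quality: class 1 is a
complete sigmoid with both asymptotes realized in range, class 2 a partial
sigmoid missing the saturating asymptote, class 3 activity at only the
highest concentration, class 4 inactive. Subclasses .1/.2 split full from
partial efficacy. Efficacy here is the *realized* span — the fitted
response difference between the lowest and highest tested concentration —
not the asymptotic span, which for partial curves is extrapolation.

A fit is *accepted* when it converged, r² ≥ `r2_min` (default 0.9), the
flat-model F test gives p < 0.05, and the fitted curve shows a response of
at least `plateau_tol` (default 10) at `min_active_points` (default 2)
tested concentrations. The last guard is this package's declared
reconstruction of how single-point activity is separated from a genuine
partial curve: fit quality alone cannot do it, because a steep bounded
sigmoid reproduces a flat series with one active endpoint almost
perfectly (r² ≈ 0.999). Accepted fits with efficacy ≥ `eff_high`
(default 80) are class x.1, in [`eff_low`, `eff_high`) class x.2, with
the 1-vs-2 split by whether both asymptotes are realized within
`plateau_tol`. Unaccepted series with |activity| ≥ `eff_low` at the top
concentration are class 3; everything else class 4.

All numeric thresholds are declared package defaults, not published
values — the source campaigns cite the qHTS strategy without printing
cutoffs — and they are echoed into every report header.

Triage: high quality requires a non-cytotoxic compound with a complete
response (1.1, 2.1) or a partial response (1.2, 2.2) that reaches
`hq_partial_eff` (default 50) *and* is supported by a structural series
(≥ 2 compounds with fingerprint Tanimoto ≥ 0.7, single-linkage — triage
only asks for "at least one similar active", not tight clusters).
Cytotoxicity is flagged when the cell channel drops below `tox_cutoff`
(default −50) at any concentration within 25× the fitted EC50 (all
concentrations when the fit shows no concentration dependence, since a
flat fit's EC50 is meaningless).

## The synthetic screen and what it can show

`simulate_screen()` draws each compound's class from a mix that mirrors a
primary screen dominated by inactives (50% class 4, 15% class 3, 18%
class 2, 17% class 1) while keeping every class testable at n = 500.
Class-consistent parameters are drawn with deliberate margins from the
decision boundaries: complete curves have midpoints well inside the range
(slope 1.8–3, span 85–100 or 45–70), partial curves have midpoints near
the top tested concentration (0.65–1 × c_max, slope ≈ 1), chosen so the
saturating asymptote is unrealized by at least twice `plateau_tol` and at
least two concentrations respond above twice the activity floor, with
spans within the ±200 fit bounds. A 25% of actives are activators
(sign-flipped). Cytotoxic compounds (5% by default) lose up to 85% of
cells along a steep curve centered on their own midpoint. Noise is
Gaussian per well, either absolute (`noise_sd`, percent units) or scaled
to each compound's span (`noise_frac`).

Noiseless recovery of the generating class is essentially perfect (100%
at n = 500 in the bundled analysis). At 10%-of-span noise, recovery is
~84–86%, and this limit is structural rather than numerical: for a partial
curve of efficacy E ≈ 45–70, the expected residual sum is 3σ² against a
total sum of squares ≈ 0.83 E², giving an expected r² of 0.88–0.91 —
*at* the default acceptance bar of 0.9 — so roughly a third of true
class-2 curves fail the gate and read as class 3, and the weakly
identified extrapolated bottom occasionally flips the
both-asymptotes judgment (class 2 ↔ class 1). Any generating region that
satisfies the class-definition constraints lands in this regime; users
who care more about class-2 sensitivity than specificity should lower
`r2_min`, and reports always carry the thresholds used.

What the generator does not emulate: plate spatial artifacts (edge
effects, gradients), non-Gaussian or heteroscedastic well noise,
compound-concentration errors, or correlated assay drift. Passing tests
on this generator show the decision logic and estimators are correct
under their stated model, not that the thresholds are optimal for any
particular instrument.

## Expression stages

The expression threshold is the 95th percentile (linear interpolation,
R type 7 — percentile conventions differ, so the rule is declared) of all
intergenic values pooled across samples; genes never reaching it are
dropped. The bundled generator calibrates its lognormal intergenic
background so this percentile is exactly 1.04 FPKM, the working value of
the screen it emulates. Replicate QC computes pairwise Spearman
correlations on log(FPKM+1); replicates whose median within-condition
correlation falls below 0.95 are dropped worst-first until stable, and no
condition falls below its best two replicates.

Differential expression is a deliberate stand-in: Welch's t on
log2(FPKM+1) with the campaign's α = 0.001, pluggable so externally
computed DE results can replace it — the original chain used a dedicated
external DE engine, and re-implementing one is out of scope. At
triplicate scale the stand-in errs conservative for weakly expressed
genes (the pseudo-count compresses low-FPKM distributions), which we
verify as a type-I-error bound at the working n = 3; the KS-uniformity
calibration study is run at five replicates per condition, where the
pseudo-count effect is negligible and the test's null distribution is
cleanly uniform.

Signature clustering standardizes each DE gene's *condition means* to Z
scores (matching how such signatures are displayed, one column per
condition) and runs k-means with k = 5, 50 restarts under a fixed seed,
best inertia kept, labels canonicalized by decreasing cluster size.
Base R's k-means uses random initialization rather than k-means++; with
50 restarts on Z-scored profiles the practical difference is nil, and
determinism comes from the seed. Zero-variance genes are excluded with a
warning. The DE-burden comparison is a two-sided Wilcoxon signed-rank
test on paired per-gene |log2FC| vectors (the paired-units reading of the
active-vs-inactive burden comparison; all-zero differences give p = 1).
Set enrichment is the upper-tail hypergeometric test per gene set with
Benjamini–Hochberg adjustment across sets; gene sets are user-supplied id
lists (no ontology database is bundled — those are versioned external
resources).

## TAG statistics and the epistasis rule

Group comparisons use classical one-way ANOVA followed by pairwise t
tests with the pooled within-group mean square (a Welch option exists)
and Bonferroni adjustment, p_adj = min(1, m·p) — the cap convention, so a
reported "p = 1" is a capped value. Degenerate inputs follow explicit
conventions (all-identical data: p = 1; zero within-group variance with
distinct means: p = 0).

The epistasis decision for a four-group experiment (reference, drug-only,
mutant-only, combined): *independent* (separate pathways) when the
combination is lower than both single perturbations and both
Bonferroni-adjusted comparisons are significant at α = 0.05;
*same pathway* when neither comparison is significant ("no enhancement",
operationalized exactly as both adjusted p ≥ α); anything else is
*inconclusive*. The verdict is invariant to which perturbation is labeled
drug vs mutant. Percent-of-reference effect sizes are reported alongside
so wet-lab magnitudes can be compared descriptively; they do not enter
the verdict. The canonical synthetic scenarios use n = 8 replicate pools
and sd = 10% of each group mean, with the additive combination at the
product of the single-effect fractions.

## Enzyme assay

Percent inhibition of esterification counts is
`100·(1 − (c − bg)/(dmso − bg))` with the no-enzyme extract as background
and the solvent reference as 0; values may leave [0, 100] with noise.
IC50 fitting reuses the Hill machinery with the zero-inhibition asymptote
constrained near 0 (±5 by default, configurable) and the saturating
asymptote free; a realized span under 10 percent, or a non-converged fit,
is reported as "no inhibition" — the expected readout for an enzyme the
compound does not touch. Synthetic titrations use three replicate wells
per concentration, treated as independent.

## Problem sizes and determinism

The bundled analyses and tests run at desk scale: screens of 500
compounds on the 7-point grid, expression matrices of ~1000 genes × 24
samples, 500-seed epistasis ensembles, 200-replicate recovery studies.
All randomness flows through explicit seeds; every generator restores the
caller's RNG state, and the pipeline itself is deterministic, so reruns
on the same inputs are byte-identical.

## Known limitations

* No plate-effect correction (B-scores, spatial detrending): the source
  chain did not use them, and the generator does not produce the
  artifacts they fix.
* The class-2/class-3 boundary at the default r² gate is noise-limited,
  as quantified above.
* The DE stand-in is not a count-model engine; its role is to exercise
  the downstream stages with calibrated inputs.
* Fingerprints are consumed as supplied bit vectors; no chemistry I/O or
  scaffold logic is included.
* Reproducing the original campaign's exact per-class counts from its
  public deposition is out of scope here: it requires the full deposited
  concentration–response set and threshold settings that were never
  published.
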