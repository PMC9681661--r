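---
title: "Methods: compartmental immune profiling of the maternal-fetal interface"
author: "mficyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmental immune profiling of the maternal-fetal interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mficyto)
```

## The problem

During the second half of mouse gestation (embryonic days E10.5–E18.5) the
maternal-fetal interface (MFI: placenta plus attached decidua) hosts maternal
immune cells in two distinct compartments — the endovascular blood space (EV)
and the protected tissue (TIS) — alongside maternal peripheral blood (PB) and
a small, growing contingent of fetal immune cells. Mass cytometry (CyTOF)
measures ~40 protein markers per cell, and three experimental tricks make the
compartments recoverable from single-cell intensities alone:

* a congenic cross (CD45.2 dam x CD45.1 sire) makes fetal immune cells
  CD45.2+CD45.1+ double-positive while maternal cells are CD45.2 single
  positive;
* an anti-CD45 antibody injected minutes before sacrifice labels every cell
  in contact with blood, so EV cells are bright on the injected channel and
  TIS cells are dark;
* DNA intercalator, cisplatin and Ter119 channels identify intact, live,
  non-erythroid cells.

This package implements the full analysis chain over such data — transform,
batch harmonization, rule-based gating, clustering and metaclustering,
compositional statistics, and gestational-trend inference — and pairs it with
a synthetic-data generator whose ground truth makes every stage testable
without the original acquisition files.

## The synthetic-data generator

`generate_study()` draws, for each (day, mouse, compartment) sample,
population counts from a multinomial over per-compartment abundance models,
then per-event marker intensities from the population's archetype.

**Marker model.** Archetypes are Gaussian on the arcsinh(x/5) scale
(positive markers near 4.5, background near 0.4, sd ~0.35), inverse
transformed to raw counts and floored at zero. Real CyTOF data are analyzed
on exactly this transformed scale, so defining archetypes there keeps them
interpretable; the specific per-population means are this package's choice
(no per-population intensity distributions are published) and are documented
in `default_populations()`.

**Abundance model.** Each population carries, per compartment, a polynomial
in day centered on the fixed reference day 14.5 (the middle of the E10.5–18.5
range): `intercept + slope*(day - 14.5) + quad*(day - 14.5)^2`, clipped at
zero and renormalized within each sample. A per-mouse log-normal random
intercept (`mouse_sd`, default 0.15) creates realistic between-mouse
variance so regression inference is exercised against over-dispersion, not
just multinomial noise. Fetal populations exist only in EV/TIS and ramp from
about 0.1% to 0.8% of immune cells across the day range.

**Gating-utility channels are set from ground truth**: DNA high for all
cells; cisplatin high only for the configured dead fraction (default 2%);
Ter119 high only for erythrocyte contaminants (default 2%); CD45.1 high only
for fetal events; injected-CD45 drawn at arcsinh mean 6.0 (sd 0.5) for PB/EV
events and 0.5 (sd 0.5) for TIS events. With these separations the rule
gates recover ground truth at ~100%; the means are configurable for harder
scenarios.

**Injections.** `inject_crossover()` rewrites two populations' models as
straight lines of opposite slope that intersect exactly at a chosen day
(slope set to 90% of the level over the maximal day distance, so both lines
stay positive). `inject_perturbation()` multiplies named populations'
abundance in the treated arm before renormalization. `add_batch_effect()`
applies a strictly monotone affine distortion on the arcsinh scale per
batch; every batch also carries one splenocyte anchor sample of common
material. `simulate_leakage_mouse()` emits a lymph-node control with a
configurable fraction of events above the EV threshold.

**What the generator does not emulate**: mass-channel spillover, bead
normalization drift, barcode collisions, doublets beyond an optional
broad-positive contaminant population, or cell-cell interaction structure.
Tests passing on this generator therefore certify the *computational*
pipeline — rules, statistics, recovery under known truth — not robustness to
every artifact of real acquisitions.

## Preprocessing

Intensities are transformed as `asinh(x / 5)`; the cofactor 5 is the
standard mass-cytometry choice and the one all downstream thresholds assume.
The transform state is carried on the event table and a double transform is
refused.

Batch harmonization maps, per batch and marker, the batch anchor's empirical
quantiles onto the reference batch anchor's quantiles: 101 equally spaced
quantile knots, linear interpolation between them, and — beyond the anchor's
observed range — continuation along the terminal knot segment's slope rather
than constant clamping, so the map is strictly increasing and within-batch
ranks are exactly preserved (a constant clamp would collapse the order of
rare bright events). The reference batch passes through untouched.
Normalization operates on the transformed scale; whether the original
analysis normalized raw or transformed intensities is not stated anywhere we
could find, so the choice is recorded in the quantile map output. The
normalization contract is verified by distortion reduction (anchor-vs-
reference KS distance strictly decreases on every marker), not by equality
with any particular package's output.

Subsampling (`subsample_events()`) retains up to a cap per group (mouse x
organ by default), uniformly without replacement, seeded — "up to" meaning
groups under the cap are kept whole.

## Gating

All gates are pure functions of transformed intensities plus a config:

* viable = DNA above threshold AND cisplatin below AND Ter119 below
  (defaults all 2.0 on the arcsinh scale, midway between the background and
  positive archetypes, each >3 sd from both);
* maternal = CD45.2 above, CD45.1 below; fetal = both above;
* compartment: maternal placental events with injected-CD45 **at or above
  3.5** are EV, below are TIS (the boundary is inclusive by rule); maternal
  PB events are PB; fetal events are never compartment-assigned by the
  injected-antibody rule.

The 3.5 cutoff is applied to the per-event channel value: a per-sample
median could not classify individual cells into compartments, which the
analysis requires. Thresholds that were drawn by hand in interactive gating
are config values here, with an optional two-component Gaussian-mixture
auto-fit (`fit_gate_valley()`) that takes the density valley between the
component means and falls back to the configured default, with a warning,
when the channel looks unimodal (component means closer than twice the mean
sd).

Leakage QC: a mouse whose lymph-node control has more than 5% of events at
or above the EV threshold is failed and excluded. "Significant leakage" has
no published definition; 5% is this package's fixed default, exposed in
`gate_config()`.

## Clustering and annotation

`cluster_events()` is a pluggable backend behind a fixed contract: exact
k-nearest-neighbor graph (k = 20) on the chosen marker panel, community
detection (Leiden, modularity objective) with a fixed seed. Cluster counts
from community detection are stochastic and data-dependent, so correctness
is judged by ground-truth recovery (adjusted Rand index), not by any
particular cluster count.

Profiles are per-cluster medians on the transformed scale; display values
min-max scale each marker across clusters, with zero-range markers defined
as 0 and flagged. `metacluster()` first applies the exclusion rules —
clusters whose scaled medians are all above 0.9 (broad-positive,
doublet-like) or all below 0.1 (all-negative) are dropped; the quantile
bounds are this package's defaults for exclusions that were visual in the
original workflow — then average-linkage agglomeration of median profiles
cut at height 3 (Euclidean). The cut height sits in the empirical gap
between within-population splinters (profile distances under ~2.5, driven by
high-variance markers such as Ly-6C) and between-lineage distances (above
~4.5, since lineages differ by ~4 arcsinh units on several markers). Manual
merge/exclude rules apply after, in order, and the whole map serializes to a
replayable rules table.

Threshold rules are boundary-inclusive exactly as stated: the FceRI = 1
split sends the boundary to the basophil branch; Ly-6C >= 4.5 is classical,
3 <= Ly-6C < 4.5 intermediate, < 3 non-classical.

## Compositional statistics

Cell fractions are tabulated per group with a declared denominator;
zero-count types are kept at fraction 0 and empty-denominator groups are
dropped with a warning. Bray-Curtis dissimilarity is
`1 - 2*sum(min(u, v)) / (sum(u) + sum(v))`, computed on counts when
available and fractions otherwise (the two coincide at equal per-sample
totals; the choice is visible in the inputs). Compartment comparisons pair
samples within mouse by default (the design is matched), with an all-pairs
mode available; group contrasts report the fold change of means and a
pooled-variance t test.

The discriminant projection is the Fisher construction: generalized
eigenvectors of between-class against pooled within-class scatter, the
within-class matrix ridge-regularized by `1e-8 * trace(Sw)/p` because eight
fraction features over few samples can make it singular. Axis signs are
fixed deterministically. The control-train/perturbed-project mode fits on
control samples and projects treated ones.

**Z-scores and the cross-over day.** `zscore_by_day()` standardizes per-day
mean fractions with the sample (n-1) sd. One analytic point matters for
cross-over detection: for any series that is *linear* in day, the z-score is
`±(day - mean(days))/sd(days)` — the slope cancels — so the z-curves of two
linear trends always intersect at the grid-mean day regardless of where the
fractions cross. The cross-over day of two cell types is therefore detected
on their per-day mean-fraction series (which intersect at the true crossing
by construction), while the z-series remain what is plotted to show the rank
exchange. `detect_crossover()` reports every consecutive day pair with a
sign change, a linearly interpolated crossing estimate, and exact zeros as
point crossings; no crossing is an empty result, not an error.

Condition contrasts report `log2(mean treated fraction / mean control
fraction)` per cell type with an uncorrected two-sample t flag at p < 0.05;
zero means are lifted by a declared pseudo-fraction (half the smallest
nonzero fraction observed).

## Gestational models

`fit_day_regression()` regresses embryonic day on fraction features by OLS
(pivoted least squares: compositions sum to one, so one feature is always
aliased and gets coefficient zero), reporting training R² and seeded 5-fold
cross-validated R² separately — the two are never conflated. Windows split
at E14: early is E10.5–13.5, late E14.5–18.5. `compare_windows()` takes the
ratio of mean R² and a pooled t test across fold scores; how the original
early-vs-late comparison was computed (folds vs mice) is not fully
specified, so the fold-score mode is the documented default.

`robust_trend_fit()` is OLS with the HC0 sandwich covariance
`(X'X)^-1 X' diag(e^2) X (X'X)^-1` and Wald z p-values — algebraically
identical to a GEE with singleton clusters and an independence working
correlation, which is why HC0 (not HC1) is the default; HC1 is an option.
Compartment is coded with PB as the reference so coefficients compare each
compartment against PB; day is mean-centered before squaring to reduce
collinearity of the quadratic term (whether the original analysis centered
is unstated; the choice is visible in the term naming).

Differential expression runs pooled two-sample t tests on per-mouse
per-marker medians with Bonferroni correction (significant = adjusted
p <= 0.05); markers with fewer than two mice per group are skipped with a
warning. `anova_dispatch()` uses a median-centered Levene test at 0.05 to
choose classic ANOVA (+ Tukey-HSD) or Welch ANOVA with Welch–Satterthwaite
degrees of freedom (+ Games-Howell from its standard studentized-range
formulation); any zero-variance group routes directly to the Welch branch.

The ratio test estimates a treated/control ratio of means with the
Taylor-series variance `V(X/Y) = E(X²)E(1/Y²) − [E(X)E(1/Y)]²` at the sample
moments — the per-observation delta-method variance, accurate to a few
percent for coefficients of variation under 0.2 — and compares two ratios by
a pooled t from descriptive statistics. Control zeros are lifted by a 0.5
pseudo-count (the conventional continuity correction), with a message.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations as follows,
chosen once as the conditions under which each claim is meaningful:

* recovery checks on the full study use 9 days x 3 mice x 3 compartments at
  1,500–2,000 events per sample;
* cross-over recovery uses 5 mice per day: the day-mean standard error under
  the default per-mouse intercept noise must be small relative to the
  injected slope for interval-level detection to be informative (at 3 mice
  per day the ±0.5-day interval check is underpowered);
* the HC0 null-calibration simulation uses 1,000 observations per replicate
  because HC0 is anti-conservative in small samples (we measure ~7%
  rejection at n = 78 and ~5.5% at n = 1,000 for a 5% nominal level); this
  is a property of the estimator, not of the implementation;
* the ANOVA-dispatch null uses 3 groups of 20; the dispatch's Levene
  pre-screen makes the compound test slightly conservative (~4.5%).

Degenerate inputs have defined behavior throughout: double transforms,
all-zero composition pairs, zero-variance z-series, unimodal auto-fit
channels, empty denominators, conflicting metacluster rules and rank-
deficient trend designs all raise errors or warnings rather than returning
silent numbers.

## Limitations

Ground-truth recovery on Gaussian archetypes is an easier problem than real
CyTOF annotation: real populations overlap, shift between batches in
non-affine ways, and contain states the panel cannot separate. The
clustering contract is deterministic only for a fixed backend version
(igraph's Leiden here). The GEE equivalence holds exactly for singleton
clusters and independence working correlation — repeated measures per mouse
across compartments are not modeled beyond the robust variance. The FCS
writer/reader covers the float list-mode subset of FCS 3.1 that this
pipeline emits, not the full standard.
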