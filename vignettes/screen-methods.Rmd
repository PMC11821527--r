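---
title: "Methods: multiomic screen statistics for mitochondrial stress recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiomic screen statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

# Scope and data model

`mitoscreen` implements the statistics layer of a multiomic screen in which
*Saccharomyces cerevisiae* strains carrying graded perturbations of
mitochondrial proteostasis are profiled by mass spectrometry (proteins,
lipids, metabolites) at an early (E) timepoint and, for growth-delayed
strains, a late (L) recovery timepoint.  The central container is the
`ScreenExperiment`, a `SummarizedExperiment` of log2 abundances with
molecule annotations (layer, mitochondrial flag, lipid class) on rows and
(strain, group, timepoint, replicate) annotations on columns.  Everything
downstream — differential abundance, enrichment, clustering, the TAG
correlation score — operates on this object or on the condition-wise
fold-change matrix derived from it.

# The screen statistics

**Differential abundance.**  For a case and reference sample set the
log2 fold change is the difference of replicate means on the log2 scale and
the p-value comes from a two-sided equal-variance Student's t-test on the
replicate values.  Welch's correction is deliberately not used; the screen's
convention is the classic Student test at n = 3 per group.  A molecule is
*significant* iff |log2 FC| > 0.7 **and** P < 0.05, both strict: boundary
values (FC exactly 0.7, P exactly 0.05) are not significant.  No
multiple-testing correction is applied by default — the screen couples a raw
P threshold with an effect-size cutoff — but a Benjamini–Hochberg flag is
available.  When both groups have zero within-group variance and unequal
means the t statistic is undefined; the record is flagged `degenerate` and
its p-value reported as the smallest positive double, so such molecules sort
first rather than vanish.

**Imputation.**  Label-free proteomics data are missing preferentially at
low intensity, so missing values are drawn per sample column from a
down-shifted normal, `N(mean − 1.8·sd, (0.3·sd)²)` of that column's observed
values — the conventional width-0.3 / down-shift-1.8 law.  Only the protein
layer of the simulator injects missingness; lipids and metabolites are
analysed complete, and imputation is applied before any fold-change
computation.

**Mitochondrial enrichment.**  Whether significantly decreased proteins are
enriched for mitochondrial proteins is tested on the 2×2 table
(mitochondrial vs not) × (significantly changed in the direction of interest
vs not) with the Fisher exact test.  The two-sided p sums hypergeometric
probabilities not exceeding the observed table's probability (with the
conventional 1e−7 relative tie tolerance); a one-sided (`greater`) variant
is available.  The odds ratio is the plain cross-product ad/bc, infinite
when bc = 0.

**Clustering.**  Strain conditions are clustered on the molecules ×
conditions matrix of mean log2 fold changes: each molecule row is z-scored,
condition–condition distances are Euclidean, and linkage is average
(configurable; the distance and z-transform are the fixed conventions).
Constant rows, whose z-score is undefined, are dropped with a warning.

**∆∆Ct.**  Relative mtDNA abundance from qPCR follows the textbook
`2^−∆∆Ct` with the nuclear actin amplicon as the reference gene.

# The average-rank Spearman correlation score

This is the procedure that connects a query set of depleted TAG species to
the proteins that co-vary with them.  Profiles are the condition-wise mean
log2 fold changes.  For every query q the Spearman coefficient ρ(q, m) is
computed against every other molecule m; molecules are ranked per query by
descending ρ (rank 1 = most positively correlated, ties averaged), and each
molecule's score is its average rank across queries.  The final order is
ascending average rank.

Conventions the procedure needs but that are genuinely open:

* **Self-pairs** ρ(q, q) are excluded from q's own ranking (they are always
  1 and carry no information); query molecules still appear in the other
  queries' rankings, so TAG species may legitimately dominate the top of the
  report.
* **Ties** in the average rank are broken by descending mean ρ (rounded to
  10 decimals so the order is stable to floating-point noise between
  correlation implementations) and then lexically by molecule id.
* **Undefined correlations** (constant profiles) are excluded from that
  query's ranking with a count; molecules undefined against every query are
  dropped with a warning.
* A flag flips rank 1 to the most negatively correlated molecule for
  exploratory use.

The implementation is checked against a brute-force oracle (explicit rank
arithmetic, quadratic loops) on hundreds of random small instances,
including tied and constant rows.

# Lipid label accounting

The tracer model is [¹³C₁]oleic acid: each incorporated oleoyl chain
carries one heavy carbon, so the fully labeled isotopologue of a species
carries one label per acyl chain — 3 for TAG, 4 for cardiolipin, 2 for
diacyl phospholipids.  Isotopologue m/z values shift by exactly
k × 1.0033548 Da (the ¹³C–¹²C mass difference) at charge 1; the target list
supplies observed m/z directly, so no adduct chemistry is computed.
Features match targets within 10 ppm and 0.4 min, one-to-one by nearest
mass then nearest retention time.  Peak areas are normalized to the CoQ₈
internal standard of the same run, and chase timepoints to the mean of the
condition's T₀ samples; mobilization kinetics come from a log-linear fit of
the T₀-relative values, reported as a decay rate per hour with its standard
error.  Natural-abundance isotope correction is available nowhere in the
chain: the tracked species are the fully labeled isotopologues, whose
natural-abundance contamination at these masses is negligible, and the
screen's convention is uncorrected areas.

The feature-quality filter chain keeps a feature only if peak intensity
≥ 2×10⁶ (5×10⁴ in the metabolomics preset), peak width ≤ 0.75 min,
S/N ≥ 1.5, intensity ≥ 3-fold blank, and QC coefficient of variation
< 30%.  Removed features carry the first failing rule's name, checked in
that order, so filter reports are reproducible.

# Organelle volume fractions

Cells are modelled as prolate ellipsoids (semi-axes a ≥ b = c) with the
major axis in the imaging plane.  The pipeline is:

1. **Cell segmentation** — a z-projection of the cell channel is Otsu
   thresholded and 8-connected components above a minimum area become cell
   footprints.  The projection is *maximum* intensity by default: the
   average projection of a rounded cell is chord-graded, and Otsu on such a
   graded image erodes the footprint by ≈8% per axis (−22% volume), while
   the maximum projection is near-binary and preserves the outline.  A mean
   projection remains available, and the downstream contract starts from
   masks, so any external segmenter's masks can be substituted.
2. **Ellipsoid fit** — a and b are the equivalent-ellipse semi-axes from the
   footprint's second-order central moments (with the 1/12-pixel variance
   correction), and `V_cell = 4/3·π·a·b²`.
3. **Organelle volume** — the probability map is thresholded at 0.5 (values
   equal to 0.5 are foreground), organelle voxels inside the cell's 2-D
   footprint are counted across all z-planes, and the count is converted to
   µm³ with the anisotropic voxel volume (default 0.2 × 0.1 × 0.1 µm, the
   0.2 µm z-step of the acquisition).  Objects touching cell borders are
   included.  Connectivity is 26 in 3-D and 8 in 2-D (the most permissive
   standard choices, configurable).
4. **Normality** — a cell is `none_detected` if it has no organelle signal,
   otherwise `normal` iff its volume fraction lies within 1.5 s.d. of the
   wild-type mean, with `abnormal_low`/`abnormal_high` by the sign of the
   deviation.  Population densities use a Gaussian KDE with Scott's-rule
   bandwidth by default.

# Growth phenotyping

Plate-reader curves (OD₆₀₀ every 10 min) are smoothed with a centred 5-point
moving average.  The diauxic shift is the local minimum of the smoothed OD
derivative between the two growth phases; a curve whose derivative never
resumes after a dip is classified as not having survived the shift, and
curves with a single phase are analysed whole.  Stationary phase is the
terminal segment whose log-slope stays below 5% of the maximum rate.
Within the post-shift, pre-stationary segment, log-OD slopes are fitted
over 5-point sliding windows.  Two numerical choices matter:

* **Rate.**  The raw maximal window slope of a logistic underestimates the
  low-density rate once growth resumes from a non-negligible post-diauxic
  baseline (by the factor 1 − OD/K), and under realistic measurement noise
  the *maximum* over many noisy window slopes is biased high by tens of
  percent.  The reported rate is therefore the median of capacity-corrected
  window slopes, `slope/(1 − OD/K̂)`, over the exponential core (windows
  clearly above baseline, below half of the stationary OD `K̂`, and within
  2× of the best corrected slope).  On a noiseless single-phase logistic
  this reduces to the planted rate.
* **Lag.**  Each core window's fitted OD is inverted through the logistic
  solution `t − lag = (1/r)·log[OD(K−B)/(B(K−OD))]` with B the pre-shift
  baseline; the median over windows is the lag.  In the early-exponential
  limit this is exactly the classic tangent–baseline intercept, without the
  curvature bias a plain tangent accrues as OD departs from the baseline.

Group assignment follows the screen's rules: group 4 if the strain did not
survive the diauxic shift; group 1 if its lag is within 20 min of
wild-type; group 2/3 split by an excess-lag cutoff.  That mild-vs-severe
boundary is not quantified anywhere authoritative, so it is an explicit
parameter (default 240 min) and no claim is made that this value is the
screen's.  The late-collection scheduler returns the earliest time a curve
reaches 90% of the average wild-type OD at 24 h.

# What the synthetic data emulate — and what they do not

Every generator is seeded and byte-deterministic, and each returns the
ground truth it planted.

**Omics screen.**  Ten strains (2 wild-type controls and 8 experimental in
four stress groups), triplicates, E for all and L for groups 2–3.  Planted
log2 effects are additive before Gaussian replicate noise (s.d. 0.2 by
default; MS abundances are lognormal, so Gaussian-on-log2 is the standard
noise model): mitochondrial proteins and cardiolipin deplete at E and
recover (CL overshoots) at L in groups 2–3, TAG species deplete in
groups 2–3 but not in group 4, and group 4 shows mitochondrial depletion
with no recovery timepoint.  Each strain carries a lognormal mean-1
severity multiplier and per-axis (mito/TAG/CL) multipliers (s.d. 0.2 each):
identical effect magnitudes within a group would make the mitochondrial and
TAG profiles collinear, which both defeats correlate recovery and is
unrealistic — real point mutants differ in severity, and the
non-recovering strain demonstrates that proteome depletion and TAG
mobilization decouple.  Exactly one designated perilipin-like protein has a
condition profile equal to the mean TAG profile scaled by
`correlate_strength` (0.9) plus independent noise scaled so the zero-noise
limit is exact; it is exempt from missingness injection, since a correlate
whose profile is destroyed by imputation has no recoverable identity.
Missing values go into the protein layer only, with probability logistic in
the within-sample abundance rank.  Effect magnitudes are configurable
defaults chosen to be plausible for this kind of screen, not asserted
measurements.

**Growth curves.**  Two logistic phases joined at a linear diauxic dip,
sampled every 10 min; non-survivors plateau after the dip.  The planted lag
is defined as the time the second-phase logistic leaves the post-dip
baseline, i.e. the tangent-intercept lag, which makes generator and
estimator speak the same convention.  Additive OD noise of s.d. 0.005 is
the realistic plate-reader magnitude used in the round-trip checks.

**Labeled peaks.**  Fully labeled isotopologues decay exponentially from T₀
at each condition's rate; light species stay at baseline; every sample
carries an internal-standard area with 5% lognormal noise and every feature
carries width/S-N/blank/QC columns so the filter chain can run on simulated
tables.  Peak areas get 10% lognormal noise.

**Image stacks.**  Prolate-ellipsoid cells are rasterized side by side with
margins; organelles are spheres of radius 9 voxels in index space (slightly
anisotropic in physical units), painted — overlap allowed, as in a merged
organelle network — until the union reaches the requested fraction of the
analytic cell volume.  The probability map is the binary truth blurred with
a Gaussian of s.d. 1 voxel and clipped to [0, 1], the minimal stand-in for
classifier softness.  The blob radius is deliberately not small: thresholding
a blurred ball at 0.5 shifts the boundary inward by ≈σ²/R per axis, so the
volume bias is ≈3σ²/R², and a radius ≥8 voxels keeps it inside the 5%
recovery band the round-trip checks use.  Ground truth records the
*rasterized* organelle volume over the analytic cell volume, since the
requested fraction is only attainable up to voxelization.

None of the generators simulate raw spectra, chromatograms, isotope
envelopes, optics (PSF, spectral bleed-through), mother/daughter cell
relationships, or batch effects.  Passing the round-trip checks therefore
demonstrates correctness of the statistics and geometry under the stated
noise models, not robustness to every artefact of real acquisitions.

# Problem sizes and determinism

The test-suite and report-script workloads are sized for interactive runs:
200 random instances for the rank-score oracle, 100 seeded screens
(~580 molecules × 45 samples each) for correlate recovery, all 2×2 tables
with total ≤ 30 for the Fisher enumeration, 10⁴ null molecules for the
type-I check, 10⁵ draws for the imputation law, three-cell stacks at
0.1 × 0.1 × 0.2 µm voxels for volume recovery, and 100 seeded curves/decay
tables for the growth and kinetics round trips.  All randomness flows
through explicit seeds; `runScreen()` writes report bundles that are
byte-identical when re-run with the same seed and configuration, with the
config digest recorded in the run log.

# Known limitations

* The t-test assumes normal replicate noise; at n = 3 it is not robust to
  heavy tails, and the screen's convention of raw P plus an FC cutoff means
  the significant set is not FDR-controlled.
* The correlation score has no significance calibration (by design — it is
  a ranking, and the screen reports no p-values for it).
* The prolate-ellipsoid model misestimates volumes of budding or clumped
  cells, and the footprint-based organelle assignment attributes any
  organelle voxel above or below a cell's footprint to that cell.
* The growth-metric capacity correction assumes a logistic saturation; on
  curves that never saturate the correction degrades gracefully to the raw
  log-slope but the lag inversion loses its anchor.
* The simulator's missingness is monotone in abundance rank; real MS
  missingness also has stochastic and batch components.
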