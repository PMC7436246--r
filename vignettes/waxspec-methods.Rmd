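---
title: "Methods: from leaf reflectance to wax QTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from leaf reflectance to wax QTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waxspec)
```

## The problem

Onion (*Allium cepa*) leaves carry epicuticular waxes — principally the
ketone hentriacontanone-16 (H16) and the fatty alcohols octacosanol-1 (Oct)
and triacontanol-1 (Tri) — whose amounts condition visual foliage classes
(glossy, semi-glossy, waxy) and feeding damage by onion thrips. The
reference assay is GCMS on chloroform leaf extracts, reported as peak areas
adjusted to an internal docosane standard per gram fresh weight; it is slow
and destructive. waxspec implements the alternative: full-range
(350--2500 nm) leaf reflectance spectroscopy, partial least-squares
regression (PLSR) calibration of wax amounts against GCMS references, and
downstream genetic mapping of the predicted amounts in an F2 family from a
glossy x waxy cross.

Because no spectra, GCMS tables, or genotypes are distributed with the
original study, the package ships a synthetic-data generator calibrated to
the published summary tables. Everything downstream of the generator is the
real method, applied to data of the published shape and magnitude.

## Synthetic standards and leaf spectra

First-derivative spectra of the pure wax standards are modeled as sums of
Gaussian features. The feature centers are the published wavelength lists:
each wax has one unique fingerprint (H16 2259 nm, Oct 645 nm, Tri 730 nm),
the 1714--1757 and 2302--2348 nm bands are common to all three waxes, and
915, 1500, 1890, and 2175 nm are shared by the two fatty alcohols.
Amplitudes and widths are nowhere printed, so they are free parameters with
defaults chosen once: width (Gaussian sd) 10 nm — features in derivative
spectra of waxy solids are a few tens of nm wide — amplitude 1.0 for unique
and 0.6 for shared features, signs alternating along the wavelength axis as
derivative spectra do. One wavelength ambiguity exists in the source
material: the Oct fingerprint is given as 645 nm in four places and 650 nm
in one; the package uses 645 nm.

Leaf spectra are a parametric green-leaf baseline (chlorophyll absorptions,
red edge, NIR plateau, water bands) plus, for each wax, the *integral* of
its first-derivative signature scaled by `amount x coupling`, plus i.i.d.
Gaussian noise, clipped to [0, 1]. Carrying the integrated form makes
preprocessing exactly invertible: differentiating a noise-free leaf
spectrum recovers the feature signature, which the test suite checks. Two
deliberate simplifications: the coupling between adjusted-peak-area units
and reflectance magnitude is unknown in reality and fixed here at 0.002 per
unit amount, and wax effects are strictly linear with no scattering
physics. Consequently a passing pipeline demonstrates correctness of the
chain, not real-leaf transferability; radiative-transfer realism
(PROSPECT-style) is out of scope.

Default measurement noise is sd 0.005 reflectance units, a realistic
magnitude for a contact probe with a Spectralon reference. At this noise
the synthetic calibration is much cleaner than real leaves, so validation
R^2 near 1 is expected here even though the published real-data values are
0.41--0.86.

## Accession panel and F2 family

The seven-accession panel draws per-plant wax amounts from Gaussians with
the published means, truncated at zero, with per-plant sd = SE x sqrt(3)
(the published SEs come from three replications). A mean of exactly zero
(Tri and the minor waxes in 'Odourless Greenleaf') yields exactly zero: the
wax is absent, not noisy. The five minor waxes, for which only percentage
profiles are printed, get means completing each accession's percentage row
at the same total; their SEs reuse the median relative SE of the three
major waxes. The panel defaults mirror the study design: three plants per
accession, two repetitions, four averaged readings collapsed to one
spectrum per plant.

The F2 generator simulates 94 individuals on an eight-chromosome map
(80 cM each, markers every 5 cM). Chromosome 8 carries the six named SNPs
of the published QTL region; only two published positions exist
(i19082_1721 at 41.1 cM, i20235_630 at 46.2 cM), so the other four sit at
synthetic positions (26, 31, 36, 51 cM) consistent with their roles as
interval flanks. Gametes are independent Markov chains with Haldane
recombination and no interference. Phenotypes follow
`y = mu + a*x_a + d*x_d + e` with the published additive/dominance effects;
the residual sd solves `a^2/2 + d^2/4 = f * total variance` for the
published variance fraction `f` under 1:2:1 frequencies, and the intercept
`mu = mean - d/2` pins the population mean to the published F2 mean (0.84
for GCMS H16). Phenotypes are *not* truncated at zero — they live on the
measurement scale, where regression predictions can be negative — but leaf
spectra are generated from the zero-truncated amounts, since a leaf cannot
carry negative wax.

## Preprocessing

Spectra are resampled to the 5 nm analysis grid (350, 355, ..., 2500 nm)
by linear interpolation; the native interpolation method of the instrument
software is unspecified, and linear is the assumption-free choice.
Replicate readings are averaged pointwise. First derivatives default to a
Savitzky-Golay smoothing derivative (window 11 points, quadratic), the
standard chemometric estimator; a plain central-difference option serves
as an independent cross-check and the two agree within a few percent on
smooth signatures at 1 nm resolution. Savitzky-Golay end points use the
filter's off-center polynomial fits rather than one-sided differences —
the standard treatment, and it avoids a discontinuity in derivative
magnitude at the spectrum ends. The quality-control screen replaces the
study's visual inspection with explicit rules (any negative or non-finite
reflectance, implausibly high reflectance, or mean 760--900 nm reflectance
below 0.10); any numeric rule is necessarily an interpretation of a visual
step, so all thresholds are configurable.

Feature detection reports signed local extrema above a prominence floor
(default 10% of the maximum absolute derivative) with a minimum separation
of 10 nm. Unique/shared classification pools the three standards' features
and single-links wavelengths within +-10 nm — the tolerance implied by the
source's informal alignment of, e.g., 643 vs 645 nm. Standards are
processed at their native 1 nm resolution; the 5 nm grid is a modeling
economy for PLSR only (on it, the fingerprints snap to the nearest grid
points).

## PLSR, PRESS, and diagnostics

The regression core is NIPALS PLS1 with deflation of the predictors only.
Determinism across platforms is enforced by a sign convention (each weight
vector's largest-magnitude element positive). Predictors are centered but
not autoscaled by default — autoscaling is a configurable option, and the
standardized-coefficient display applies standardization regardless — and
the response is centered. Degenerate deflation (no covariance left) stops
extraction early with a warning rather than fabricating components.

Calibration/validation partitioning is random within quartiles of the
stratifying variable so both sets span the range; one plan is reused for
all three waxes, stratified on the *total* of the three wax amounts, since
the source does not say which chemical's quartiles constrained its shared
split. The latent-vector count minimizes PRESS over 500 random 90/10
splits of the calibration set (independent draws, not a partition), with
argmin ties broken toward fewer components; the default candidate ceiling
is 15, capped at half the calibration size. Cross-validation performance
is computed from the pooled held-out predictions at the chosen count;
external validation applies the frozen model to the untouched validation
third plus the F2 family, matching the study design.

Reported metrics: R^2 as squared Pearson correlation (the scatter-plot
definition; `1 - SSE/SST` is the documented alternative), RMSE, and
relative RMSE = 100 x RMSE / observed range. Variable importance in
projection follows Wold's formula, so squared VIP scores average to
exactly 1 and VIP > 1 flags influential wavelengths; standardized
coefficients are `b_j * sd(X_j)/sd(y)`.

## QTL mapping

Genotype probabilities are evaluated every 1 cM (pseudomarkers plus
markers) conditional on the nearest non-missing flanking markers under the
two-gamete Markov model with Haldane distances — the mapping-software
default, chosen because the source is silent on the map function. The
Haley-Knott scan regresses the phenotype on `P(BB) - P(AA)` and `P(AB)`,
so a positive additive effect means the waxy-parent allele increases the
trait, and `LOD = (n/2) log10(RSS0/RSS1)`. Marker covariates (the
source's "ten markers as covariates" device) are supported with a 10 cM
exclusion window around the test position, but plain interval mapping is
the default mode, which is what the published QTL table reports.
Significance uses the 95th linear-interpolation quantile of genome-wide
maximum LOD over 1000 phenotype permutations; support intervals are
1.5-LOD drops with the nearest typed markers outside each end; the greedy
stepwise search adds QTL while the conditional LOD gain beats the
threshold and refits jointly.

A known property of this estimator matters when comparing recovered to
published values: the raw fitted variance fraction `1 - RSS1/RSS0` at
n = 94 with two regressors overestimates the population fraction by
roughly `(1 - R^2) * 2/n` (about 1.7 points at R^2 = 0.21), and fitting at
the maximum-LOD position adds selection bias of about one more point. The
package reports the raw fitted values, as the original analysis tooling
does, and does not bias-correct; simulated recovery under a preset
therefore averages a little above the preset's population fraction, and
mean maximum LOD a little above the closed-form
`(n/2) log10(1/(1 - R^2))` at the true position.

## Accession statistics

Accession means come from the fixed-effects two-way model
`y = mu + accession + repetition + accession:repetition + error`,
least-squares marginal means with SEs, Type II sums of squares when data
are unbalanced (the source is silent; Type II avoids order dependence).
Pairwise comparisons use the studentized range (Tukey HSD) at alpha =
0.05, summarized by an insert-and-absorb compact letter display
implemented in the package; two accessions share a letter exactly when
their adjusted difference is non-significant, which the tests verify
directly against the pairwise p-values.

## Numerical choices and problem sizes

Tolerances and tie-breaks that are not principled statistics are fixed
as follows: NIPALS stops at weight or score norms below 1e-12; PRESS and
stepwise ties resolve toward the smaller model; permutation thresholds use
quantile type 7; QC, prominence, separation, and linkage tolerances as
above. All generators accept a seed and are bit-reproducible; drawing
order is documented by the code structure (panel: accession x repetition x
plant; F2: chromosome by chromosome, then residuals).

The packaged experiments use the study's sizes where printed (94 F2
individuals, three plants x two repetitions, 500 PRESS permutations, 1000
scan permutations, 200 simulated families for recovery experiments); the
test suite exercises reduced sizes of the same code paths where a property
does not need the full design.

## Limitations

The simulator omits scattering physics, instrument splice artifacts,
water-band saturation, within-leaf heterogeneity, and any attenuation of
the spectroscopy-predicted phenotype relative to GCMS truth — so
spectroscopy-predicted and GCMS QTL results agree more tightly here than
on real data. The QC rules are an interpretation of a visual screen. The
compact letter display assumes the pairwise tests' error structure is
exchangeable across pairs, as Tukey HSD does. None of the published
real-data R^2 values can be reproduced without the unreleased
measurements; the recoverable quantities are the arithmetic identities,
the unique-wavelength structure, and the generator calibration targets.
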