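---
title: "Mapping protein gradients along porto-central trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein gradients along porto-central trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonemap)
```

## The problem

Hepatocytes change their proteome continuously along the axis from the
portal to the central vein of a liver lobule. Single-cell Deep Visual
Proteomics can measure that variation cell by cell, but two computational
problems sit between the microscope and a zonation statement. First, which
cells should be excised? A trajectory between one central and one portal
vein must be covered evenly with a limited cell budget, because laser
microdissection and MS time are the bottleneck. Second, how should a
per-protein gradient be estimated and tested when cells are nested in
patients whose baseline intensities differ? `zonemap` answers the first
with max-min dispersion sampling and the second with a random-intercept
linear mixed model, and ships synthetic generators so both answers are
continuously verified against known ground truth.

## Cell selection geometry

Vein lumens carry no cells, so they appear as voids in the cell-boundary
stain. `detect_veins()` blurs the channel (default sigma 5 px), applies a
grayscale dilation (disc radius 10 px) to erase small voids, and thresholds
at the minimum between the two modes of the intensity histogram. The
histogram-minimum threshold is found by smoothing the histogram with a
width-3 moving average until exactly two maxima remain; because heavy
smoothing can manufacture a shallow "valley" inside a single mode on
near-constant images, the located valley must also be nearly empty on the
raw histogram (mean count within two bins below 5% of the modal count), or
the image is declared void-free. A constant image is an error ("no
histogram valley"); a unimodal one simply yields no candidates.

Candidate regions are typed by comparing the mean image-wide-standardized
pericentral and periportal marker intensities in an annulus around the
region (defaults: 15 px wide, clipped at the image border); veins are then
paired greedily by anchor distance. The trajectory ROI keeps cells whose
centroid projects onto the open segment between the anchors and whose
angular deviation from the axis, measured at the nearer anchor, is at most
65 degrees. The 65-degree wording admits several geometries (one-sided
wedge, lens, band); the implementation uses the symmetric two-sided cone
and documents it — changing the predicate changes the ROI and should be a
deliberate choice.

Selection solves max-min dispersion greedily (farthest-first traversal):
initialize with the exact diameter pair of the centroid set (ties broken by
lowest cell id for reproducibility), then repeatedly add the cell
maximizing its minimum distance to the selection. The greedy value is never
below half the exhaustive optimum; the test suite checks this bound on 200
random instances against a brute-force oracle and exact equality on a
collinear instance. Each selected cell's spatial ratio is
`S = d_central / (d_central + d_portal)` from centroid-to-anchor distances,
so S = 0 at the central and S = 1 at the portal anchor; an `orientation`
flag flips the convention. In manual mode two clicked points replace the
detected anchors (degenerate point veins) and everything downstream is
identical — the suite asserts exact agreement between the modes.

Cutting contours are simplified before export: vertices are decimated
uniformly to at most `ceiling(0.10 * n)` (minimum 3), and the simplified
polygon is rescaled about its centroid so its area equals the original
exactly. Pure vertex-subset decimation cannot keep the area of a dense
circle-like contour within a few percent at a 10:1 reduction (an inscribed
decagon already loses 6.5%), which is why area renormalization is part of
the operation. Export writes the Leica-style XML dialect (three calibration
points, per-shape vertex lists) with a lossless reader alongside.

## The gradient model

Per protein, observed intensities across the analyzed cohort go through
Tukey's fences (k = 1.5; quartiles by linear interpolation, R type 7) and a
robust scaler ((x − median)/IQR; zero IQR skips the protein with a logged
reason). The model is then

$$y_{ij} = \beta_0 + \beta_1 S_{ij} + u_i + \epsilon_{ij}, \qquad
u_i \sim N(0, \sigma_u^2), \quad \epsilon_{ij} \sim N(0, \sigma^2)$$

fitted by REML via lme4 with a fallback to ML on non-convergence;
a boundary fit with $\sigma_u^2 = 0$ is a valid result, and a single-patient
cohort degenerates to ordinary least squares. The zonation coefficient
$\beta_1$ (units: normalized intensity per unit S) is Wald-tested with the
standard normal reference — the large per-protein cell counts make the
difference to a t reference negligible, and the choice is documented and
encapsulated should a t reference ever be preferred. Q values are
Benjamini–Hochberg over all converged fits; $\beta_1 < 0$ is central
enrichment, and |β₁| > 1 with Q < 0.05 is the "strong" call. Proteins are
fitted independently, with no shrinkage across proteins; the model is
deliberately linear in S and does not attempt splines or spatial
autocorrelation.

Cross-condition contrasts take the strongly zonated proteins of the
reference condition, compute $\Delta\beta_1$ with
$SE = \sqrt{SE_A^2 + SE_B^2}$, Wald-test against zero, BH-adjust within the
scoped set, and call a loss at $|\Delta\beta_1| > 1$ and Q < 0.05. Scoped
proteins absent or unconverged in the second condition are reported as not
detected rather than dropped silently. The per-direction summary reports
median $|\Delta\beta_1|$, loss/maintained/not-detected fractions and a
two-sided unpaired rank-sum test between the central and portal groups
(all-tied inputs return p = 1 by convention).

## Quality control and the discrete comparator

"Detected" always means a finite positive intensity; zeros, empty fields
and NaN are missing, and no imputation happens anywhere. Sample QC excludes
shapes whose identification count lies below median − 1.5 s.d. or above
median + 3 s.d.; median and (n−1) s.d. are computed once over all samples
before exclusion — a single-pass rule, since iterating the fences would
make the filter depend on its own output. The completeness filter keeps
proteins observed in at least 70% of samples (inclusive). The pipeline
applies sample QC first, then completeness; the order matters on crafted
inputs and is pinned by a regression test. Contamination scores rank each
sample's detected proteins ascending (average ranks on ties, undetected
markers rank 0) and report the median rank per marker panel, which makes
the score invariant under any strictly monotone transform of a sample's
intensities. The PCA check uses only proteins with no missing values,
standardizes each, excludes samples with any |Z| > 3, fixes each PC's sign
(first nonzero loading positive) and reports the Spearman correlation of
PC1 with S. Because features are standardized, a lone high-variance
spatial feature cannot dominate PC1; the association emerges when several
proteins share the spatial signal, which is what the tests construct.

The discrete comparator bins cells into 20 equal-width, left-closed bins on
[0, 1] (last bin closed), averages observed values per (protein, bin),
Z-scores along the bin axis with the sample (n−1) standard deviation, and
orders heatmap rows by (mean of last 3 bins) − (mean of first 3 bins). The
endpoints of the "expression difference" sort key are not uniquely
determined by its name; 3-bin end means were chosen over single end bins
for robustness to a single sparse bin, and ties break by protein id. The
per-protein one-way ANOVA across bins uses the ordinary sums of squares
(for a single factor the Type II decomposition coincides with it) and is
verified against a from-scratch oracle; constant inputs return F = 0,
p = 1 rather than 0/0.

## DIA window design

`compute_variable_windows()` places the interior edges of 60 contiguous
windows over 380–980 m/z at inverse-ECDF quantiles of the in-range
precursor m/z values, averaging the two adjacent order statistics when a
quantile lands exactly on one. With distinct m/z values this makes
per-window precursor counts differ by at most one under the half-open
[low, high) convention, and the edges are exactly invariant to duplicating
every precursor. Equal counts were chosen as the density functional;
equalizing summed intensity would be a one-line change but needs
intensities the input list may not carry. A minimum window width is
exposed but off by default, because enforcing it trades away the
equal-count property; exact duplicate edges (heavily tied inputs) are
merged with a warning.

## What the synthetic generators emulate — and what they do not

The tissue generator draws two circular vein lumens on a 256 × 512 px
scene (anchors 400 px apart, lumen radius 24 px — a long trajectory
relative to the lumen, as in a real lobule section), exponential marker
fields decaying from each anchor (length 60 px), a uniformly bright
boundary channel that is exactly zero inside lumens, and nuclei discs at
cell centroids, plus |N(0, 0.02)| pixel noise. Cells are star-convex
radial-jitter polygons around jittered grid seeds (pitch 16 px, jitter
3 px); the maximal polygon radius is kept below half the minimal seed
distance, so cells are disjoint by construction without running a
segmentation model. A Voronoi tessellation of the seeds was the obvious
alternative; the radial-jitter construction was chosen because it needs no
tessellation dependency and gives the same downstream geometry (disjoint
polygons with known centroids tiling the non-vein area). The generator does
not model optics (PSF, tiling), nucleus morphology, or touching-cell
boundaries — conclusions about segmentation robustness cannot be drawn
from it.

The proteome generator draws from exactly the model the fitter assumes:
per-protein β₀ ~ N(20, 1) (a log-like intensity scale), a fraction (default
0.3) of proteins zonated with |β₁| uniform in [0.5, 2] and random sign,
per-(protein, patient) random intercepts (σ_u = 0.5), residual noise
(σ_e = 0.3), and 14 patients × 44 cells by default. Missingness is
intensity-dependent: an entry with per-protein standardized latent value z
is observed with probability plogis((z − m)·s), defaults m = −2, s = 1
(≈88% observed, missingness concentrated at low intensities). The true
dropout law of single-cell DVP data is unknown; logistic MNAR is a stand-in
with exposed parameters, and `dropout_midpoint = -Inf` disables it. Because
generator and fitter share the model family, passing recovery tests shows
the estimator is correct and calibrated — not that real data satisfy the
model; the linearity and Gaussian assumptions remain assumptions.

## Numerical and calibration choices

Problem sizes in the tests and the acceptance script were fixed in advance
at the cohort design the package targets: 14 patients × 44 cells, 200
proteins for recovery and error-control runs, 50 replicates of 12 proteins
for contrast power (14 vs 4 patients), 20 replicates for the contrast
null, 200 random instances for the dispersion oracle. Calibration runs
(slope recovery, type-I error, contrast power) fit the generator output
directly without Tukey/robust-scale preprocessing and without dropout: the
generator already emits values on the normalized scale with no outliers,
and the recovery and loss thresholds (bias < 0.05, |Δβ₁| > 1) are stated
on the generator's coefficient scale, which per-cohort IQR rescaling would
distort. The preprocessing path is exercised separately by the pipeline
tests. All randomness flows through one seeded generator per call and the
global RNG state is restored afterwards, so runs are bit-reproducible;
rerunning the zonation workflow must produce byte-identical output files,
and a test asserts it.

## Known limitations

Vein detection needs a bimodal boundary histogram; faint or very small
lumens (after dilation) fall below the area filter or the valley check and
require manual anchors — which is precisely the GUI workflow the manual
mode mirrors for diseased tissue. The cone ROI is a geometric
approximation of "between the veins"; the mixed model is linear in S and
blind to non-monotone gradients; Wald inference uses the normal reference,
which is mildly anticonservative for designs with few patients and strong
between-patient information; and the contamination score depends on the
marker panels' reference table, which the package consumes but cannot
validate biologically.
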