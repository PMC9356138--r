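---
title: "Phasor segmentation and the metabolic index: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor segmentation and the metabolic index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsmi)
```

## The measurement problem

Platinum-resistant cancer cells shift their metabolism from glucose-driven
anabolism toward exogenous fatty-acid (FA) uptake and beta-oxidation.
Hyperspectral stimulated Raman scattering (SRS) microscopy makes both
fluxes visible in single cells: deuterated glucose labels newly
synthesised macromolecules in the C–D window (~2050–2350 cm⁻¹), while a
deuterated FA, or the alkyne-tagged FA analog ODYA with its sharp C≡C
band near 2100 cm⁻¹, reports FA uptake. A stack of ~50 images across a
Raman window gives every pixel a spectrum; the analysis task is to turn
those spectra into per-cell chemical quantities and, ultimately, a single
per-sample number — the metabolic index — that predicts resistance.

## The spectral phasor

For a pixel spectrum $I_k$, $k = 0 \dots N-1$, the first-harmonic phasor
coordinates are

$$g = \frac{\sum_k I_k \cos(2\pi h k/N)}{\sum_k I_k}, \qquad
  s = \frac{\sum_k I_k \sin(2\pi h k/N)}{\sum_k I_k},$$

with harmonic $h = 1$ by default. Three geometric facts carry the whole
segmentation:

* **Unit-disc containment.** For non-negative spectra, $(g, s)$ is a
  convex combination of points on the unit circle, hence $g^2+s^2 \le 1$.
* **Mixture linearity.** The phasor of a per-channel mixture
  $\alpha A + (1-\alpha) B$ lies on the segment between the phasors of
  $A$ and $B$, weighted by their total (DC) intensities.
* **Scale invariance.** $I \to cI$ ($c > 0$) leaves $(g, s)$ unchanged,
  so clustering groups pixels by spectral shape, not brightness.

$h = 1$ is the standard phasor convention and gives the widest spread for
single-banded spectra; higher harmonics are exposed as a parameter but
fold the axis and are rarely useful here.

Pixels with total intensity at or below a floor are excluded. The default
floor is `median + 5 * mad` of the DC intensity in the four 8 × 8 image
corners — a robust background estimate that requires no user-marked
region. It errs conservative on fields whose corners contain cells; pass
`dc_floor` explicitly in that case.

### Clustering and component mapping

The default clusterer is a Gaussian mixture on the valid pixels' $(g, s)$,
fitted with a regularizing conjugate prior so that degenerate clusters
(noise-free phantoms collapse each compartment to a single point) do not
produce singular covariances; if the mixture fit fails the implementation
falls back to k-means seeded deterministically from distinct phasor
points. Observation weighting by DC intensity is not applied — DC enters
through the validity floor and through cluster ordering (ids are assigned
in descending total-DC order, so labels are stable across runs). Polygon
gates are supported for parity with interactive phasor tools.

Clusters are given semantic names by proximity of their centroid to the
phasors of user-supplied reference spectra (greedy one-to-one matching),
which removes the manual gate-drawing step; the original workflow's
hand-drawn gates are unrecoverable, so reference-anchored automatic
mapping is this package's documented substitute. A component image is the
DC intensity restricted to one cluster; over valid pixels the component
images partition the DC image.

Whether the original lipid maps used C–H channels only or the full
acquired window is unstated in the source workflow; this package uses the
full acquired window by default (the phasor is computed over all
channels present in the stack).

### Dual-probe unmixing

As the linear counterpart to two-probe phasor segmentation,
`unmix_dual_probe` solves a per-pixel non-negative least-squares problem
against two reference spectra (closed form for two components: the
unconstrained solution is kept when feasible, otherwise each coefficient
is clamped to zero in turn and the lower-residual solution wins). A
residual-norm image is returned for QC. Near-collinear references
(condition number of the Gram matrix above 1e10) are rejected. On
noise-free phantoms the phasor route and the unmixing route agree exactly
on pure-abundance pixels; this equivalence is a test.

## Cell segmentation

Nuclei: Otsu threshold of the nuclei component image, connected
components, distance-transform watershed to split touching nuclei, area
filter (defaults 20 px to infinity). Cells: nucleus-seeded region growing
(`EBImage::propagate`, the same seeded secondary-object algorithm used by
CellProfiler) over the whole-cell foreground; the foreground threshold is
Otsu computed after clipping the image at twice its median positive value,
so that a small, very bright class (lipid droplets at 10× cytoplasm
intensity) cannot drag the threshold above the cytoplasm mode. Nuclei
falling outside the foreground are kept and grown from the seed, with a
warning. Droplets: particles above an intensity floor, watershed-split,
filtered at a minimum diameter of 3 px (droplets are diffraction-limited
puncta at a 60× objective; smaller components are noise), each assigned
to the cell containing its centroid; background-centroid droplets are
dropped and counted. The droplet floor defaults to 0 because phasor
component maps are exactly zero off-support; raw images need an explicit
floor.

Edge-touching cells are excluded from the cell table by default, since
truncated cells bias per-cell intensity histograms.

The original CellProfiler module chain and parameters are unpublished, so
equivalence with it is functional (metrics-level on phantoms with known
truth), not pixel-level.

## Single-cell metrics and subpopulations

Per cell and per component image: integrated intensity (sum over the
cell's signal pixels — the component map masked onto the outlined cell,
not all cell pixels), mean intensity (integrated / signal-pixel count;
defined as 0 with a flag for zero-signal cells, avoiding NaN propagation
into histograms), and signal area fraction. The identity
`integrated = mean × signal pixels` is the documented convention.

Lipid-poor/lipid-rich subpopulation detection fits univariate Gaussian
mixtures on **log** intensity for k = 1…4 and selects k by BIC. The
source histograms never state a selection criterion; BIC is the standard
choice and is recorded in the fit object. On two-component fits the
lower-mean component is "lipid-poor". Classification is scale invariant
(a global intensity factor is a log shift). Group comparisons share one
pooled two-component fit so both groups use the same poor/rich boundary,
and report the rich-fraction difference with a bootstrap percentile CI.

## The metabolic index

$$M = \frac{F}{F + G} \in [0, 1]$$

with $F$ the FA-uptake signal and $G$ the glucose-anabolism signal on the
same per-cell metric. $M$ is strictly increasing in $F$, strictly
decreasing in $G$, and invariant to a common positive scaling — robust to
global imaging-power changes. Cells with $F + G = 0$ have an undefined
index and are excluded with a count (never silently set to 0).

The default per-cell metric is the **signal area fraction**, following the
convention of presenting C–D intensities as area fraction; mean-intensity
and integrated-intensity modes are available since intensity-based
quantification is also standard, and the choice is a function argument.
The per-sample summary is the mean of per-cell indices with
$\mathrm{SEM} = \mathrm{sd}/\sqrt{n}$ (the per-patient averaging
convention), not the index of per-sample mean signals.

## Resistance statistics

**IC50.** The 4PL model is parameterized on $\log_{10}$ dose,
$v = b + (t - b) / (1 + 10^{h(x - x_{50})})$, and fitted by bounded
Levenberg–Marquardt with three starts at the dose quantiles (bounds
$t \in [50, 120]$, $b \in [-10, 50]$, $h \in [0.2, 5]$ percent viability);
bounded multi-start makes convergence deterministic where the original
fitting software is unspecified. Flat viability data is reported as
non-converged rather than fitted. The default IC50 confidence interval is
the asymptotic t-interval on the $\log_{10}$ IC50 parameter; a
case-resampling bootstrap (stratified by dose) is available. The
asymptotic interval was chosen as the default because it has nominal
coverage under the model at plate-assay noise levels (~5% viability SD,
six replicates) and keeps repeated-simulation studies cheap; the test
suite checks ≥ 90% empirical coverage over 500 simulated experiments.

**ROC.** AUC by the rank (Mann–Whitney) formulation with half credit for
ties; the operating threshold maximizes Youden's $J$ and is reported as
the midpoint between adjacent distinct scores (the source analysis states
a threshold but not its selection rule; Youden is the standard choice and
is configurable in principle by consuming the returned curve). The AUC is
invariant under strictly monotone score transforms and equals brute-force
concordant-pair counting, both tested.

**Assay arithmetic.** OCR is the least-squares slope of fluorescence over
time per cell; FAO rate is OCR_total − OCR_etomoxir, with negative values
retained but flagged (biologically impossible, useful QC). ΔCt is
control − target, so higher means more expressed. Tumor volume is
length × width² / 2, swapping (with a warning) when width exceeds length.
Seahorse metrics follow the standard convention: non-mitochondrial
respiration is the post-rotenone/antimycin mean; basal is the last
pre-injection value minus non-mito; ATP-linked subtracts the
post-oligomycin plateau; maximal uses the post-FCCP segment. The group
test is pooled-variance Student's t by default, Welch optional, one- or
two-sided.

## What the synthetic data emulates — and what it does not

The phantom generator renders non-overlapping disc cells with a nucleus,
cytoplasm and droplets, each compartment a fixed linear mixture of
Gaussian-band component spectra. Choices, and their reasons:

* **Gaussian band shape.** No lineshape is stated for the probes;
  Gaussians are analytically simple and adequate for segmentation tests
  (real Raman bands are closer to Voigt profiles).
* **Noise.** Gaussian with sd $= \text{shot\_scale}\sqrt{\text{signal}}$
  plus additive Gaussian — photodetection statistics without a full
  Poisson renderer. Defaults 0.02 and 0.01 against compartment DC
  intensities of order 10–100, i.e. high-SNR imaging of fixed cells.
* **Geometry.** Discs with a radial intensity taper applied to total
  intensity only, so pixel spectral shape (and hence phasor position) is
  unchanged. Defaults: 192 × 192 px fields, 12 cells of radius 12–16 px,
  nucleus at 0.35 of the cell radius, Poisson(3) droplets of radius
  2.5–3.5 px — roughly the per-field cell density of large-area imaging
  scaled down to test size.
* **Population structure.** Two classes, lipid-poor and lipid-rich, at
  50/50 by default, with the rich class's droplet abundance scaled 10×.
  No per-class abundance ratio is reported for real lines; 10× is a
  placeholder that produces unambiguous bimodality, not a fitted value.
* **Cohorts.** Per-cell indices are truncated normal on [0, 1] by
  resampling (preserving the index's domain), defaults mean 0.30
  (sensitive) vs 0.52 (resistant), sd 0.04, 30 cells per sample — group
  means straddling the reported patient threshold region and cell counts
  matching the reported per-patient range.
* **Dose–response.** Exact 4PL plus i.i.d. Gaussian noise, six replicates
  per dose (the plate-assay convention).

Passing tests on phantoms therefore demonstrate algorithmic correctness —
exact recovery where the model is exact, graceful degradation under the
stated noise — but not robustness to everything real tissue adds:
overlapping and non-convex cells, autofluorescence and broadband
background, spectral shifts from chemical environment, stitching
artifacts, 3-D sectioning. Those are out of scope by design.

## Numerical conventions and edge cases

* Coordinates are row-major, 0-based channel-first `(channel, row, col)`,
  origin top-left; all public functions take and return plain matrices,
  converting to EBImage's transposed layout internally.
* TIFF storage is 32-bit fixed point in [0, 1]; stacks are scaled by a
  power of two recorded in the JSON sidecar (`srsmi-stack/1`), making the
  round trip exact to $2^{-31}$ of full scale. Reading refuses to guess a
  missing or mismatched wavenumber calibration. Non-finite pixels are
  flagged, counted in metadata and set to 0 on load.
* Montage layouts floor non-integer overlap pixel counts, so output sizes
  are deterministic: `tile + (tile - overlap) * (grid - 1)` per axis.
  Feathered blending uses complementary linear ramps normalized by the
  accumulated weight; "first-wins" is available for exactness arguments.
  Registration comes from stage positions (the acquisition convention);
  no cross-correlation refinement is applied.
* Mixture-model ties in cluster assignment resolve to the
  maximum-responsibility component, exact ties to the lower id.
* All generators take an explicit integer seed and are bit-reproducible;
  every random path in the package routes through one seeded generator
  per call.
* Test problem sizes: phantoms of 8–12 cells on 160–224 px grids, 500-cell
  intensity populations, 500-dataset coverage studies — sizes at which
  every suite runs in seconds to a couple of minutes on one CPU while
  keeping sampling error well inside the asserted tolerances.

## Known limitations

* Absolute metabolic-flux calibration (µmol-scale units) is out of scope;
  the index is a ratio of imaging metrics.
* Single-label designs are assumed per experiment: no spectral correction
  for C–D signal contributed by both a deuterated FA and glucose-d7 in
  the same window.
* The clustering substitute for manual phasor gating is deterministic but
  not identical to any particular hand-drawn gate set.
* IC50 values from real viability tables depend on unpublished fitting
  choices; only self-consistency and simulation-calibrated coverage are
  claimed here.
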