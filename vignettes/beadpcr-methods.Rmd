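---
title: "Methods: bead-compartment digital PCR analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bead-compartment digital PCR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement principle

Conventional digital PCR distributes a master mix over many compartments of
known volume $V_C$ and estimates the target concentration from the fraction
of PCR-negative compartments via Poisson statistics,

$$C_s = \frac{-\ln(N_{neg}/N)}{V_C}\, D = \frac{\lambda}{V_C}\, D ,$$

so any error in the assumed compartment volume propagates directly into the
concentration. The bead-based format this package analyses works
differently: DNA in a sample of volume $V_S$ is *bound* to a known number
$N_B$ of DNA-binding hydrogel beads, each bead later serving as its own PCR
compartment. Because the targets are distributed over beads by binding
rather than by volume splitting, the concentration follows from the bead
count alone,

$$c_S = \lambda \cdot \frac{N_B}{V_S}, \qquad
  \lambda = -\ln\!\left(\frac{N_{neg}}{N}\right),$$

with no compartment-volume term. `concentration_beads()` and
`concentration_volume()` implement the two estimators; a consistency check
(in the test suite) confirms they coincide exactly when $N_B$ beads of
volume $V_C$ tile the sample volume ($V_S = N_B V_C$, $D = 1$).

Two caveats shape the analysis. With $N_{neg} = 0$ no finite $\lambda$
exists; `poisson_lambda()` flags the well *above range* and reports the
resolvable lower bound $\ln N$ instead of a point estimate. With a
unimodal intensity distribution the well could be all-negative or
all-positive; the package resolves this against a configurable
positive-control intensity and otherwise flags the well indeterminate —
a controls-based decision, as is standard laboratory practice.

# Image analysis

Each well holds a self-assembled monolayer of beads (~95 µm diameter)
imaged in two fluorescence channels: a marker channel in which every bead
fluoresces, and a detection channel in which only amplification-positive
beads are bright. Detection runs on the marker channel — PCR-negative beads
must still be counted — and intensities are then measured inside the same
circles on the detection channel.

**Region detection.** Beads are found as maximally stable extremal regions
(MSER): `detect_regions()` sweeps `n_levels` (default 24) thresholds across
the image's relative intensity range, labels bright connected components at
each level (`EBImage::bwlabel`), and tracks each extremal region across
levels by its seed pixel (the component's brightest pixel). A region is
emitted at the level where its relative area variation across ±`delta`
levels is minimal, subject to area bounds derived from the bead radius
bounds. Thresholds are placed on the image's own intensity range, which
makes detection invariant to positive rescaling and fully deterministic.
Two compactness limits (bounding-box fill ≥ 0.65 and aspect ratio ≤ 1.4)
prevent the stability criterion from preferring regions that have merged
with a neighbour at low thresholds — a single disc fills ~79% of its
bounding box, while merged doublets either fill ~50% (diagonal) or have
aspect ~2 (axis-aligned).

**Circle fitting.** The circle of interest is the one that defines the
outer bead boundary, so `fit_circle()` computes the *minimal enclosing
circle* (Welzl's algorithm on the convex hull) rather than a least-squares
circle, grown by half a pixel so the circle covers the full extent of the
boundary pixels (a lone pixel is a circle of radius 0.5). Coordinates are
0-based with x = column and pixel centres at integers; radii are in pixels,
and micrometre conversion happens only through the configured pixel size.

**Representative intensity.** A uniformly fluorescent sphere projects to
the chord-length profile $I(r) = A\sqrt{1-(r/R)^2} + b$. `representative_
intensity()` estimates the local background $b$ as the median in the
annulus $r \in [1.1R, 1.5R]$ and obtains the amplitude $A$ (peak intensity
above background) by least squares over the interior pixels. On a flat disc
(no spherical profile) this estimator reads high relative to the disc mean;
that bias is documented rather than corrected, since real beads are
spherical.

**Validity filters.** Detections are invalidated, each with a single
primary reason in fixed priority order: radius outside bounds (`size`),
region-to-circle area ratio below threshold (`shape`), centre within the
edge margin (`edge`), or >50% circle overlap with an already accepted
detection (`overlap`; the larger region wins, since doublet artifacts are
rarer than true beads). Default filter values were chosen from bead
geometry and are all exposed in `segmentation_params()`.

# Thresholding

Per-bead detection-channel intensities are classified by first deciding
modality: one- and two-component Gaussian mixtures are fitted by EM
(k-means initialisation, multiple restarts, fixed seed) and compared by
BIC $= p\ln N - 2\ln\hat L$. A two-component win is demoted to unimodal if
either weight is below `min_fraction` (default $5/N$) or the means are
closer than two pooled standard deviations. For bimodal wells the
threshold is the minimum of a Gaussian kernel density estimate (Silverman
bandwidth, 512-point grid) restricted to the interval between the
component means, ties breaking toward lower intensity; a monotone density
falls back to the midpoint of the means with a warning flag. Silverman's
bandwidth and the 512-point grid are conventional defaults; both are
fixed rather than tunable so that thresholds are reproducible.

For wells with only a handful of positive beads the per-well mixture fit
correctly refuses a bimodal call (the weight guard), which would discard
genuinely positive wells near the detection limit. `quantify_well()`
therefore accepts an explicit `threshold`, and the demo pipeline by
default pools all replicates of a dilution level to set one run-level
threshold — mirroring how an instrument run is analysed and reproducing
the partial-detection behaviour of the most dilute level.

# Binding models

The Langmuir isotherm $[\mathrm{DNA}]_b = q_{max}[\mathrm{DNA}]_s /
(K_D + [\mathrm{DNA}]_s)$ describes saturable DNA adsorption with per-bead
capacity $q_{max}$ (ng/bead) and dissociation constant $K_D$ (ng/µL).
Adsorption kinetics follow a finite-bath Langmuir rate law in which both
the free DNA and the free capacity deplete,

$$\frac{db}{dt} = \frac{k_a}{b_{max}}\,(C_0 - b)(b_{max} - b)
\;\Rightarrow\;
b_t = \frac{C_0\, b_{max}\left(1 - e^{-k_a t (C_0-b_{max})/b_{max}}\right)}
           {C_0 - b_{max}\, e^{-k_a t (C_0-b_{max})/b_{max}}},$$

with $b_0 = 0$, monotone approach, and saturation at
$\min(C_0, b_{max})$ — whichever of DNA supply or bead capacity runs out
first — and the logistic limit $b_t = C_0 k_a t/(1+k_a t)$ at
$C_0 = b_{max}$. $k_a$ has units of s⁻¹. At the study's kinetics
conditions (13,900 beads in 100 µL, $C_0 = 50$ ng/µL, $k_a = 0.21$ s⁻¹)
the trajectory reaches >99% of its asymptote well before ten minutes.

Fitting uses Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) with multi-start initial guesses; the optimiser is
an implementation detail — only the optimum matters — and the fits are
verified against a brute-force grid search in the tests. `fit_isotherm()` offers optional $1/b^2$ weights, the
efficient choice when the readout carries constant relative (CV) noise, as
photometric measurements do; unweighted least squares remains the default.
`fit_kinetics()` can fix $b_{max}$ to the isotherm capacity or co-estimate
it; both modes are exposed, with the fixed mode recommended whenever an
isotherm is available, since the capacity is poorly identified from early
time points alone.
95% confidence intervals come from a nonparametric bootstrap over rows
(default 2000 resamples, seeded) or from the asymptotic covariance; the
bootstrap is the default because it makes no distributional assumption,
which matters at six data points.

`capture_fraction()` predicts the fraction of input DNA bound at
equilibrium by solving the mass balance
$f V + N q_{max} f/(K_D + f) = m_{input}$ for the free concentration $f$
with a bracketed root find on $[0, m_{input}/V]$ (relative tolerance
1e-10; the irreversible $K_D = 0$ limit is handled analytically).
Conservation of mass, monotonicity in every argument, and the limits are
all property-tested.

# Method comparison

Concentrations from two methods are compared on the log10 scale. Deming
regression handles error in both variables; with $\delta$ the ratio of
error variances (y over x, default 1 on the log scale — the package has no
information to prefer either method, and the value is configurable), the
closed-form slope is
$\hat\beta = \big(S_{yy} - \delta S_{xx} + \sqrt{(S_{yy} - \delta
S_{xx})^2 + 4\delta S_{xy}^2}\big)/(2S_{xy})$. Confidence intervals use a
leave-one-out jackknife by default; a pairs bootstrap is available. Bland–Altman
agreement reports the mean difference and $\pm 1.96$ SD limits of
agreement of the paired log10 differences. Replicate precision is the SD
of log10 concentrations per dilution level, with zero-result replicates
excluded from the SD and counted separately — exactly the accounting
needed near the detection limit, where only part of the replicates return
a nonzero result. Replicates are aggregated to level means before
regression by default, so each dilution level contributes one point.

# What the synthetic generator emulates — and what it does not

The generator produces every input the pipeline consumes, with ground
truth:

* **Bead populations**: diameters log-normal with mean 94.8 µm and CV
  0.07 (log-normal reproduces a stated mean and CV without allowing
  negative draws).
* **Monolayers**: beads are placed on a jittered hexagonal lattice inside
  a circular well. Physical monolayer self-assembly is near-hexagonal, and
  at the study geometry (≈3,300 beads of 94.8 µm in a 7 mm well, area
  fraction ≈0.6) purely random sequential placement jams below the
  required density, so lattice placement is also the only faithful option.
  Minimum centre distances are guaranteed by construction.
* **Images**: each bead is rendered as a projected uniform sphere (chord
  profile) over a constant background with Gaussian pixel noise, 16-bit
  range, clipped with a warning. PCR-negative and -positive representative
  intensities are Gaussian modes (defaults 2000 ± 600 and 8000 ± 1400,
  ~5–6 pooled SD apart, emulating the clear bimodality of endpoint
  fluorescence in amplified bead monolayers). Optical artifacts are flat,
  small or eccentric elliptical blobs.
* **Assays**: isotherm tables solve the same equilibrium mass balance the
  fitter assumes, at the study's input ladder (10–401 ng/µL, 13,900 beads
  in 100 µL); kinetics tables follow the finite-bath trajectory with
  optional additive noise and an absorbance readout (50 ng/µL per A260
  unit); paired method measurements are log-normal perturbations of the
  truth with an optional constant log10 bias.

Not emulated: optics (PSF, vignetting, autofocus), spectral crosstalk,
emulsion physics, image stitching, pipetting volume errors, and any
systematic binding inhomogeneity. Passing tests therefore demonstrate the
*analysis chain* is correct under the stated statistical model of the
data; they cannot certify performance on real instrument images, whose
noise structure is richer.

# Numerical choices and problem sizes

All randomness flows through explicit integer seeds and generators restore
the caller's RNG state. The mixture EM stops at a relative log-likelihood
change of 1e-8 with an SD floor at 1e-4 of the data SD; k-means restarts
default to 5. Root finds use a relative tolerance of 1e-10 or tighter.
Degenerate inputs are contracts, not crashes: constant images yield zero
regions, all-zero kinetics yield a zero rate flagged degenerate, and
all-zero replicate sets report an undefined SD.

The test suite scales the study down to run on one CPU in minutes, sizes
chosen once as representative: the imaged dilution series uses four
ten-fold levels at 16 wells × 500 beads per level (8,000 beads/level,
340×340 px wells, radius ≈5 px); the bead-count precision check uses nine
wells of ~2,000 beads with per-well Poisson bead-number sampling; mixture
and regression properties use 100–200 seeded repetitions; the full-scale
demo study (5 levels × 12 replicates × 3,300 beads) runs on simulated
per-bead intensities, with image rendering exercised on smaller
configurations. Parameter-recovery checks at 5% relative noise use
relative weights for the isotherm (matching the generator's constant-CV
noise; a Cramér–Rao calculation shows unweighted least squares cannot
reach the same efficiency for $K_D$ at the six-point design).

# Known limitations

* MSER is implemented as a discrete threshold sweep (24 levels); very low
  contrast beads close to the background quantisation can be missed at
  this granularity.
* The minimal enclosing circle of a thresholded region underestimates the
  true bead boundary by a sub-pixel margin that grows for dim beads; the
  half-pixel growth corrects most but not all of it (radius errors stay
  within ~10% at the default geometry).
* The chord-profile intensity estimator assumes uniform internal
  fluorescence; fluorophore localisation at the bead surface would bias
  amplitudes.
* Kinetics and isotherm share $q_{max}$ only through the user's choice of
  `b_max`; no joint fit is provided.
* Per-well thresholds are unreliable below ~5 positive beads by design
  (the weight guard); use run-level thresholds there.
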