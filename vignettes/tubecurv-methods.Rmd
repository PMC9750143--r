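---
title: "Models and methods behind tubecurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tubecurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubecurv)
```

tubecurv quantifies membrane-curvature sensing and induction in two model
systems: optically pulled membrane nanotubes imaged by confocal microscopy,
and sinusoidally buckled bilayer patches sampled by a membrane-bound probe.
This vignette documents the underlying models, the tunable parameters, the
synthetic-data generator that stands in for experimental inputs, and the
numerical and design choices made where the procedures left genuine freedom.

## 1. The nanotube arm

### Image model and segmentation

A confocal equatorial section shows the GUV as a bright ring and the tube as
a dim quasi-1D line. Following standard practice, tube and GUV are analysed
in separate rectangular regions of interest; within each region the
membrane-dye channel is thresholded by Otsu's method and the remaining
pixels of the region provide its background. All reported intensities are
background-subtracted means ("average value" semantics, not medians), which
makes the measurement exactly invariant to adding a constant offset to both
channels, and segmentation is performed on a min–max-normalised region, so
masks are invariant to positive rescaling of the intensities.

Backgrounds are estimated *per region* rather than pooled. The point-spread
function leaks a small fraction of each structure's light into its own
region's background pixels; because that leak is proportional to the
structure's brightness, per-region backgrounds make the leak cancel in the
tube/GUV intensity ratio, whereas a pooled background would couple the
bright GUV's tail into the faint tube measurement and bias the radius
estimate by several percent.

Pixels where the GUV's light bleeds into the tube near the junction are
excluded by trimming tube-mask pixels within 5 PSF standard deviations of
the GUV mask (configurable) — a deliberate choice to keep junction bleed
from inflating the tube signal.

### Sorting ratio, radius, tension and density

The sorting ratio
$S = (I_{prot,tube}/I_{mem,tube})/(I_{prot,GUV}/I_{mem,GUV})$
is a ratio of ratios, so channel gains and — with the per-region background
above — segmentation geometry cancel; in noise-free synthetic frames it is
recovered essentially exactly, and the residual error at realistic noise is
well below a percent.

The fluorescence radius $R = k_{tub}\,(I_{mem,tube}/I_{mem,GUV})$ relies on
the thin-tube limit (tube circumference, and hence membrane area per unit
length, proportional to $R$). The calibration constant $k_{tub}$ comes from
pulls at known radius: aspiration tension
$\sigma = \Delta P\, r_{pip} / (2 (1 - r_{pip}/r_{GUV}))$ — the Laplace
relation across the pipette and vesicle caps — combined with the tether
force balance $R = F/(4\pi\sigma)$, regressed against the intensity ratio.
The regression is fitted *with* an intercept rather than forced through
the origin; the slope is used as $k_{tub}$ and the intercept is reported as
a quality control that should be compatible with zero. Units are fixed at the module boundary: Pa, µm, pN,
N/m, nm, with conversions inside the functions.

Surface density uses three standard-curve slopes: bulk dilution series of
the protein fluorophore and of the dye lipid (their ratio corrects for
optical differences between the fluorophores), and GUV intensity against
dye-lipid surface density at 0.7 nm² per lipid. A `leaflet_factor` of 2
(default) assumes both leaflets fluoresce in an equatorial section; this is
a declared, configurable assumption. Densities are computed per fluorophore
copy and divided by `copies_per_complex` (2 for a dimer labelled once per
protomer) when complexes are the unit of interest.

### Time-course analysis

Curvature induction appears as a negative slope of tube protein density
against tube radius over a time course. "Initial" and "final" values are
means over head/tail windows (default 3 frames — a compromise between noise
averaging and endpoint fidelity; the acceptance script uses a window of 1
when the quantity of interest is the ramp endpoint itself). Degenerate
series are flagged rather than silently propagated: a constant series is
`flat`, a density ramp at constant radius is `infinite_slope`.

## 2. The synthetic imaging generator

The generator renders the study conditions rather than arbitrary images:
GUV radius 8 µm, pixel size 100 nm, PSF sigma 120 nm, 16-bit counts,
Poisson noise at gain 1, a 0.3 mol% dye lipid at 0.7 nm² per lipid, and
tube radii in the 10–150 nm range of tether experiments. The GUV is drawn
as its equatorial ring and the tube as a line whose membrane-channel
brightness is proportional to its radius, i.e. the intensity ratio encodes
$R/k_{tub}$ by construction; the protein channel is the membrane channel
scaled by the label stoichiometry and, on the tube, by the imposed sorting
ratio. Ridges are rendered analytically as Gaussian transverse profiles
(the exact PSF convolution of an ideal line) rather than by discrete
convolution; with `psf_sigma = 0` structures become single-pixel lines and
the measurement chain recovers the imposed ratio exactly, which the tests
use as the noiseless identity case.

Two rendering details matter for fidelity. The GUV centre is placed off the
pixel grid and the tube is tilted by 2% — a pixel-aligned tube would be
sampled at one special sub-pixel phase of its transverse profile and bias
the measured mean by several percent relative to the rim arc, which
averages over all phases. And the calibration generator renders and
measures its GUV standards through the package's own segmentation pipeline,
so the optical geometry factor cancels between calibration and measurement
exactly as it does in a real calibrated experiment.

What the generator does *not* emulate: shot-noise correlations, flat-field
and bleaching effects, defocus, membrane fluctuations, protein-binding
kinetics (time courses follow prescribed schedules, not kinetics), or
polarisation effects of the dye. Passing tests therefore validate the
measurement chain, not robustness to those artefacts.

## 3. The buckled-membrane arm

### Height field and shape operator

Headgroup positions are fitted by linear least squares with the periodic
basis $\{1, \cos, \sin\}(2\pi m x/L_x) \otimes \{1, \cos, \sin\}(2\pi n
y/L_y)$ up to orders $(N_x, N_y)$. The truncation is a free parameter;
the default is $(6, 2)$ — resolving six harmonics along the buckle and two
across it — and the nested-model property (residual RMS never increases with order) is
tested, so convergence can be checked by refitting at higher orders. For
the dominant sinusoidal mode the basis contains the truth, and fits to
exact sinusoids reproduce heights and crest curvature to machine
precision; with thermal height jitter (0.3 nm) the height-field error is
jitter-limited at $\approx \sigma_{jit}\sqrt{n_{basis}/n_{points}}$.

Mean curvature is half the trace of the shape operator of the fitted Monge
patch, from analytic derivatives of the Fourier series, and is
cross-checked against a finite-difference shape operator in the tests. The
surface is assumed single-valued in $z$ (valid for the sine buckle;
overhangs are out of scope). **Sign convention:** $H > 0$ where the
membrane is convex toward $+z$, the side the probe binds, so a buckle crest
carries $H = +2\pi^2 A/L_x^2$. With this convention "preference for
positive curvature" maps to a positive mean of the probe's sampled $H$.

### Curvature preference and insertion depth

Per retained frame, $H$ is evaluated at the probe's in-plane position and
at `n_random` randomly drawn phosphate positions of the same frame —
per-frame drawing, so probe and null share each frame's fit and the
comparison is paired. Frames before the equilibration cut are
excluded (the probe has not yet reached its preferred regions); the
generator marks its first 10% of frames pre-equilibration, mirroring a
5 µs gate on 50 µs replicates, and samples the probe uniformly there.
Sampling defaults to every stored frame at the 10 ns frame interval.

The binding leaflet is assigned *locally*: the leaflet whose mean phosphate
height within an in-plane neighbourhood of the probe is nearer the probe's
height. A global leaflet mean would misassign on strong buckles, where the
surface height varies by more than the bilayer thickness.

Insertion depth is the probe height minus the local phosphate level (mean
over binding-leaflet phosphates within `radius`, default 1.5 nm, periodic
in-plane distances), expressed as a percentage of the monolayer thickness;
negative values mean insertion below the phosphates. On curved patches the
local level estimate carries a small curvature-coupled bias of order
$\nabla^2 h \cdot r^2/8$ (≈0.02 nm at the default geometry); it averages
out for an unbiased probe and is documented rather than corrected.

### The buckle generator

Defaults reproduce the coarse-grained study conditions: box
63 × 28 × 38 nm, buckle amplitude 6 nm (crest curvature
$2\pi^2 A/L_x^2 \approx 0.030$ nm⁻¹, matching the curvature scale the
probe samples), 5040 lipids at 0.7 nm² per lipid in two leaflets offset by
a 2 nm monolayer thickness, 0.3 nm height jitter, 10 ns frames. The probe's
curvature preference is imposed as an exponential tilt
$p(x) \propto e^{\beta H(x)}$ with $\beta = 100$ nm — the simplest
monotone one-parameter bias. The tilt is a generative convenience (real
helices sense curvature through packing defects, which the coarse bead
model does not resolve), with the default chosen to place the probe's mean sampled $H$ near the observed
0.02–0.03 nm⁻¹ scale. Probe positions are drawn by rejection sampling, so
the marginal follows the tilt exactly (verified by a χ² goodness-of-fit
test at $n = 10^4$). Trajectory lengths in the tests and acceptance script
are scaled to hundreds to ~1100 frames with 1600–5040 lipids — sizes chosen
so the whole suite runs in well under a minute per stage while keeping
per-frame fits overdetermined by an order of magnitude.

## 4. Pipelines and reproducibility

`pipeline_config()` collects paths, constants and the seed; it round-trips
losslessly through YAML, and every output row carries an 8-character hash
of the analysis parameters (paths excluded, so relocating output does not
change the hash). The high/low surface-density grouping of the sorting
pipeline is a configurable threshold (`density_split`, default 250 µm⁻²),
since any fixed cut between the regimes is arbitrary. Sorting-versus-curvature fits are unweighted ordinary least
squares with $r^2$ reported. Same config + same seed gives byte-identical
result tables.

## 5. Known limitations

* The thin-tube intensity model ignores polarisation and any dependence of
  dye brightness on curvature.
* No flat-field, bleaching or drift correction is applied.
* The Monge-gauge surface cannot represent overhangs or vesicles; only
  buckles that are single-valued in $z$ are supported.
* Saturated frames are flagged, not corrected; sorting ratios near
  instrument saturation will be compressed.
* The sorting-density relationship (saturation of sorting at high surface
  density) is left to the data; no thermodynamic sorting model is fitted.
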