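---
title: "Optode-bead chemical imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optode-bead chemical imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obci)
```

## The measurement problem

Colorimetric optode microbeads immobilized in a thin hydrogel above a surface
report the local pH through their reflectance color. Because the beads are
sparse (tens of micrometres apart) and micrometre-sized, they sample the
concentration field without perturbing it, and a camera captures the entire
region of interest in a single exposure. `obci` turns time series of such
images into continuous, time-resolved pH maps and tracks how far an iso-pH
front has travelled from a pore source. A diffusion–titration simulator and a
synthetic image renderer close the loop, so every stage of the pipeline can
be validated against a known ground truth without laboratory data.

## Color representation

A camera pixel carries three reflectance intensities $(R, G, B)$. Only their
ratios encode chemistry; the overall brightness depends on illumination.
Every color in the pipeline is therefore Pythagorean-normalized,

$$X_{Pn} = \frac{X}{\sqrt{R^2 + G^2 + B^2}}, \qquad X \in \{R, G, B\},$$

which maps each color to a unit vector on the positive octant of the sphere.
The normalization is invariant to scaling all channels by a common factor,
idempotent, and leaves two independent color degrees of freedom. Sum
normalization ($X/(R+G+B)$) is provided for comparison but is not used by the
pipeline: it does not produce unit-length vectors, so vector analysis on it
is less convenient. Channel ratios (e.g. $R_{Pn}/B_{Pn}$) are available as an
alternative single-variable response; note they are not confined to $[0,1]$.

## Calibration

Calibration points are mean bead colors at known pH (the protocol exposes the
membrane to buffers from pH 5.0 to 8.0 in 0.5 steps, in both titration
directions). The default channel model is a monotone, shape-preserving
piecewise-cubic interpolant (Fritsch–Carlson, `stats::splinefun(method =
"monoH.FC")`): it reproduces every calibration point exactly and guarantees
the strict monotonicity that inversion requires, without committing to an
optode response theory. A 4-parameter logistic fit (`method = "logistic"`) is
available when a smoother parametric model is preferred; on responses that
are truly sigmoidal it is the more accurate interpolant between knots (the
test suite measures ~0.0027 pH worst-case round-trip error for the logistic
fit against ~0.025 pH for the spline on the renderer's logistic forward
model).

Inversion (color to pH) root-finds on the strictly monotone inversion
channel — normalized red by default, since red is the most pH-sensitive
channel, with `r/b` available by configuration. Observations outside the
calibrated color span are clamped to the nearest endpoint and flagged rather
than rejected: a saturated optode still reports its rail. Repeated-pH points
from the two calibration directions are pooled, and their mean absolute gap
on the inversion channel is reported as a hysteresis diagnostic (the
calibration data themselves do not quantify hysteresis, so it is surfaced
rather than modeled). The near-flat green channel is not used for inversion;
its frame-to-frame mean is exposed as a drift QC statistic.

The pH resolution estimate is first-order error propagation,
$\delta\mathrm{pH} = \sigma_{color} / |dX_{Pn}/d\mathrm{pH}|$, which is
minimized where the response is steepest (near pH 6.5 for this chemistry).
The color noise level is a parameter: the achievable resolution depends on
the camera and averaging, so the package does not hard-code a value.

## Bead detection

Beads are strongly colored (blue through orange) on a near-white substrate.
Each pixel is scored by chroma ($\max(R,G,B)-\min(R,G,B)$) plus darkness
($255-\min$), and the mask threshold is chosen by Otsu's method on that
score (a fixed manual threshold can be configured). The pure-chroma score
variant is exactly invariant to global intensity rescaling. Sampling is
pixel-level: every masked pixel contributes one normalized color sample, as
the interpolation stage uses bead data, not per-bead centroids (an optional
connected-component centroid mode exists). Beads are immobilized, so one
consensus mask (pixels present in at least half the frames) is applied to
all frames of a run; frames whose mask disagrees with the consensus (Jaccard
< 0.8) are flagged as possible movement or focus loss.

Positions follow a 0-based `(row, col)` convention with the origin at the
top-left; physical coordinates are pixel indices times the configured
micrometres per pixel.

## Field reconstruction

The pipeline per frame is: Delaunay-triangulate the bead samples and
piecewise-linearly interpolate each color channel onto the pixel grid
(pixels outside the convex hull are marked invalid, never extrapolated);
ring-average each channel around the source; re-normalize each pixel's
recomposed color back to unit norm; then linearly interpolate the channel
fields in time (10 s output from 30 s acquisitions by default) and convert to
pH through the calibration. Averaging happens in color space because rings
average *color*; a pH-space ordering is available for sensitivity analysis.
The re-normalization adjustment is logged as QC — its median is small (a few
thousandths) on rendered fixtures, and large values indicate strongly
disagreeing neighbor beads.

Ring averaging enforces the circular symmetry of transport around the pore:
pixels are binned into concentric annuli `floor(r / width)` of 5 px width by
default, and each annulus receives the pixel-weighted mean of itself and its
immediate inner and outer neighbors — a 5-pixel ring carrying 15 pixels of
radial information. Annuli run from the source to the image corners; an
annulus whose window is empty inherits the nearest valid annulus value and
is flagged. With a window of one annulus the operation is a projection and
exactly idempotent; the default 3-annulus window adds further radial
smoothing on each application, so idempotence holds for the binning, not the
smoothing.

Delaunay triangulation and barycentric interpolation are delegated to the
`interp` package (the same piecewise-linear scheme as Matlab's `griddata`);
the test suite checks it against an independently coded barycentric oracle
built on `deldir` and against the exact reconstruction of affine fields.

## Front tracking

The front is defined on the annulus-averaged radial pH profile, not on 2-D
contours, matching the circular-symmetry processing; the default target is
pH 6.5, the grayish-green intermediate color, which is slightly displaced
from true neutrality but tracks the propagation dynamics. The radius is the
linear interpolation between the two adjacent annuli bracketing the target,
scanning outward. When over-titration produces several bracketing pairs, the
outermost crossing on the monotone run attached to the source is used and
the multiplicity is flagged (`quality = 1/n_crossings`); plateaus behind the
front can produce spurious brackets but not genuine re-crossings in this
regime. Frames without a crossing are recorded as missing, not errors.
Traces are smoothed with a centered moving average over six consecutive
measurements by default; each smoothed point is placed at the mean time of
its window so linear traces pass through unchanged. We read "six consecutive
measurements" as consecutive frames rather than six replicate experiments —
the other reading cannot be exercised on a single run.

## The diffusion–titration simulator

Acid/base propagation is not single-species diffusion: H⁺ and OH⁻ are
dissociation products of the medium itself, the water ion product must hold
everywhere at all times, and the local buffer capacity sets how much acid or
base a volume element absorbs while its pH shifts. The simulator embodies
exactly this picture on a 1-D radial grid, in two geometries: quasi-2D
lateral (thin gap; annular volume increments $\propto r$) and 3D
hemispherical (shell increments $\propto r^2$). It is a ground-truth fixture
generator embodying the stated physics — diffusion plus local titration under
the water ion product — not a claim of quantitative reproduction of any
particular experiment, for which the exact buffer compositions would be
needed.

Each step operator-splits: (i) every species — H⁺, OH⁻, and a single
effective monoprotic buffer HA/A⁻ — diffuses with its own coefficient
($D_{H^+} = 9.31\times10^{-5}$, $D_{OH^-} = 5.27\times10^{-5}$,
$D_{buffer} = 8\times10^{-6}\ \mathrm{cm^2/s}$) through a finite-volume
central-difference stencil whose face weights are $r$ or $r^2$, so the
titrated-volume-increment argument distinguishing the two geometries is
structurally encoded; (ii) every node is re-equilibrated by solving

$$[H^+] - K_w/[H^+] + B_{tot}\frac{[H^+]}{[H^+]+K_a} = P$$

for the conserved proton excess $P = [H^+]-[OH^-]+[HA]$ and total buffer
$B_{tot}$, with a vectorized safeguarded Newton iteration (the left side is
strictly increasing in $[H^+]$, so the root is unique; residuals are driven
below $10^{-12}$ mol/L, with a bisection fallback). Electroneutrality
coupling (ambipolar diffusion) is neglected: the 0.138 M NaCl supporting
electrolyte screens migration in these media. The buffer is a single
effective acid with pKa 7.2, the dominant phosphate pK near the working
range; multi-pK phosphate is out of scope. The thin-gap height enters only
as a constant factor in the 2D finite-volume weights and cancels; it is kept
in the configuration for documentation.

Numerical choices: uniform radial grid with cell centers at $R+(i-\frac12)\Delta r$;
explicit time stepping with the bound $\Delta t \le 0.4\,\Delta r^2/\max D$
enforced at configuration time (the automatic choice is half that, which
also keeps the half-width boundary cells stable) and $\Delta t$ shrunk so
output times land exactly on the requested interval; Dirichlet compositions
at the pore rim (source pH, source buffer) and outer boundary (bulk), with
`closed` available for conservation tests and, for the hemispherical
geometry, an `open` condition that sets the ghost value on the far-field
$1/r$ decay. The open boundary exists because a zero-Dirichlet outer rim
makes the finite-domain steady state $c_0 R (L-r)/(r(L-R))$, which is ~50%
below the unbounded-bath hyperbola $c_0 R/r$ at mid-domain — with it, the
tracer-mode hemispherical run reproduces $c_0 R/r$ within ~1% over
$[2R, L/2]$. Negative concentrations abort the run (they indicate a
stability violation); round-off level negatives are clipped.

Two compositions deserve note. The bulk is $10^{-4}$ M buffer adjusted to
pH 4.5 (or the mirrored basic value). The *source*, however, is held at the
composition of the pore plug, which is cast from four-fold-diluted 0.01 M
phosphate buffer — $2.5\times10^{-3}$ M, twenty-five times the bulk
(`source_buffer_total`). This asymmetry matters: with a $10^{-4}$ M source
the simulated lateral front stalls ~90 µm from the pore almost immediately,
while with the plug composition it expands from ~0.5 mm to ~1.1 mm over ten
minutes while decelerating, the behavior seen in the distance-versus-time
measurements. Either way the front stalls one to two orders of magnitude
short of the $100R \approx 10$ mm that the hyperbolic steady state would
predict from the hundredfold hydroxide drop between pH 8.5 and pH 6.5 —
titration, not diffusion distance, sets the range.

One property needs a carefully controlled pair: "titration flattens the
profile". The flatness statistic is the pH range over the middle 60% of the
pore-to-front span divided by the pore-to-bulk pH difference (0 for a step,
0.6 for a linear ramp). In pH units a diffusive tracer profile is already
log-compressed (about 0.6 pH across the middle of the span,
asymptotically), and with the strong plug source the buffered mid-zone slope
(A⁻/HA decaying with distance) is comparable, so the statistic does not
separate the two. The asserted comparison therefore uses the hemispherical
geometry with the *same* $10^{-4}$ M buffer on both sides, where the only
difference between the paired runs is whether titration acts (flatness 0.15
buffered vs 0.23 tracer at matched 600 s); the lateral pair at desk scale is
not separable by this statistic and is not asserted.

The acid-versus-base speed comparison mirrors the entire chemistry
(pH $\to 14-$pH, pKa $\to 14-$pKa, species roles swapped) so that the only
asymmetry left is $D_{H^+} > D_{OH^-}$; the acid front then provably leads,
which is what the simulations show. The lateral-acid fixture preset instead
keeps the actual acid-run settings (source pH 3.5 into bulk 7.5).

## Synthetic imaging

The renderer's forward color model is a 4-parameter logistic per raw RGB
channel between a blue bead color (70, 90, 200) at the acidic rail and an
orange one (230, 95, 110) at the basic rail, inflected at pH 6.5 with slope
0.7 — a gradual 10–90% response across the pH 5–8 window, steepest at 6.5.
After normalization the red channel swings most, blue distinctly less, and
green varies only a few percent. These numbers are the package's own
reference truth (no tabulated response exists to transcribe) and are kept
separate from fitted calibrations so round-trip tests remain honest.

Bead sites are placed uniformly with a 50 µm minimum spacing; the default of
250 sites on the default 1.4 mm (~2 mm²) ROI yields a mean nearest-neighbor
spacing of ~63 µm, inside the 50–100 µm working range (denser dispersions
improve spatial resolution, which is why the default sits in the lower half
of the range). 15% of sites become aggregates of 2–6 touching disks;
aggregates are data like single beads. Physical beads of 1–3 µm would be
sub-pixel at this scale, so beads render as 2 px disks — a documented scale
compromise; resolution statements are in ring widths, not bead diameters.
The camera model is additive Gaussian noise (2 counts per channel by
default), clipping, then 8-bit quantization; there is no spatial PSF since
rendered beads already span several pixels. Bead response time (seconds) is
treated as instantaneous relative to the 30 s frame interval. A
`quantize = FALSE` mode keeps float radiometry: near the calibration rails
the response slope is shallow enough that 1/255 quantization alone exceeds
the 0.02 pH budget of the noiseless round-trip check, so that check isolates
the color model from the camera.

Fixture presets mirror the four experimental settings (lateral/hemispherical
base, lateral acid, calibration series) and write self-describing
directories (frames, truth TIFFs, bead table, calibration CSV, config,
seed). Truth pH TIFFs are stored as 32-bit samples of pH/14 (the TIFF writer
has no float mode; the quantization is ~3 nV on this scale, i.e. negligible)
with 0 marking invalid pixels.

## What the synthetic tests do and do not show

The generator emulates sparse colored reporters with a known monotone
response, radially symmetric transport, uniform illumination and white
substrate, Gaussian camera noise, and immobile beads. It does not emulate
uneven illumination or spectral drift (the normalization's main target),
bead-to-bead response variability, hydrogel autofluorescence or background
chroma, out-of-focus blur, or real multi-pK phosphate chemistry. Passing the
end-to-end recovery tests therefore demonstrates that the *pipeline* is
correct and numerically well-behaved under the stated imaging model — not
that any particular laboratory accuracy is guaranteed.

Problem sizes were chosen to keep the full test suite and the acceptance
script each within a few minutes on one CPU: 128×128 pixels over ~2 mm² and
20 frames for the end-to-end run, radial grids of 75–100 nodes at 20–25 µm
spacing, and 600–3000 s of simulated time. At 11 µm/px the prescribed
5-pixel rings are 55 µm wide, a substantially coarser radial smoothing than
the same ring recipe applied to a ~1.4 µm/px camera raster; the end-to-end
pH RMSE (~0.145 against clipped truth) is dominated by that smoothing, and
comparisons against truth clip it to the calibrated range [5, 8] because an
optode reports its rails outside its dynamic range.

## Known limitations

- The simulator's buffer is a single effective monoprotic acid; absolute
  front positions and stall radii therefore depend on a composition the
  package has to assume, and only limit behaviors and ordering properties
  are asserted.
- The reconstruction is strictly radially symmetric after ring averaging;
  anisotropic transport would be averaged away by design.
- Interpolation never extrapolates beyond the bead hull, so corners of the
  ROI without beads are reported invalid rather than estimated.
- The 2-D lateral geometry has no unbounded steady state (its resistance
  grows logarithmically), so lateral runs are always transient; the outer
  Dirichlet rim at 2 mm weakly shapes late-time lateral profiles.
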