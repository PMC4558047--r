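# obci — optode-bead chemical imaging of surface pH fields

`obci` reconstructs continuous, time-resolved pH maps of a surface from
reflectance images of sparse colorimetric reporter microbeads immobilized in
a thin hydrogel above the surface, and tracks how far an iso-pH front has
propagated from a pore source. It is aimed at people doing functional
chemical imaging of active surfaces — pores, membranes, secreting cell
layers — where a scanning probe would be too slow or too invasive and a
snapshot of the whole region of interest is wanted at every time point.

Each bead encodes the local pH in its color. Because only color ratios carry
chemistry, every pixel color is Pythagorean-normalized,

    X_Pn = X / sqrt(R² + G² + B²),   X ∈ {R, G, B},

a unit vector on the positive octant of the color sphere, invariant to
illumination intensity. Calibration fits a strictly monotone map from pH to
the normalized red channel (the most sensitive one) and inverts observed
colors by root finding; resolution is estimated by first-order error
propagation, δpH = σ_color / |dX_Pn/dpH|.

The reconstruction pipeline per frame is the classic four-step scheme:

1. **thresholding** — chroma-plus-darkness score, Otsu threshold, one
   consensus bead mask per experiment;
2. **Delaunay triangulation** — per-channel piecewise-linear (barycentric)
   interpolation of the bead colors over the pixel grid, no extrapolation
   beyond the bead hull;
3. **radial ring averaging** — concentric 5-pixel annuli around the source,
   each averaged with its inner and outer neighbor (a 15-pixel radial
   window), enforcing the circular symmetry of transport from a pore;
4. **pixel re-normalization** — recomposed colors projected back to unit
   norm, then converted to pH and linearly interpolated in time (10 s output
   from 30 s acquisitions).

The front tracker reports the radius of the pH 6.5 circle (the
grayish-green intermediate color) over time from the annulus-averaged
profile, with moving-average smoothing over 6 consecutive measurements.

Because pH propagation is *not* single-species diffusion — H⁺ and OH⁻ are
dissociation products of the medium, the water ion product [H⁺][OH⁻] = Kw
must hold everywhere at all times, and local buffer capacity is titrated as
the front passes — the package also ships a radial diffusion–titration
simulator (2D lateral and 3D hemispherical geometries, operator-split
explicit finite volumes with a vectorized Newton equilibration at every
node) and a synthetic bead-image renderer. Together they close the loop:
simulate → render → detect → interpolate → ring-average → calibrate → track,
all against known ground truth. The analytic anchors: at hemispherical
steady state c(r) ≈ c0·R/r, so the hundredfold hydroxide drop from pH 8.5
to 6.5 puts the front at r_st = 100·R (10 mm for a 0.1 mm pore) — while
the simulated buffered front stalls an order of magnitude short of that,
the signature of titration consuming the propagating base.

## Worked example

A complete synthetic experiment — simulate a lateral base-propagation run
(pH 8.5 source into pH 4.5 bulk, 100 µm pore, 10⁻⁴ M buffer), render a
10-frame bead-image stack on a ~2 mm² ROI, calibrate from a rendered
calibration series, reconstruct and track:

```r
library(obci)
res <- obci_e2e(seed = 7, n_frames = 10)

res$curve
#> obci calibration: 7 points, pH 5.00-8.00, inversion channel 'r' (spline, increasing)
estimate_resolution(res$curve, 6.5, color_noise = 0.01)
#> [1] 0.047
round(res$ph_rmse, 3)
#> [1] 0.164
head(subset(as.data.frame(smooth_trace(res$front, 6)), !is.na(radius_um)))
#>   t_s radius_um smoothed_radius_um
#> 2  20     72.33              317.3
#> 3  25    291.58              354.9
#> 4  35    438.27              387.1
#> 5  45    467.04              469.5
#> 6  55    505.25              519.2
#> 7  65    548.07              548.8
round(res$front_max_offset_px, 2)
#> [1] 1.14
```

Reading those numbers: the calibration curve spans the 7 knots of the pH
5.0–8.0 protocol and inverts through the red channel; at pH 6.5 (the
steepest part of the response) a color noise of 0.01 propagates to ≈0.05 pH
resolution. The reconstructed pH maps match the simulated truth (clipped to
the calibrated range) to 0.16 pH RMSE over this short 10-frame run, and the
traced pH 6.5 front — expanding and decelerating over the first minutes —
stays within about one pixel of the front traced on the true field.

Fixture directories for the four experiment presets (`lateral-base`,
`hemispherical-base`, `lateral-acid`, `calibration-series`) are written by
`make_fixture()`, and a thin command-line wrapper lives at
`inst/cli/obci.R` (`Rscript obci.R e2e --seed 1 --out DIR`, plus
`calibrate`, `reconstruct`, `track`, `simulate`, `render`, `presets`).

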