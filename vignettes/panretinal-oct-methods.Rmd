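---
title: "Models and methods behind panoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panoct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panoct)
```

# The problem

Ultra-wide-field OCT of the infant eye pivots the scan beam about a point
on the iris plane and sweeps well past the equator of the globe. Three
quantitative questions follow directly from that geometry, and this
package exists to answer them reproducibly:

1. **Where does a given scanner angle land on the retina?** Wide-field
   devices quote their field of view in two incompatible conventions —
   the angle swept about the scan pivot, and the angle subtended at the
   centre of the eyeball (the convention of scanning-laser
   ophthalmoscopes). Converting between them, and knowing how deep an
   imaging window must be to contain the curved retina without aliasing,
   requires an explicit eye model.
2. **How long is the eye?** OCT measures optical path length (OPL); axial
   length in millimetres of tissue requires dividing by the average group
   index of the media the beam traversed, and the measurement itself has
   to be assembled from two acquisitions at different reference-arm
   positions because the imaging window is much shorter than the eye.
3. **How big is a tumor on a curved retina?** Transverse sizes read off a
   flat en-face projection understate peripheral lesions; sizes should be
   measured along the fitted spherical surface.

# The spherical-eye scan model

The globe is an ideal sphere of radius $r$ centred at $C$; the pivot $P$
sits on the visual axis a distance $a$ anterior of $C$ ($0 \le a \le r$).
A ray leaving $P$ at half-angle $\alpha$ from the posterior direction
intersects the sphere at chord length

$$L(\alpha) = a\cos\alpha + \sqrt{r^2 - a^2\sin^2\alpha},$$

and strikes the retina at central angle
$\beta/2 = \arccos[(L\cos\alpha - a)/r]$ from the posterior pole. Both
follow from elementary ray–sphere intersection; the test suite verifies
them against an independent brute-force solver (quadratic root finding on
the implicit sphere equation) to $10^{-9}$ on a thousand random
configurations. Useful limits: with the pivot at the centre ($a = 0$) the
two angle conventions coincide and the retina renders flat; with the pivot
on the globe ($a = r$) the inscribed-angle theorem gives
$\beta/2 = 2\alpha$ exactly.

Assumptions and their consequences:

- **No refraction.** The pivot is the *post-optics* pivot inside the eye
  and rays travel straight; corneal and lenticular refraction are treated
  as already absorbed into the pivot placement. This mirrors how contact
  wide-field probes are designed (the pivot is set on the iris plane by
  the probe itself) but means the model cannot predict where the pivot
  lands for a given external optic.
- **Ideal sphere.** Real globes are mildly aspheric; the robust sphere fit
  in the morphometry stage (below) absorbs small deviations, but strongly
  staphylomatous eyes would violate the model.
- **Angle-linear scanning.** Galvanometer scanning is uniform in pivot
  angle, so the sample grid is uniform in $(\alpha_{fast},
  \alpha_{slow})$ and the two axes compose as orthogonal rotations about
  $P$: $D = (\sin\alpha_f,\ \cos\alpha_f \sin\alpha_s,\
  -\cos\alpha_f \cos\alpha_s)$.

Default geometry: the sphere radius is half the schematic eye's axial
length (newborn: $r = 8.725$ mm) and the pivot sits on the iris plane,
$a = r - (\mathrm{CT} + \mathrm{ACD}) = 6.125$ mm. At a 140° pivot FOV
this reaches a centre-referenced half-angle of 111.3° and sweeps the
retina through 8.41 mm of optical depth — the reason wide-field imaging
needs long depth windows, and the reason placing the pivot nearer the
centre of the eye (which flattens the scan) trades against iris
vignetting, quantified by `vignetting_limit()`.

# The schematic eye and OPL-to-length conversion

The newborn Gullstrand preset carries five segments (mm / group index):
cornea 0.75/1.377, anterior chamber 1.85/1.336, lens 3.7/1.43, vitreous
11.0/1.334, retina 0.15/1.346. The average index is the thickness-weighted
mean

$$\bar n = \frac{\sum_i n_i d_i}{\sum_i d_i},$$

which evaluates to 1.3565 (printed as 1.357 at the conventional three
decimals), and the conversion is $\mathrm{GL} = \mathrm{OPL}/\bar n$.
Full precision is used internally by default; the rounded 1.357 is what a
user comparing against published biometry would apply, and both routes are
exposed because the difference (about 6 µm on a newborn eye) is below the
depth-pixel scale anyway. The axial length is referenced to the retinal
pigment epithelium (RPE); `total_axial_length(eye, include_retina =
FALSE)` gives the inner-limiting-membrane reference used by ocular
ultrasound, which explains part of the systematic OCT–ultrasound
discrepancy in axial length.

The biometry record combines two acquisitions: with the stage at $P_1$ the
corneal apex appears at in-image depth $d_a$; with the stage at $P_2$ the
foveal RPE appears at $d_f$. Then

$$\mathrm{OPL} = k\,(P_2 - P_1) + (d_f - d_a) + c,$$

where $k$ is the stage-travel-to-OPL factor (1 for a stage calibrated in
optical path, 2 for a double-pass arm; exposed, not guessed) and $c$ a
fixed contact-optics offset defaulting to 0. The pipeline is invariant to
shifting both stage positions by a common offset, which the tests assert
exactly.

# Protocol calculators

All closed forms, pure and dimensionally checked: acquisition time
$N_A N_B / f_{A}$; axial resolution $(2\ln 2/\pi)\,\lambda_0^2/\Delta\lambda$
(Gaussian-spectrum FWHM; at 1060 nm / 70 nm this gives 7.083 µm in air —
quoted hardware figures computed under slightly different spectral
assumptions commonly differ by a fraction of a percent); sampling-limited
depth $\lambda_0^2 N / (4\,\Delta\lambda_{sweep})$, where the *full* sweep
range, not the 6 dB bandwidth, sets the window; Gaussian focal diameter
$4(\lambda_0/n) f / (\pi D)$. A consistency check rejects protocols whose
digitizer cannot sample the spectrum within the active sweep fraction.

# The synthetic-volume generator

No public raw volumes exist for this kind of system, so the package ships
a first-class generator whose output has the statistical structure the
downstream analyses assume. It emulates:

- the spherical retina sampled by the pivot scanner, with the surface of
  each A-scan placed at optical depth $L(\alpha)\,\bar n - z_0$, where
  $z_0$ is the zero-delay optical path set by the reference arm (so stage
  bookkeeping is exact by construction and the biometry pipeline can be
  validated end to end);
- a layer stack riding on the surface. The default stack puts the
  brightest band — standing in for the RPE, the layer all axial
  measurements here reference — at the rendered surface, with a dimmer
  choroid 50 µm below. Bands are rendered as Gaussian axial profiles of
  σ = 3 µm optical (≈7 µm FWHM, matching the system resolution), widened
  to 0.7 of the depth pitch whenever the protocol undersamples the PSF so
  a band can never vanish between depth bins;
- ellipsoidal-cap lesions, elevation $h\sqrt{1 - (2s_1/L)^2 -
  (2s_2/W)^2}$ in geodesic coordinates on the sphere, elevating inward.
  Ground truth is stored as normal (radial) height and geodesic extents;
- fully developed speckle as unit-mean multiplicative exponential noise
  (the standard statistics for coherent imaging), an additive exponential
  noise floor, and exponential sensitivity roll-off in dB/mm (a free
  scene parameter — it varies between instruments and no single value is
  canonical);
- explicit mandatory seeds with a private RNG stream: the global R random
  state is never touched, and identical (scene, protocol, seed) give
  bit-identical volumes.

Rendering the elevated surface is a genuine ray-casting problem: the
surface $|x| = r - e(\hat x)$ must be intersected with each oblique ray.
A fixed-point iteration on the chord length fails to converge at steep cap
edges, so the generator brackets the root between the chords to the
maximally elevated sphere and to the base sphere and bisects (45 steps,
sub-nanometre in $t$). At grazing incidence the rendered cap still differs
subtly from its radial definition (rays clip the near side of elevated
caps); this is a property of real pivot-scanned imaging too, and it is
part of what the morphometry tolerances absorb.

What the generator does **not** emulate — and hence what green tests do
not certify on real data: motion artifacts, eyelash/lid shadows, axial
PSF sidelobes and dispersion, refraction errors in the scan model,
vascular texture, detector saturation. Parameter-recovery results on this
synthetic data are best-case bounds, not clinical accuracy claims.

# Detection and morphometry: numerical choices

- **Sub-pixel depths.** Depth pixel $k$ is centred at $(k-\tfrac12)\cdot$
  pitch. Peaks are localised by log-parabolic interpolation over the peak
  and its two neighbours — exact for a noiseless Gaussian band regardless
  of how coarsely it is sampled. Surface detection uses the brightest
  band; a first-crossing mode (two consecutive samples above threshold,
  so a lone speckle spike cannot trigger) exists for volumes where the
  first surface is not the brightest. The default threshold is 6 dB above
  the noise floor, or 5% of the volume maximum for noiseless scenes;
  the median windows are 5 A-scans (apex trace), 5×5 angular
  (segmentation) and 3×3 when a narrow lesion's apex must be preserved —
  a wide median erodes sharp peaks, so the lesion wrapper re-reads
  heights from a lightly filtered surface.
- **Scan conversion.** $(\alpha_s, \alpha_f, d) \mapsto P + tD$ with
  $t = (d + z_0)/\bar n$; the inverse mapping is closed-form and
  round-trips to machine precision.
- **Sphere fitting.** Algebraic (linearised) least squares seeds a
  Gauss-Newton refinement of the centre with the radius as the weighted
  mean distance; two robust passes zero-weight residuals beyond 3×MAD so
  lesion regions do not bias the globe. Coplanar degeneracy is detected
  via the singular values of the centred cloud.
- **Elevation and detection.** Elevation is the signed radial excess over
  the fitted sphere, positive inward. Footprints are
  elevation-thresholded, labelled 8-connected (union-find), and filtered
  by on-sphere footprint area computed from the local metric of the scan
  grid (cross products of neighbouring projected points).
- **Extents.** Length and width are extents along the principal axes of
  the footprint's area-weighted second-moment ellipse, measured in the
  tangent-plane log map at the footprint centroid (geodesic, i.e. arc
  lengths on the sphere; a chord mode is provided for comparison since
  published tumor tables rarely state which convention they use). Plain
  pixel-centre extents lose about half a grid step per edge, so the
  boundary is refined to sub-pixel by interpolating the threshold
  crossing toward the first outside pixel — tightened by a gradient
  extrapolation from the next pixel inward, because an ellipsoidal cap's
  edge slope is unbounded and plain linear interpolation overshoots; the
  step is additionally clamped to the interior pixel spacing because at
  grazing incidence the first outside ray lands far beyond the cap in its
  shadow zone.
- **Ties and degenerate inputs.** Equal-intensity peaks resolve to the
  first (shallowest) bin; empty volumes and >50% sub-threshold
  segmentations raise errors rather than returning silent garbage;
  length ≥ width is enforced by ordering.

# Problem sizes and test design

The suite builds every fixture in code at run time. Geometry properties
use thousands of random configurations; generator and biometry tests use
narrow-field volumes of roughly 48–128 A-scans per B-scan and 400–600
depth samples; the full-loop morphometry checks use 200×200×1200 volumes
with a 12 mm optical window. That window exceeds the 6 mm air window of
the hardware protocol deliberately: a 140° field sweeps ≈8.4 mm of
optical depth on the newborn globe, and the generator refuses to alias —
scenes that do not fit the window are rendered with a warning and empty
peripheral A-scans. Noiseless end-to-end accuracy achieved under these
conditions: axial length within ~2 µm over 16–24 mm (tolerance: one
depth-pixel geometric equivalent, 5.5 µm); lesion length/width within
~2% (tolerance 5%) and heights within a few µm (tolerance one depth
pixel) for caps centred from the posterior pole out to 100° central
angle. Azimuthal rotation of a scene changes transverse measurements by
up to ~2% at these grid resolutions — discretisation, not geometry: the
scan raster is square in pivot angles, so a rotated lesion is sampled by
a genuinely different pixel pattern.

# Known limitations

Single-index conversion (no per-segment ray tracing through a growing
eye); no refraction or asphericity in the scan model; fovea localisation
in synthetic volumes uses scene metadata (real volumes need the operator
to centre the scan or supply the foveal angle); morphometry assumes
lesions are elevations of the retinal surface (flat or excavated
pathology would need a different detector); the hill-climbing autofocus
assumes a unimodal sharpness metric on the search interval.
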