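---
title: "Geometric cone-beam simulation and FDK reconstruction with coneBeamSim"
author: "coneBeamSim maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric cone-beam simulation and FDK reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coneBeamSim)
```

# Scope and model

`coneBeamSim` simulates X-ray acquisition for cone-beam systems with fully
configurable source and detector positioning, and reconstructs volumes with
FDK-style weighted filtered backprojection.  It is a *geometric* simulator:
rays are straight lines from a point source, the detector is an ideal
integrating grid, and projection values are line integrals of the
attenuation volume.  Source physics (heel effect, polychromatic spectra,
finite focal spot) and detector physics (noise, intensity response,
scatter) are deliberately out of scope; simulated projections are exact
noise-free forward models.

## Coordinate conventions

One set of conventions is used everywhere:

* Array indices are 0-based in formulas; index $k$ on an axis of $n$
  elements with spacing $d$ sits at the centred physical coordinate
  $(k - (n-1)/2)\,d$ mm.  Pixel and voxel coordinates refer to centres.
* The volume axes are $(u, v, z)$.  At view angle $\theta$ the rotated
  frame has lateral axis $u'$ and depth axis $v'$, with
  $U = u'\cos\theta + v'\sin\theta$, $V = -u'\sin\theta + v'\cos\theta$.
  The source sits at $v' = -\mathrm{DSO}$, the detector plane at
  $v' = +\mathrm{DDO}$; $\theta$ increases counter-clockwise viewed from
  $+z$.
* DSO and DDO are the distances from the centre of the field of view to
  the source and to the detector.  All angles are radians inside the
  package; the command-line interface speaks degrees.

A point at lateral position $u'$ and depth $v'$ projects to the detector
coordinate $x = u' \, (\mathrm{DSO}+\mathrm{DDO}) / (\mathrm{DSO}+v')$;
equivalently the sampling position at depth $v$ for a detector coordinate
$x$ is $x \cdot \mathrm{Mag}(v)$ with
$\mathrm{Mag}(v) = (\mathrm{DSO}+v)/(\mathrm{DSO}+\mathrm{DDO})$
(`magnificationAt`).  The same quantity evaluated at a voxel for a given
view is `magnificationBackproj`; the backprojector *divides* the rotated
lateral coordinate by it, which is the only reading under which projection
and backprojection describe the same ray bundle (single-pixel
backprojections land on the analytic source–pixel ray, and the FDK loop
closes — both are tested).

# Detector misalignment model

Deviations from the ideal detector pose are five parameters: in-plane
shifts $x_\mathrm{shift}, y_\mathrm{shift}$ (mm), in-plane skew rotation
$\phi$, and two out-of-plane inclinations — *roll* about the detector's
vertical axis (affecting $x$) and *tilt* about its horizontal axis
(affecting $y$).

**In-plane map.** A coordinate $(x, y)$ on the misaligned detector
corresponds to the ideal-frame coordinate
$R(\phi)\,(x + x_\mathrm{shift},\; y + y_\mathrm{shift})$
(`applyShiftSkew`; shift first, then rotation).

**Inclination map.** For a detector inclined by $\varepsilon$ about the
piercing point, with the source on the central axis at distance
$L = \mathrm{DSO}+\mathrm{DDO}$, the ray aimed at ideal in-plane
coordinate $p$ meets the inclined detector at arc position

$$p' \;=\; \frac{L\,p}{L\cos\varepsilon + p\sin\varepsilon},$$

the exact 2-D ray/line intersection (`applyInclination`), with exact
inverse $p = L p' \cos\varepsilon / (L - p'\sin\varepsilon)$.  It is the
identity at $\varepsilon = 0$, fixes the piercing point, and agrees with
any small-angle expansion of the inclination geometry.  Roll applies this
map along $x$, tilt along $y$ — a separable approximation that is exact
for a single-axis inclination and first-order accurate when roll and tilt
combine.

**Order and inverses.** The projector maps each *real* pixel coordinate to
its ideal-frame equivalent: in-plane map first, then the *inverse*
inclination per axis.  The backprojector applies the exact inverse chain —
forward inclination, then the inverse in-plane map — so that both kernels
describe the same geometry.  (Formulations exist that list the
backprojection steps in a different order; only the exact inverse keeps
single-voxel projections and single-pixel backprojections on the same ray,
which is what the tiny-instance tests pin down.)  All misalignment
branches are skipped when a parameter is exactly zero, so the
zero-misalignment path is arithmetically identical to a separately coded
ideal-geometry kernel — tested as exact equality.

# Forward projection

For every view and detector pixel, the line integral is accumulated as

$$p_\theta(x, y) \;=\; \mathrm{step} \times \frac{1}{\cos\alpha}
\sum_{k=0}^{N_\mathrm{step}-1} f\!\big(U(v_k), V(v_k), z(v_k)\big),
\qquad v_k = -\mathrm{rad} + k\,\mathrm{step},$$

where $\alpha$ is the cone angle of the pixel
(`coneAngle`; $\tan\alpha = \sqrt{x^2+y^2}/L$) and the $1/\cos\alpha$
factor converts the depth-axis sampling into arc length along the oblique
ray.  `rad` bounds the integration to the field of view; sampling covers
$2\,\mathrm{rad}$ with $N_\mathrm{step} = \lfloor 2\,\mathrm{rad} /
\mathrm{step}\rfloor + 1$ samples (the end-inclusive convention; any
consistent convention only perturbs values by one sample of padding zeros
for compactly supported objects).

Defaults (`samplingPolicy`): `step` is the minimum detector pixel size;
`rad` is half the volume's largest in-plane physical diagonal.  For
impulse-like volumes the step should not exceed half the voxel size, or a
footprint narrower than the sampling interval can be stepped over.

* **Ray-driven mode** samples the volume with trilinear interpolation at
  the ray point of each depth sample.  Out-of-volume samples contribute
  zero (line-integral semantics for compactly supported objects).
* **Distance-driven mode** projects the *pixel boundaries* instead of its
  centre: at each depth the two boundary rays delimit an interval on the
  volume axis most orthogonal to the ray direction ($u$ when
  $|\cos\theta| \ge |\sin\theta|$, $v$ otherwise — the classical axis
  selection), and in $z$; the sample value is the overlap-weighted average
  of the voxels between the boundaries, normalised by the interval widths,
  with linear interpolation along the remaining axis.  The weights are a
  partition of unity, so constant volumes project identically in both
  modes (tested within 1%); boundary coincidences produce zero-width
  intervals that fall back to point interpolation, never double counting.

Both modes are linear in the volume, deterministic (fixed ascending
summation order), and are validated against dense system matrices built
by an independent R enumeration on tiny instances ($8^3$ volume, $12^2$
detector, 4 views) to $10^{-5}$ relative.

# Backprojection

The backprojector spreads (optionally filtered) projection values back
along rays:

$$f(u, v, z) \;=\; \sum_\theta \Delta\theta \; W_2(u, v, \theta)\;
p_\theta\!\big(x(u,v), \; y(z)\big),$$

with bilinear interpolation in the projection plane (voxel-driven) or the
overlap-weighted average between the projected voxel boundaries
(distance-driven, same axis-selection construction as the projector).
Rays whose detector intersection misses the physical detector contribute
zero — no clamping, so truncated fields of view behave as truncated.

$\Delta\theta$ defaults to the uniform angular spacing when the view
angles are evenly spaced (detected exactly); otherwise per-view midpoint
weights are used.  Because contributions add per view, backprojecting any
partition of the views and summing is exactly the whole (angular
additivity) — the basis of set partitioning.

Distance-driven backprojection averages over the voxel footprint, which
suppresses the high-frequency Moiré-type patterning that centre-point
interpolation produces; the test suite asserts the energy ordering on a
uniform-disk reconstruction slice.

# FDK reconstruction

`fdkReconstruct` composes

1. cosine pre-weighting $W_1 = D/\sqrt{D^2 + x^2 + y^2}$
   (`cosineWeightMap`) over centred detector coordinates,
2. row-wise ramp filtering (`rampFilter`),
3. backprojection with the distance weight
   $W_2 = \big(\mathrm{DSO}/(\mathrm{DSO}+v')\big)^2$ and $\Delta\theta$,
4. a fixed analytic normalisation $\tfrac12 (\mathrm{DSO}+\mathrm{DDO})
   / \mathrm{DSO}$, which converts filtering on the physical detector to
   the isocentre-plane filtering of the classical derivation ($\tfrac12$
   because a full scan measures every ray twice).

The constant is derived, not calibrated: reconstructing a uniform cylinder
from its own projections yields an interior mean of about 0.99 with no
free parameter (asserted within ±5%).

**Two readings of the weight distances.** Some formulations state $W_1$
with the source–detector distance, some with the source–isocentre
distance (the difference is whether detector coordinates are scaled to
the isocentre plane first).  The default uses the source–detector
distance on physical detector coordinates, which is self-consistent with
step 4; the other reading is available via
`cosineWeightMap(distance = "source-isocenter")`.  For $W_2$ the exported
`distanceWeight(v)` takes $v$ measured from the isocentre *toward the
source* — under that sign convention the printed form
$(\mathrm{DSO}/(\mathrm{DSO}-v))^2$ is the standard
$\mathrm{DSO}^2/U^2$ weight, monotone increasing toward the source.

**Ramp filter.** Rows are zero-padded to the next power of two at least
twice the detector width.  The FFT backend multiplies by the exact
discrete ramp $|f|$ (zero at DC); the spatial backend convolves with the
exact impulse response of that same discrete ramp, so the two agree to
rounding error.  The impulse response approaches the classical
band-limited kernel $h(0) = 1/4$, $h(\pm k_\mathrm{odd}) = -1/(\pi k)^2$,
$h(k_\mathrm{even}) = 0$ (per unit sample spacing) with $O(1/M^2)$
finite-length deviations.  No apodisation window is applied — the filter
is the pure ramp.  Note that zero-padding turns a globally constant row
into a boxcar whose filtered edge tails decay like $1/x^2$; "constant
rows vanish" therefore holds exactly only for the periodic (unpadded)
reading, and to a few parts in $10^3$ in the padded interior.

# Scan configurations

**Circular** (`circularViews`): `nproj` evenly spaced angles over `span`
degrees, end-exclusive, starting at `ini`, with an optional shared
misalignment.

**Helical** (`helicalViews`): circular angles plus a cumulative bed
translation.  View $k$ (0-based) carries a z-shift of
$k \cdot \mathrm{pitch}/(n \cdot \mathrm{thick})$ voxels, where $n$ is
views per rotation and `thick` the slice thickness — the one reading under
which a full rotation advances the bed by exactly one pitch, for any span.
The shift translates the *sampling coordinates*, not the volume, so no
resampling error is introduced; projector and backprojector displace
consistently.

**Arbitrary poses** (`arbitraryToViews`): each source position and
detector pose (centre, normal, in-plane axis) is decomposed into the
deviation from the ideal circular pose at the source's azimuth —
(1) shifts placing the piercing point at the stored coordinate origin,
(2) roll/tilt/skew extracted as $R_y(\mathrm{roll})\,R_x(\mathrm{tilt})\,
R_z(\mathrm{skew})$ Euler angles of the relative rotation.  `viewPose`
renders a view back to a pose; round trips are exact to $10^{-9}$.
Sources are currently restricted to the $z = 0$ plane (the decomposition
target is the circular-scan frame).

**Tomosynthesis** (`tomosynthesisViews`): realised on a static *virtual
detector* wider than the real one, with per-view regions of interest
(ROIs) of real-detector size.  The focal plane sits at depth
$\mathrm{FP}$ mm from the isocentre toward the source.  For the linear
flavor the source moves laterally to $S_x$ (views spaced linearly on
$[-S_{x,\max}, +S_{x,\max}]$), modelled *exactly* as a per-view source
offset in the kernels (a lateral source shift is not expressible as any
detector misalignment); the focal-plane centre then projects to
$-D_x = -S_x(\mathrm{DDO}+\mathrm{FP})/(\mathrm{DSO}-\mathrm{FP})$, and
the ROI is centred there, which is precisely what makes focal-plane
structures stationary in ROI coordinates (the defining property of
tomosynthesis, asserted to half a pixel over a 41-view scan).  For the
arc flavor the source moves on the arc of radius
$\mathrm{DSO}-\mathrm{FP}$ about the focal-plane centre:
$S_x = \sin S_\beta \,(\mathrm{DSO}-\mathrm{FP})$, per-view
$\mathrm{DSO}' = \cos S_\beta\,(\mathrm{DSO}-\mathrm{FP}) + \mathrm{FP}$
(a per-view DSO override), ROI centre $-\tan S_\beta\,
(\mathrm{DDO}+\mathrm{FP})$.  The virtual width is the larger of the
closed-form large-detector size and the exact ROI union; both are
computed and compared.  ROI centres at the focal-plane projection were
chosen over centring at $D_x + S_x$ because only the former satisfies the
stationarity property the configuration exists for.

**Wide field of view** (`wideFovViews`): in tilting mode (a rotating
source covers successive detector positions; for a point source this
changes collimation, not ray geometry) a virtual detector is tiled by $N$
ROIs with a fixed pixel overlap, ROI $n$ centred at
$n D_\mathrm{real} - (n-1)\,\mathrm{Overlap} - D_\mathrm{real}/2$ pixels
from the left edge.  The printed closed-form size
$N(D_\mathrm{real} - (N-1)\mathrm{Overlap})$ undercounts the exact union
$N D_\mathrm{real} - (N-1)\mathrm{Overlap}$ whenever the overlap is
positive; the implementation reports the printed value, warns on the
mismatch, and sizes the virtual detector to the union so that the ROIs
tile it exactly.  Linear-displacement mode steps the volume along $z$
between positions (helical-style), with the step chosen so consecutive
detector footprints overlap by the requested pixels at the isocentre
plane.

# Memory-bounded partitioning

`planPartitions` splits the volume along $z$ into chunks and the views
into sets such that each partition's working array of 8-byte doubles fits
the byte budget, and reports the minimal feasible budget when none does.
`projectPartitioned` accumulates per-chunk projections (line-integral
additivity over depth segments); `backprojectPartitioned` accumulates
per-set backprojections (angular additivity) and computes per-chunk
z-slabs independently.  Summation order is deterministic (ascending
index), single-partition plans are bitwise-identical to monolithic
execution, and arbitrary plans agree to $10^{-5}$ relative (float
summation order is the only difference).  Angular weights always come
from the *full* view set so that set boundaries do not perturb midpoint
weights.

# Synthetic data

All inputs are generated: additive ellipsoid phantoms (voxel-centre
rule), uniform cylinders, and point/bead grids (`makeEllipsoidPhantom`,
`makeCylinderPhantom`, `makePointGrid`).  Phantom generation is
deterministic.  These objects emulate the geometric content of anatomy —
smooth compact structures, sharp interfaces, calibration beads — but none
of the physics of real data: no noise, no spectral effects, no scatter,
no detector blur, no motion.  Passing tests therefore demonstrate the
geometric and numerical correctness of the operators, not robustness to
the degradations of measured projections.

Voxelised phantoms have jagged surfaces, so properties that are exact for
smooth objects (angular symmetry of projections, integration-step
convergence) are asserted on analytically smooth Gaussian test objects,
while voxelisation-facing checks (chord lengths, voxel counts) use the
voxelised phantoms directly.

# Numerical choices and degenerate inputs

* Out-of-volume samples and off-detector rays contribute zero.
* Zero-width overlap intervals (exact boundary coincidence) fall back to
  point interpolation; no double counting.
* Rays parallel to an inclined detector (non-positive intersection
  denominator) are a domain error in `applyInclination`; the kernels skip
  such pixels.
* Voxels at or behind the source plane are skipped in backprojection.
* All kernels are single-threaded and deterministic; repeated runs are
  bitwise identical.
* Impulse-resolution condition: a single voxel's trilinear footprint
  spans two voxel widths, magnified onto the detector.  Test geometries
  for point phantoms keep the detector pitch below that footprint and the
  integration step at half the voxel, so footprints are always sampled.

The tiny-instance oracle tests use an $8^3$ volume with a $12^2$ detector
and 4 views; the reconstruction tests use $48^3$–$64^3$ volumes with
$96^2$–$128^2$ detectors and up to 180 views over 360°, sizes at which the
full pipeline completes in seconds while leaving cone angles and
magnification gradients large enough to be meaningfully exercised.

# Known limitations

* The separable roll/tilt inclination model is first-order accurate for
  combined out-of-plane rotations; large combined inclinations are better
  expressed through `arbitraryToViews` poses.
* FDK is an approximate algorithm away from the mid-plane; cone-angle
  artefacts at large half-angles are a property of the method, not of
  this implementation.
* No short-scan (Parker) weighting: partial spans are backprojected with
  the same $\Delta\theta$ weighting as full scans.
* Arbitrary poses assume sources in the axial plane of the isocentre.
* Projection stitching for wide-FOV scans (blending the overlapped ROIs
  into one image) is left to downstream post-processing.
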