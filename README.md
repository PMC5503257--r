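# coneBeamSim

Geometric simulation of X-ray projection imaging and filtered-backprojection
reconstruction for flexible cone-beam systems, in R.

Researchers designing non-standard X-ray acquisitions — C-arms, digital
tomosynthesis, helical scans, stitched wide-field-of-view protocols — need to
evaluate scanning geometries and reconstruction behaviour before committing
to hardware. `coneBeamSim` provides the building blocks for that kind of
study: configurable forward projection (simulated acquisition),
backprojection, FDK reconstruction, and a configuration layer that turns
high-level scan descriptions into per-view geometry, all exercised on
synthetic digital phantoms with no external data.

## The model

Rays run from a point source at distance DSO from the centre of the field of
view to a flat detector at distance DDO. A projection value is the line
integral of the attenuation volume f along the source–pixel ray, accumulated
by depth sampling:

    p_theta(x, y) = step * (1/cos alpha) * sum_k f(U(v_k), V(v_k), z(v_k))

with alpha the cone angle of the pixel and the sampling positions
demagnified by Mag(v) = (DSO + v) / (DSO + DDO). Deviations of the detector
from its ideal pose are five parameters — shifts (x, y), in-plane skew phi,
and out-of-plane roll and tilt — applied as a shift-then-rotation in the
plane and an exact ray/inclined-plane intersection per axis. Reconstruction
is FDK: cosine pre-weighting W1 = D / sqrt(D^2 + x^2 + y^2), row-wise ramp
filtering (|f| response, zero DC), and backprojection weighted by
W2 = (DSO / (DSO + v'))^2 and the angular step.

Both the projector and backprojector come in two interpolation flavours:
ray-/voxel-driven (centre-point trilinear/bilinear interpolation) and
distance-driven (overlap of projected voxel/pixel boundaries on a shared
axis), the latter trading speed for fewer interpolation artefacts.

Scan configurations: circular (`circularViews`), helical with exact
pitch-per-rotation bed motion (`helicalViews`), arbitrary source/detector
poses decomposed into misalignment parameters (`arbitraryToViews`), linear
and arc tomosynthesis on an enlarged virtual detector whose per-view ROIs
keep focal-plane structures stationary (`tomosynthesisViews`), and
wide-field-of-view tiling (`wideFovViews`). Memory-bounded execution splits
volumes into z-chunks and views into sets (`planPartitions`,
`projectPartitioned`, `backprojectPartitioned`) with results equal to
monolithic runs.

## Worked example

```r
library(coneBeamSim)

## a micro-CT-like bench: 48^3 volume of 1 mm voxels, 96^2 detector
geom <- systemGeometry(dso = 500, ddo = 250, detRows = 96, detCols = 96,
                       detPixel = 1.2, volShape = c(48, 48, 48), voxel = 1)

## two-ellipsoid phantom (values are attenuation in 1/mm)
phantom <- makeEllipsoidPhantom(list(
  ellipsoidSpec(center = c(0, 0, 0), semiAxes = c(16, 13, 12), value = 0.02),
  ellipsoidSpec(center = c(5, 3, 2), semiAxes = c(5, 4, 6),
                rotation = 0.5, value = 0.01)), geom)

## simulate a circular scan with a slightly misaligned detector
views <- circularViews(span = 360, nproj = 120,
                       misalignment = detectorMisalignment(
                         xShift = 0.8, tilt = 1 * pi / 180),
                       geometry = geom)
stack <- projectVolume(phantom, views)
stack
#> ProjectionStack 120 views of 96 x 96 px (1.2 x 1.2 mm), range [0, 0.7358]

## FDK reconstruction
recon <- fdkReconstruct(stack)
cor(as.vector(volumeData(recon)), as.vector(volumeData(phantom)))
#> [1] 0.9913
mean(volumeData(recon)[volumeData(phantom) >= 0.02])
#> [1] 0.0196   # true value 0.02
```

The peak projection value (0.736) is the longest chord through the phantom
times its attenuation (about 37 mm of material at 0.02/mm), and the
reconstruction recovers the interior attenuation to 2% with r = 0.99 —
the misaligned detector is handled by the same kernels as the ideal one.

A command-line front end wrapping the same functions lives at
`inst/cli/conebeam.R` (subcommands `phantom`, `project`, `backproject`,
`reconstruct`, `plan`; run any of them with `--help`).

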