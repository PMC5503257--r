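#' @import methods
NULL

#' Scanner system geometry
#'
#' Describes a cone-beam acquisition geometry: the distances from the centre
#' of the field of view to the X-ray source (\code{dso}) and to the detector
#' (\code{ddo}), the detector matrix and pixel size, and the reconstruction
#' volume matrix and voxel size.  All lengths are millimetres.
#'
#' @slot dso numeric(1), centre-of-FOV to source distance (mm), > 0.
#' @slot ddo numeric(1), centre-of-FOV to detector distance (mm), >= 0.
#' @slot detRows,detCols integer(1), detector matrix (pixels).
#' @slot detPixel numeric(2), detector pixel size (x, y) in mm.
#' @slot volShape integer(3), volume matrix (nu, nv, nz) in voxels.
#' @slot voxel numeric(3), voxel size (u, v, z) in mm.
#' @export
setClass("SystemGeometry",
  representation(dso = "numeric", ddo = "numeric",
                 detRows = "integer", detCols = "integer",
                 detPixel = "numeric", volShape = "integer",
                 voxel = "numeric"))

setValidity("SystemGeometry", function(object) {
  msg <- NULL
  if (length(object@dso) != 1L || !is.finite(object@dso) || object@dso <= 0)
    msg <- c(msg, "'dso' must be a single positive finite number")
  if (length(object@ddo) != 1L || !is.finite(object@ddo) || object@ddo < 0)
    msg <- c(msg, "'ddo' must be a single non-negative finite number")
  if (object@detRows < 1L || object@detCols < 1L)
    msg <- c(msg, "detector matrix must have at least one pixel per axis")
  if (length(object@detPixel) != 2L || any(object@detPixel <= 0))
    msg <- c(msg, "'detPixel' must be two positive sizes (mm)")
  if (length(object@volShape) != 3L || any(object@volShape < 1L))
    msg <- c(msg, "'volShape' must be three counts >= 1")
  if (length(object@voxel) != 3L || any(object@voxel <= 0))
    msg <- c(msg, "'voxel' must be three positive sizes (mm)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SystemGeometry
#'
#' @param dso,ddo source and detector distances from the centre of the FOV
#'   (mm).
#' @param detRows,detCols detector matrix size in pixels.
#' @param detPixel detector pixel size, length-2 (x, y) mm (scalar recycled).
#' @param volShape volume matrix, length-3 (nu, nv, nz) voxels.
#' @param voxel voxel size, length-3 (u, v, z) mm (scalar recycled).
#' @return A \linkS4class{SystemGeometry} object.
#' @examples
#' systemGeometry(dso = 500, ddo = 250, detRows = 64, detCols = 64,
#'                detPixel = 1.2, volShape = c(32, 32, 32), voxel = 1)
#' @export
systemGeometry <- function(dso, ddo, detRows, detCols, detPixel,
                           volShape, voxel) {
  if (length(detPixel) == 1L) detPixel <- rep(detPixel, 2L)
  if (length(voxel) == 1L) voxel <- rep(voxel, 3L)
  new("SystemGeometry", dso = as.numeric(dso), ddo = as.numeric(ddo),
      detRows = as.integer(detRows), detCols = as.integer(detCols),
      detPixel = as.numeric(detPixel), volShape = as.integer(volShape),
      voxel = as.numeric(voxel))
}

#' Detector misalignment
#'
#' Deviation of the detector from its ideal pose: in-plane shifts (mm),
#' in-plane skew rotation, and out-of-plane inclinations.  Roll inclines the
#' detector about its vertical axis (affecting the x coordinate), tilt about
#' its horizontal axis (affecting y).  Angles are radians; the all-zero
#' object is the ideal detector.
#'
#' @slot xShift,yShift numeric(1) mm.
#' @slot skew,roll,tilt numeric(1) radians.
#' @export
setClass("DetectorMisalignment",
  representation(xShift = "numeric", yShift = "numeric", skew = "numeric",
                 roll = "numeric", tilt = "numeric"),
  prototype(xShift = 0, yShift = 0, skew = 0, roll = 0, tilt = 0))

setValidity("DetectorMisalignment", function(object) {
  vals <- c(object@xShift, object@yShift, object@skew, object@roll,
            object@tilt)
  if (length(vals) != 5L || any(!is.finite(vals)))
    "all misalignment parameters must be single finite numbers"
  else TRUE
})

#' @rdname DetectorMisalignment-class
#' @param xShift,yShift detector shifts (mm).
#' @param skew,roll,tilt detector rotations (radians).
#' @return A \linkS4class{DetectorMisalignment}.
#' @export
detectorMisalignment <- function(xShift = 0, yShift = 0, skew = 0,
                                 roll = 0, tilt = 0) {
  new("DetectorMisalignment", xShift = as.numeric(xShift),
      yShift = as.numeric(yShift), skew = as.numeric(skew),
      roll = as.numeric(roll), tilt = as.numeric(tilt))
}

#' A single view of an acquisition
#'
#' One source/detector position: gantry angle \code{theta}, detector
#' misalignment, optional bed translation \code{zShift} (voxels, for helical
#' and wide-FOV scans), optional per-view DSO/DDO overrides (arc
#' tomosynthesis), a lateral source displacement \code{sourceX} (mm, linear
#' and arc tomosynthesis), and an optional virtual-detector ROI centre.
#'
#' @slot theta numeric(1) radians.
#' @slot misalignment a \linkS4class{DetectorMisalignment}.
#' @slot zShift numeric(1), bed translation in voxels.
#' @slot dsoOverride,ddoOverride numeric(1) mm or NA.
#' @slot sourceX numeric(1) mm, lateral source displacement.
#' @slot roiCenterX numeric(1) mm on the virtual detector, or NA.
#' @export
setClass("View",
  representation(theta = "numeric", misalignment = "DetectorMisalignment",
                 zShift = "numeric", dsoOverride = "numeric",
                 ddoOverride = "numeric", sourceX = "numeric",
                 roiCenterX = "numeric"),
  prototype(theta = 0, zShift = 0, dsoOverride = NA_real_,
            ddoOverride = NA_real_, sourceX = 0, roiCenterX = NA_real_))

setValidity("View", function(object) {
  if (!is.finite(object@theta)) return("'theta' must be finite")
  if (!is.finite(object@zShift)) return("'zShift' must be finite")
  TRUE
})

#' @rdname View-class
#' @param theta view angle (radians).
#' @param misalignment a \linkS4class{DetectorMisalignment}.
#' @param zShift bed translation in voxels.
#' @param dsoOverride,ddoOverride per-view distance overrides (mm) or NA.
#' @param sourceX lateral source displacement (mm).
#' @param roiCenterX virtual-detector ROI centre (mm) or NA.
#' @return A \linkS4class{View}.
#' @export
view <- function(theta = 0, misalignment = detectorMisalignment(),
                 zShift = 0, dsoOverride = NA_real_, ddoOverride = NA_real_,
                 sourceX = 0, roiCenterX = NA_real_) {
  new("View", theta = as.numeric(theta), misalignment = misalignment,
      zShift = as.numeric(zShift), dsoOverride = as.numeric(dsoOverride),
      ddoOverride = as.numeric(ddoOverride), sourceX = as.numeric(sourceX),
      roiCenterX = as.numeric(roiCenterX))
}

#' An ordered set of views sharing one system geometry
#'
#' @slot views list of \linkS4class{View}.
#' @slot geometry the shared \linkS4class{SystemGeometry}.
#' @export
setClass("ViewSet",
  representation(views = "list", geometry = "SystemGeometry"))

setValidity("ViewSet", function(object) {
  if (length(object@views) < 1L) return("a ViewSet must contain views")
  ok <- vapply(object@views, is, logical(1), class2 = "View")
  if (!all(ok)) return("'views' must all be View objects")
  TRUE
})

#' @rdname ViewSet-class
#' @param views list of \linkS4class{View} objects.
#' @param geometry a \linkS4class{SystemGeometry}.
#' @return A \linkS4class{ViewSet}.
#' @export
viewSet <- function(views, geometry) {
  new("ViewSet", views = views, geometry = geometry)
}

#' A voxelized 3D scalar field
#'
#' Data are stored (u, v, z) column-major with the physical origin at the
#' array centre: voxel index k (0-based) on an axis of n voxels with spacing
#' d sits at (k - (n-1)/2) * d mm.
#'
#' @slot data 3D numeric array (nu, nv, nz).
#' @slot voxel numeric(3) voxel size (mm).
#' @export
setClass("Volume", representation(data = "array", voxel = "numeric"))

setValidity("Volume", function(object) {
  if (length(dim(object@data)) != 3L) return("'data' must be a 3D array")
  if (length(object@voxel) != 3L || any(object@voxel <= 0))
    return("'voxel' must be three positive sizes")
  if (any(!is.finite(object@data))) return("volume values must be finite")
  TRUE
})

#' @rdname Volume-class
#' @param data 3D numeric array (u, v, z).
#' @param voxel voxel sizes (mm), scalar recycled to length 3.
#' @return A \linkS4class{Volume}.
#' @export
volume <- function(data, voxel) {
  if (length(voxel) == 1L) voxel <- rep(voxel, 3L)
  new("Volume", data = data, voxel = as.numeric(voxel))
}

#' A stack of projection images with per-view geometry provenance
#'
#' Data are stored (detector row y, detector column x, view).
#'
#' @slot data 3D numeric array (rows, cols, views).
#' @slot pixel numeric(2) pixel size (x, y) mm.
#' @slot views the \linkS4class{ViewSet} that produced (or describes) the
#'   stack.
#' @export
setClass("ProjectionStack",
  representation(data = "array", pixel = "numeric", views = "ViewSet"))

setValidity("ProjectionStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("'data' must be a 3D array (rows, cols, views)")
  if (d[3] != length(object@views@views))
    return("view count of 'data' must match the ViewSet")
  if (length(object@pixel) != 2L || any(object@pixel <= 0))
    return("'pixel' must be two positive sizes")
  if (any(!is.finite(object@data)))
    return("projection values must be finite")
  TRUE
})

#' @rdname ProjectionStack-class
#' @param data 3D numeric array (rows, cols, views).
#' @param pixel pixel sizes (mm), scalar recycled.
#' @param views a \linkS4class{ViewSet}.
#' @return A \linkS4class{ProjectionStack}.
#' @export
projectionStack <- function(data, pixel, views) {
  if (length(pixel) == 1L) pixel <- rep(pixel, 2L)
  new("ProjectionStack", data = data, pixel = as.numeric(pixel),
      views = views)
}

#' Sampling policy for forward projection
#'
#' @slot step integration step along the depth axis (mm).
#' @slot rad maximum FOV radius covered by the integral (mm); sampling covers
#'   2 * rad.
#' @slot mode "ray_driven" or "distance_driven".
#' @export
setClass("SamplingPolicy",
  representation(step = "numeric", rad = "numeric", mode = "character"))

setValidity("SamplingPolicy", function(object) {
  if (object@step <= 0) return("'step' must be > 0")
  if (object@rad <= 0) return("'rad' must be > 0")
  if (!object@mode %in% c("ray_driven", "distance_driven"))
    return("mode must be 'ray_driven' or 'distance_driven'")
  TRUE
})

#' @rdname SamplingPolicy-class
#' @param step integration step (mm); default min detector pixel size.
#' @param rad FOV radius (mm); default half the largest in-plane physical
#'   diagonal of the volume.
#' @param mode "ray_driven" (default) or "distance_driven".
#' @param geometry optional \linkS4class{SystemGeometry} used to fill the
#'   defaults.
#' @return A \linkS4class{SamplingPolicy}.
#' @export
samplingPolicy <- function(step = NULL, rad = NULL, mode = "ray_driven",
                           geometry = NULL) {
  if (is.null(step)) {
    if (is.null(geometry))
      stop("either 'step' or 'geometry' must be given")
    step <- min(geometry@detPixel)
  }
  if (is.null(rad)) {
    if (is.null(geometry))
      stop("either 'rad' or 'geometry' must be given")
    ext <- geometry@volShape[1:2] * geometry@voxel[1:2]
    rad <- sqrt(sum(ext^2)) / 2
  }
  new("SamplingPolicy", step = as.numeric(step), rad = as.numeric(rad),
      mode = mode)
}

#' Backprojection policy
#'
#' @slot mode "voxel_driven" or "distance_driven".
#' @slot applyW2 logical, multiply the FDK distance weight per view.
#' @slot deltaTheta angular step (radians); NA means derive per-view weights
#'   from the view angles (midpoint rule, uniform spacing detected exactly).
#' @export
setClass("BackprojectionPolicy",
  representation(mode = "character", applyW2 = "logical",
                 deltaTheta = "numeric"),
  prototype(mode = "voxel_driven", applyW2 = FALSE, deltaTheta = NA_real_))

setValidity("BackprojectionPolicy", function(object) {
  if (!object@mode %in% c("voxel_driven", "distance_driven"))
    return("mode must be 'voxel_driven' or 'distance_driven'")
  if (!is.na(object@deltaTheta) && object@deltaTheta <= 0)
    return("'deltaTheta' must be > 0")
  TRUE
})

#' @rdname BackprojectionPolicy-class
#' @param mode "voxel_driven" (default) or "distance_driven".
#' @param applyW2 apply the FDK distance weight (default FALSE).
#' @param deltaTheta angular step in radians, or NA to derive it from the
#'   view angles.
#' @return A \linkS4class{BackprojectionPolicy}.
#' @export
backprojectionPolicy <- function(mode = "voxel_driven", applyW2 = FALSE,
                                 deltaTheta = NA_real_) {
  new("BackprojectionPolicy", mode = mode, applyW2 = applyW2,
      deltaTheta = as.numeric(deltaTheta))
}

#' Memory partition plan
#'
#' Half-open index ranges (0-based, [lo, hi)) splitting the volume along z
#' into chunks and the views into sets, so that each partition's working
#' arrays fit a memory budget.
#'
#' @slot chunkExtents list of integer(2) half-open z ranges.
#' @slot setExtents list of integer(2) half-open view ranges.
#' @slot memoryBudget numeric(1) bytes.
#' @export
setClass("PartitionPlan",
  representation(chunkExtents = "list", setExtents = "list",
                 memoryBudget = "numeric"))

.checkExtents <- function(ext, total, what) {
  if (length(ext) == 0L) return(sprintf("no %s extents", what))
  m <- do.call(rbind, ext)
  if (m[1, 1] != 0L || m[nrow(m), 2] != total)
    return(sprintf("%s extents must cover [0, %d)", what, total))
  if (nrow(m) > 1L && any(m[-1, 1] != m[-nrow(m), 2]))
    return(sprintf("%s extents must be contiguous and ordered", what))
  if (any(m[, 2] <= m[, 1]))
    return(sprintf("%s extents must be non-empty", what))
  NULL
}

#' @rdname PartitionPlan-class
#' @param chunkExtents,setExtents lists of integer(2) half-open ranges.
#' @param memoryBudget budget in bytes.
#' @return A \linkS4class{PartitionPlan}.
#' @export
partitionPlan <- function(chunkExtents, setExtents, memoryBudget = NA_real_) {
  new("PartitionPlan",
      chunkExtents = lapply(chunkExtents, as.integer),
      setExtents = lapply(setExtents, as.integer),
      memoryBudget = as.numeric(memoryBudget))
}

#' Ellipsoid specification for phantom construction
#'
#' @slot center numeric(3) mm.
#' @slot semiAxes numeric(3) mm, all > 0.
#' @slot rotation numeric(1) radians about z.
#' @slot value numeric(1) additive attenuation value.
#' @export
setClass("EllipsoidSpec",
  representation(center = "numeric", semiAxes = "numeric",
                 rotation = "numeric", value = "numeric"),
  prototype(center = c(0, 0, 0), rotation = 0, value = 1))

setValidity("EllipsoidSpec", function(object) {
  if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
    return("'semiAxes' must be three positive lengths")
  if (length(object@center) != 3L) return("'center' must have length 3")
  TRUE
})

#' @rdname EllipsoidSpec-class
#' @param center ellipsoid centre (mm).
#' @param semiAxes semi-axis lengths (mm).
#' @param rotation rotation about z (radians).
#' @param value additive attenuation value.
#' @return An \linkS4class{EllipsoidSpec}.
#' @export
ellipsoidSpec <- function(center = c(0, 0, 0), semiAxes, rotation = 0,
                          value = 1) {
  new("EllipsoidSpec", center = as.numeric(center),
      semiAxes = as.numeric(semiAxes), rotation = as.numeric(rotation),
      value = as.numeric(value))
}

#' Tomosynthesis configuration
#'
#' @slot flavor "linear" or "arc".
#' @slot fp focal-plane height (mm, measured from the isocentre toward the
#'   source).
#' @slot sxMax maximum lateral source displacement (mm, linear flavor).
#' @slot sBetaMax maximum source arc angle (radians, arc flavor).
#' @slot nViews number of views.
#' @export
setClass("TomoConfig",
  representation(flavor = "character", fp = "numeric", sxMax = "numeric",
                 sBetaMax = "numeric", nViews = "integer"),
  prototype(fp = 0, sxMax = NA_real_, sBetaMax = NA_real_))

setValidity("TomoConfig", function(object) {
  if (!object@flavor %in% c("linear", "arc"))
    return("flavor must be 'linear' or 'arc'")
  if (object@nViews < 1L) return("'nViews' must be >= 1")
  if (object@flavor == "linear" && !is.finite(object@sxMax))
    return("linear tomosynthesis needs 'sxMax'")
  if (object@flavor == "arc" && !is.finite(object@sBetaMax))
    return("arc tomosynthesis needs 'sBetaMax'")
  TRUE
})

#' @rdname TomoConfig-class
#' @param flavor "linear" or "arc".
#' @param fp focal-plane height (mm).
#' @param sxMax maximum source displacement (mm), linear flavor.
#' @param sBetaMax maximum source arc angle (radians), arc flavor.
#' @param nViews number of views.
#' @return A \linkS4class{TomoConfig}.
#' @export
tomoConfig <- function(flavor = c("linear", "arc"), nViews, fp = 0,
                       sxMax = NA_real_, sBetaMax = NA_real_) {
  flavor <- match.arg(flavor)
  new("TomoConfig", flavor = flavor, fp = as.numeric(fp),
      sxMax = as.numeric(sxMax), sBetaMax = as.numeric(sBetaMax),
      nViews = as.integer(nViews))
}

#' Wide field-of-view configuration
#'
#' @slot mode "tilting" or "linear_displacement".
#' @slot nPositions number of detector positions.
#' @slot overlap overlap between consecutive positions (pixels).
#' @export
setClass("WideFovConfig",
  representation(mode = "character", nPositions = "integer",
                 overlap = "integer"))

setValidity("WideFovConfig", function(object) {
  if (!object@mode %in% c("tilting", "linear_displacement"))
    return("mode must be 'tilting' or 'linear_displacement'")
  if (object@nPositions < 1L) return("'nPositions' must be >= 1")
  if (object@overlap < 0L) return("'overlap' must be >= 0")
  TRUE
})

#' @rdname WideFovConfig-class
#' @param mode "tilting" or "linear_displacement".
#' @param nPositions number of detector positions.
#' @param overlap overlap between consecutive positions (pixels).
#' @return A \linkS4class{WideFovConfig}.
#' @export
wideFovConfig <- function(mode = c("tilting", "linear_displacement"),
                          nPositions, overlap = 0L) {
  mode <- match.arg(mode)
  new("WideFovConfig", mode = mode, nPositions = as.integer(nPositions),
      overlap = as.integer(overlap))
}
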