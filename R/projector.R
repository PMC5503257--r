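#' Forward projection of a volume
#'
#' Simulates cone-beam acquisition: for every view and detector pixel the
#' line integral of the volume along the source-pixel ray is accumulated as
#' step * sum over depth samples of (1 / cos alpha) * f(sample), with
#' trilinear interpolation (ray-driven mode) or overlap-weighted averaging
#' of the volume values between the projected pixel boundaries
#' (distance-driven mode).  Detector misalignments (shifts, skew via the
#' in-plane map; roll and tilt via the inclination map) are applied to the
#' pixel coordinates before the ray is cast; samples outside the volume
#' contribute zero.
#'
#' @param volume a \linkS4class{Volume} consistent with the geometry of
#'   \code{views}.
#' @param views a \linkS4class{ViewSet}.
#' @param policy a \linkS4class{SamplingPolicy}; defaults to step = min
#'   detector pixel and rad = half the volume's in-plane diagonal.
#' @param ... passed to methods.
#' @return A \linkS4class{ProjectionStack}.
#' @examples
#' g <- systemGeometry(500, 250, 33, 33, 2, c(16, 16, 16), 1)
#' vol <- makeEllipsoidPhantom(list(ellipsoidSpec(semiAxes = c(5, 5, 5))), g)
#' stk <- projectVolume(vol, circularViews(360, 4, geometry = g))
#' dim(projectionData(stk))
#' @rdname projectVolume
#' @export
setMethod("projectVolume", signature(volume = "Volume", views = "ViewSet"),
          function(volume, views, policy = NULL, ...) {
  g <- views@geometry
  .checkVolumeGeometry(volume, g)
  if (is.null(policy)) policy <- samplingPolicy(geometry = g)
  stopifnot(is(policy, "SamplingPolicy"))
  .projectSlab(volume@data, g, views, policy,
               z0 = 0L, fullNz = dim(volume@data)[3])
})

# core call used by both monolithic and chunk-partitioned projection:
# `data` holds z-slices [z0, z0 + dim(data)[3]) of a full volume of fullNz
# slices
.projectSlab <- function(data, g, views, policy, z0, fullNz) {
  vp <- .viewMatrix(views)
  arr <- cpp_project(as.numeric(data), dim(data), g@voxel,
                     as.integer(fullNz), as.integer(z0),
                     g@detRows, g@detCols, g@detPixel, vp,
                     policy@step, policy@rad,
                     policy@mode == "distance_driven")
  projectionStack(arr, g@detPixel, views)
}

#' @rdname projectVolume
#' @details \code{projectDistanceDriven} is a convenience wrapper selecting
#'   the distance-driven mode of \code{projectVolume}.
#' @export
projectDistanceDriven <- function(volume, views, policy = NULL) {
  g <- views@geometry
  if (is.null(policy)) policy <- samplingPolicy(geometry = g)
  policy@mode <- "distance_driven"
  projectVolume(volume, views, policy)
}
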