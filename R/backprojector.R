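#' Backprojection of a projection stack
#'
#' Spreads (possibly filtered) projection values back into the volume:
#' f(u, v, z) = sum over views of delta-theta * p_theta at the detector
#' position where the voxel projects, with bilinear interpolation in the
#' projection plane (voxel-driven mode) or an overlap-weighted average of
#' the pixels between the projected voxel boundaries (distance-driven
#' mode).  Misalignments are applied to the computed detector coordinates
#' with the exact inverse of the projector's chain (inclination, then skew,
#' then shift); rays missing the detector contribute zero.  When
#' \code{policy@applyW2} is set, the FDK distance weight
#' (DSO / (DSO + depth))^2 multiplies each view's contribution.
#'
#' @param stack a \linkS4class{ProjectionStack}.
#' @param geometry optional \linkS4class{SystemGeometry}; defaults to the
#'   stack's.
#' @param policy a \linkS4class{BackprojectionPolicy}.
#' @param ... passed to methods.
#' @return A \linkS4class{Volume}.
#' @rdname backprojectStack
#' @export
setMethod("backprojectStack", signature(stack = "ProjectionStack"),
          function(stack, geometry = NULL, policy = backprojectionPolicy(),
                   ...) {
  g <- if (is.null(geometry)) stack@views@geometry else geometry
  stopifnot(is(policy, "BackprojectionPolicy"))
  if (dim(stack@data)[3] != nViews(stack@views))
    stop("view count of the stack does not match its ViewSet")
  if (dim(stack@data)[1] != g@detRows || dim(stack@data)[2] != g@detCols)
    stop("stack detector size does not match the geometry")
  nz <- g@volShape[3]
  .backprojectSlab(stack, g, policy, z0 = 0L, nzSlab = nz, fullNz = nz)
})

# slab form shared with set/chunk partitioning: reconstruct z-slices
# [z0, z0 + nzSlab) of a full volume of fullNz slices
.backprojectSlab <- function(stack, g, policy, z0, nzSlab, fullNz) {
  vp <- .viewMatrix(stack@views)
  dth <- .deltaThetaWeights(viewAngles(stack), policy@deltaTheta)
  volDim <- c(g@volShape[1:2], as.integer(nzSlab))
  arr <- cpp_backproject(as.numeric(stack@data), dim(stack@data),
                         stack@pixel, as.integer(volDim), g@voxel,
                         as.integer(fullNz), as.integer(z0), vp, dth,
                         policy@applyW2,
                         policy@mode == "distance_driven")
  volume(arr, g@voxel)
}

#' @rdname backprojectStack
#' @details \code{backprojectDistanceDriven} is a convenience wrapper
#'   selecting the distance-driven mode.
#' @export
backprojectDistanceDriven <- function(stack, geometry = NULL,
                                      policy = backprojectionPolicy()) {
  policy@mode <- "distance_driven"
  backprojectStack(stack, geometry, policy)
}
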