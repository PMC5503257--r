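#' Accessors for the core containers
#'
#' \code{nViews} and \code{viewAngles} summarise a \linkS4class{ViewSet} or
#' \linkS4class{ProjectionStack}; \code{geometry} returns the shared
#' \linkS4class{SystemGeometry}; \code{volumeData} and \code{projectionData}
#' return the bare numeric arrays.
#'
#' @param x a ViewSet, ProjectionStack or Volume as appropriate.
#' @return counts, numeric vectors or arrays as described.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("nViews", "ViewSet", function(x) length(x@views))

#' @rdname accessors
#' @export
setMethod("nViews", "ProjectionStack", function(x) dim(x@data)[3])

#' @rdname accessors
#' @export
setMethod("viewAngles", "ViewSet",
          function(x) vapply(x@views, slot, numeric(1), name = "theta"))

#' @rdname accessors
#' @export
setMethod("viewAngles", "ProjectionStack", function(x) viewAngles(x@views))

#' @rdname accessors
#' @export
setMethod("geometry", "ViewSet", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("geometry", "ProjectionStack", function(x) x@views@geometry)

#' @rdname accessors
#' @export
setMethod("volumeData", "Volume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("projectionData", "ProjectionStack", function(x) x@data)

setMethod("show", "SystemGeometry", function(object) {
  cat("SystemGeometry\n")
  cat(sprintf("  DSO %.6g mm, DDO %.6g mm\n", object@dso, object@ddo))
  cat(sprintf("  detector %d x %d px (%.6g x %.6g mm)\n",
              object@detRows, object@detCols,
              object@detPixel[1], object@detPixel[2]))
  cat(sprintf("  volume %s voxels (%s mm)\n",
              paste(object@volShape, collapse = " x "),
              paste(signif(object@voxel, 6), collapse = " x ")))
})

setMethod("show", "ViewSet", function(object) {
  th <- viewAngles(object)
  cat(sprintf("ViewSet of %d views, theta in [%.4g, %.4g] deg\n",
              length(th), min(th) * 180 / pi, max(th) * 180 / pi))
  zs <- vapply(object@views, slot, numeric(1), name = "zShift")
  if (any(zs != 0))
    cat(sprintf("  z-shift range [%.4g, %.4g] voxels\n", min(zs), max(zs)))
  show(object@geometry)
})

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume %d x %d x %d voxels (%s mm), range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(signif(object@voxel, 6), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ProjectionStack %d views of %d x %d px (%.6g x %.6g mm), range [%.4g, %.4g]\n",
    d[3], d[1], d[2], object@pixel[1], object@pixel[2],
    min(object@data), max(object@data)))
})

setMethod("show", "PartitionPlan", function(object) {
  fmt <- function(e) paste(vapply(e, function(r)
    sprintf("[%d,%d)", r[1], r[2]), character(1)), collapse = " ")
  cat("PartitionPlan\n")
  cat("  chunks:", fmt(object@chunkExtents), "\n")
  cat("  sets:  ", fmt(object@setExtents), "\n")
  if (is.finite(object@memoryBudget))
    cat(sprintf("  budget: %.4g MB\n", object@memoryBudget / 2^20))
})
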