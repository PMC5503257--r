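#' Plan memory-bounded partitions
#'
#' Splits the volume along z into chunks and the views into sets so that
#' the working array of each partition (8-byte doubles) fits the byte
#' budget: chunks of floor(budget / bytes-per-slice) slices and sets of
#' floor(budget / bytes-per-view) views, each capped at the full extent.
#' When everything fits the plan is a single chunk and a single set.
#'
#' @param geom a \linkS4class{SystemGeometry}.
#' @param nViews number of views to partition.
#' @param budget memory budget in bytes.
#' @return A \linkS4class{PartitionPlan}.
#' @export
planPartitions <- function(geom, nViews, budget) {
  stopifnot(is(geom, "SystemGeometry"))
  nViews <- as.integer(nViews)
  bytesSlice <- 8 * prod(geom@volShape[1:2])
  bytesView <- 8 * geom@detRows * geom@detCols
  minimal <- max(bytesSlice, bytesView)
  if (budget < minimal)
    stop(sprintf(
      "budget too small: at least %d bytes needed for one slice and one view",
      minimal))
  nz <- geom@volShape[3]
  cz <- min(nz, as.integer(floor(budget / bytesSlice)))
  sv <- min(nViews, as.integer(floor(budget / bytesView)))
  split1 <- function(total, size) {
    lo <- seq.int(0L, total - 1L, by = size)
    lapply(lo, function(l) c(l, min(total, l + size)))
  }
  partitionPlan(split1(nz, cz), split1(nViews, sv), budget)
}

#' Chunk-partitioned forward projection
#'
#' Projects each z-chunk of the volume independently and accumulates the
#' per-chunk projections, in ascending chunk order; a single-chunk plan is
#' bitwise-identical to the monolithic projection.
#'
#' @param volume a \linkS4class{Volume}.
#' @param views a \linkS4class{ViewSet}.
#' @param policy a \linkS4class{SamplingPolicy} (default from the geometry).
#' @param plan a \linkS4class{PartitionPlan} covering the volume.
#' @return A \linkS4class{ProjectionStack}.
#' @export
projectPartitioned <- function(volume, views, policy = NULL, plan) {
  g <- views@geometry
  .checkVolumeGeometry(volume, g)
  if (is.null(policy)) policy <- samplingPolicy(geometry = g)
  nz <- dim(volume@data)[3]
  err <- .checkExtents(plan@chunkExtents, nz, "chunk")
  if (!is.null(err)) stop(err)
  acc <- NULL
  for (ext in plan@chunkExtents) {
    slab <- volume@data[, , (ext[1] + 1L):ext[2], drop = FALSE]
    p <- .projectSlab(slab, g, views, policy, z0 = ext[1], fullNz = nz)
    acc <- if (is.null(acc)) p@data else acc + p@data
  }
  projectionStack(acc, g@detPixel, views)
}

#' Set- and chunk-partitioned backprojection
#'
#' Backprojects each view set independently and accumulates (angular
#' additivity); within a set, each z-chunk of the output volume is computed
#' and stored independently.  Single-set, single-chunk plans are
#' bitwise-identical to the monolithic backprojection.
#'
#' @param stack a \linkS4class{ProjectionStack}.
#' @param geometry optional \linkS4class{SystemGeometry}.
#' @param policy a \linkS4class{BackprojectionPolicy}.
#' @param plan a \linkS4class{PartitionPlan} covering views and volume.
#' @return A \linkS4class{Volume}.
#' @export
backprojectPartitioned <- function(stack, geometry = NULL,
                                   policy = backprojectionPolicy(), plan) {
  g <- if (is.null(geometry)) stack@views@geometry else geometry
  nz <- g@volShape[3]
  nv <- dim(stack@data)[3]
  err <- .checkExtents(plan@chunkExtents, nz, "chunk")
  if (!is.null(err)) stop(err)
  err <- .checkExtents(plan@setExtents, nv, "set")
  if (!is.null(err)) stop(err)
  # angular weights must come from the full view set, not each subset
  dthAll <- .deltaThetaWeights(viewAngles(stack), policy@deltaTheta)
  out <- array(0, c(g@volShape[1:2], nz))
  for (sext in plan@setExtents) {
    idx <- (sext[1] + 1L):sext[2]
    sub <- projectionStack(stack@data[, , idx, drop = FALSE], stack@pixel,
                           viewSet(stack@views@views[idx], g))
    subPolicy <- policy
    for (cext in plan@chunkExtents) {
      nzSlab <- cext[2] - cext[1]
      vp <- .viewMatrix(sub@views)
      arr <- cpp_backproject(as.numeric(sub@data), dim(sub@data),
                             sub@pixel, c(g@volShape[1:2],
                                          as.integer(nzSlab)),
                             g@voxel, as.integer(nz), as.integer(cext[1]),
                             vp, dthAll[idx], subPolicy@applyW2,
                             subPolicy@mode == "distance_driven")
      out[, , (cext[1] + 1L):cext[2]] <-
        out[, , (cext[1] + 1L):cext[2]] + arr
    }
  }
  volume(out, g@voxel)
}
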