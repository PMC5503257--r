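#' Additive ellipsoid phantom
#'
#' Voxelises a list of ellipsoids into the geometry's volume grid: each
#' voxel takes the sum of the values of all ellipsoids containing its
#' centre.  An empty list yields a zero volume.
#'
#' @param specs list of \linkS4class{EllipsoidSpec}.
#' @param geom a \linkS4class{SystemGeometry}.
#' @return A \linkS4class{Volume}.
#' @export
makeEllipsoidPhantom <- function(specs, geom) {
  stopifnot(is(geom, "SystemGeometry"))
  sh <- geom@volShape
  vx <- geom@voxel
  u <- (seq_len(sh[1]) - 1 - (sh[1] - 1) / 2) * vx[1]
  v <- (seq_len(sh[2]) - 1 - (sh[2] - 1) / 2) * vx[2]
  z <- (seq_len(sh[3]) - 1 - (sh[3] - 1) / 2) * vx[3]
  vol <- array(0, sh)
  if (length(specs) == 0L) return(volume(vol, vx))
  U <- array(u, sh)
  V <- array(rep(v, each = sh[1]), sh)
  Z <- array(rep(z, each = sh[1] * sh[2]), sh)
  for (s in specs) {
    stopifnot(is(s, "EllipsoidSpec"))
    cu <- U - s@center[1]; cv <- V - s@center[2]; cz <- Z - s@center[3]
    if (s@rotation != 0) {
      cs <- cos(s@rotation); sn <- sin(s@rotation)
      ru <- cs * cu + sn * cv
      rv <- -sn * cu + cs * cv
      cu <- ru; cv <- rv
    }
    inside <- (cu / s@semiAxes[1])^2 + (cv / s@semiAxes[2])^2 +
      (cz / s@semiAxes[3])^2 <= 1
    vol <- vol + s@value * inside
  }
  volume(vol, vx)
}

#' Uniform cylinder phantom
#'
#' A z-aligned cylinder of the given radius and value (an axial-extent
#' convenience over \code{\link{makeEllipsoidPhantom}}'s voxel-centre
#' rule).
#'
#' @param radius cylinder radius (mm).
#' @param geom a \linkS4class{SystemGeometry}.
#' @param value attenuation value.
#' @param height cylinder height (mm); default spans the volume.
#' @return A \linkS4class{Volume}.
#' @export
makeCylinderPhantom <- function(radius, geom, value = 1, height = Inf) {
  sh <- geom@volShape
  vx <- geom@voxel
  u <- (seq_len(sh[1]) - 1 - (sh[1] - 1) / 2) * vx[1]
  v <- (seq_len(sh[2]) - 1 - (sh[2] - 1) / 2) * vx[2]
  z <- (seq_len(sh[3]) - 1 - (sh[3] - 1) / 2) * vx[3]
  disk <- outer(u, v, function(a, b) a^2 + b^2 <= radius^2)
  inz <- abs(z) <= height / 2
  vol <- array(0, sh)
  for (k in which(inz)) vol[, , k] <- value * disk
  volume(vol, vx)
}

#' Point (bead) grid phantom
#'
#' Sets the voxel nearest to each physical position to 1; used as the bead
#' phantom for geometric calibration oracles.
#'
#' @param positions list (or n x 3 matrix) of physical positions (mm),
#'   all inside the volume.
#' @param geom a \linkS4class{SystemGeometry}.
#' @return A \linkS4class{Volume}.
#' @export
makePointGrid <- function(positions, geom) {
  stopifnot(is(geom, "SystemGeometry"))
  if (is.matrix(positions)) positions <- asplit(positions, 1)
  sh <- geom@volShape
  vx <- geom@voxel
  vol <- array(0, sh)
  for (p in positions) {
    p <- as.numeric(p)
    idx <- round(p / vx + (sh - 1) / 2)
    if (any(idx < 0) || any(idx > sh - 1))
      stop("position outside the volume")
    vol[idx[1] + 1, idx[2] + 1, idx[3] + 1] <- 1
  }
  volume(vol, vx)
}

#' Physical position of the voxel nearest to a point
#'
#' Round-trip helper for the centred coordinate convention: the voxel index
#' chosen by \code{\link{makePointGrid}} and its centre coordinates.
#'
#' @param p physical position (mm), length 3.
#' @param geom a \linkS4class{SystemGeometry}.
#' @return list with \code{index} (0-based) and \code{center} (mm).
#' @export
nearestVoxelCenter <- function(p, geom) {
  sh <- geom@volShape
  vx <- geom@voxel
  idx <- round(as.numeric(p) / vx + (sh - 1) / 2)
  list(index = as.integer(idx), center = (idx - (sh - 1) / 2) * vx)
}
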