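#' Detector pixel index to centred physical coordinate
#'
#' Pixel indices are 0-based and refer to pixel centres; the physical origin
#' is the detector centre, so pixel ((detCols-1)/2, (detRows-1)/2) maps to
#' (0, 0).
#'
#' @param i,j 0-based column (x) and row (y) pixel indices (vectorised).
#' @param geom a \linkS4class{SystemGeometry}.
#' @return A list with components \code{x} and \code{y} (mm).
#' @examples
#' g <- systemGeometry(500, 250, 512, 512, 0.2, c(64, 64, 64), 0.125)
#' pixelToPhysical(0, 0, g)$x      # -51.1
#' @export
pixelToPhysical <- function(i, j, geom) {
  stopifnot(is(geom, "SystemGeometry"))
  if (any(i < 0) || any(i > geom@detCols - 1L) ||
      any(j < 0) || any(j > geom@detRows - 1L))
    stop("pixel index out of range")
  list(x = (i - (geom@detCols - 1) / 2) * geom@detPixel[1],
       y = (j - (geom@detRows - 1) / 2) * geom@detPixel[2])
}

#' Apply detector shift and skew to in-plane coordinates
#'
#' Shifts the point by (xShift, yShift) and rotates the result by the skew
#' angle: the in-plane part of the misalignment model, mapping a coordinate
#' on the misaligned detector to the corresponding ideal-frame coordinate.
#'
#' @param x,y coordinates (mm), vectorised.
#' @param m a \linkS4class{DetectorMisalignment} (roll/tilt ignored here).
#' @param inverse if TRUE apply the exact inverse map (rotate by -skew,
#'   then subtract the shifts).
#' @return list with components \code{x}, \code{y}.
#' @examples
#' m <- detectorMisalignment(xShift = 2, skew = pi / 6)
#' applyShiftSkew(0, 0, m)   # (2 cos30, 2 sin30)
#' @export
applyShiftSkew <- function(x, y, m, inverse = FALSE) {
  stopifnot(is(m, "DetectorMisalignment"))
  cs <- cos(m@skew); sn <- sin(m@skew)
  if (!inverse) {
    xp <- x + m@xShift; yp <- y + m@yShift
    list(x = cs * xp - sn * yp, y = sn * xp + cs * yp)
  } else {
    xr <- cs * x + sn * y
    yr <- -sn * x + cs * y
    list(x = xr - m@xShift, y = yr - m@yShift)
  }
}

#' Map an ideal-detector coordinate onto an inclined detector
#'
#' The detector is inclined by \code{epsilon} about the piercing point; the
#' source sits on the central axis at distance DSO + DDO from it.  The map
#' is the exact 2-D ray/inclined-line intersection
#' \deqn{pa' = L\,pa / (L\cos\varepsilon + pa\sin\varepsilon)}
#' with L = DSO + DDO; \code{epsilon = 0} is the identity and the piercing
#' point is a fixed point.  Roll applies this map to the detector x
#' coordinate, tilt to y.
#'
#' @param pa in-plane coordinate on the ideal detector (mm), vectorised.
#' @param epsilon inclination angle (radians).
#' @param geom a \linkS4class{SystemGeometry} (supplies DSO + DDO).
#' @param inverse if TRUE map a real-detector coordinate back to the ideal
#'   detector (exact inverse).
#' @return numeric vector of mapped coordinates (mm).
#' @export
applyInclination <- function(pa, epsilon, geom, inverse = FALSE) {
  stopifnot(is(geom, "SystemGeometry"))
  L <- geom@dso + geom@ddo
  if (!inverse) {
    den <- L * cos(epsilon) + pa * sin(epsilon)
    if (any(den <= 0))
      stop("degenerate geometry: ray parallel to the inclined detector")
    L * pa / den
  } else {
    den <- L - pa * sin(epsilon)
    if (any(den <= 0))
      stop("degenerate geometry: ray parallel to the inclined detector")
    L * pa * cos(epsilon) / den
  }
}

#' Cone angle of a detector position
#'
#' Angle between the ray through the centred detector position (x, y) and
#' the central ray: alpha = arctan(sqrt(x^2 + y^2) / (DSO + DDO)).
#'
#' @param x,y centred detector coordinates (mm), vectorised.
#' @param geom a \linkS4class{SystemGeometry}.
#' @return cone angle(s) in radians.
#' @export
coneAngle <- function(x, y, geom) {
  stopifnot(is(geom, "SystemGeometry"))
  atan(sqrt(x^2 + y^2) / (geom@dso + geom@ddo))
}

#' Magnification along the source-detector axis
#'
#' Mag = (DSO + v) / (DSO + DDO) with v the depth coordinate along the
#' source-detector axis (v = DDO at the detector, v = -DSO at the source).
#' A point at depth v and lateral position u projects to detector
#' coordinate u / Mag.
#'
#' @param v depth coordinate (mm), vectorised.
#' @param geom a \linkS4class{SystemGeometry}.
#' @return dimensionless magnification(s).
#' @export
magnificationAt <- function(v, geom) {
  stopifnot(is(geom, "SystemGeometry"))
  (geom@dso + v) / (geom@dso + geom@ddo)
}

#' Inverse detector magnification at a voxel, backprojection form
#'
#' Mag = (DSO + u sin(theta) + v cos(theta)) / (DSO + DDO): the depth term
#' u sin(theta) + v cos(theta) is the voxel's coordinate along the
#' source-detector axis of the view.  The backprojector reads the detector
#' at u_rot / Mag (and z / Mag).
#'
#' @param u,v centred volume coordinates (mm), vectorised.
#' @param theta view angle (radians).
#' @param geom a \linkS4class{SystemGeometry}.
#' @return dimensionless magnification(s).
#' @export
magnificationBackproj <- function(u, v, theta, geom) {
  stopifnot(is(geom, "SystemGeometry"))
  (geom@dso + (u * sin(theta) + v * cos(theta))) / (geom@dso + geom@ddo)
}

## ---- internal helpers -----------------------------------------------------

# flatten a ViewSet into the kernel parameter matrix; per-view dso/ddo
# overrides resolved against the shared geometry
.viewMatrix <- function(vs) {
  g <- vs@geometry
  t(vapply(vs@views, function(v) {
    m <- v@misalignment
    c(theta = v@theta, xs = m@xShift, ys = m@yShift, skew = m@skew,
      roll = m@roll, tilt = m@tilt, zshift = v@zShift,
      dso = if (is.na(v@dsoOverride)) g@dso else v@dsoOverride,
      ddo = if (is.na(v@ddoOverride)) g@ddo else v@ddoOverride,
      srcx = v@sourceX)
  }, numeric(10)))
}

# per-view angular weights: uniform spacing detected exactly, otherwise
# midpoint rule on the sorted angles (one-sided at the ends)
.deltaThetaWeights <- function(thetas, deltaTheta = NA_real_) {
  n <- length(thetas)
  if (!is.na(deltaTheta)) return(rep(deltaTheta, n))
  if (n == 1L) return(2 * pi)
  d <- diff(thetas)
  if (max(d) - min(d) < 1e-12) return(rep(d[1], n))
  ord <- order(thetas)
  th <- thetas[ord]
  w <- numeric(n)
  w[1] <- (th[2] - th[1])
  w[n] <- (th[n] - th[n - 1])
  if (n > 2L) w[2:(n - 1)] <- (th[3:n] - th[1:(n - 2)]) / 2
  out <- numeric(n)
  out[ord] <- w
  out
}

.checkVolumeGeometry <- function(vol, geom) {
  if (!all(dim(vol@data) == geom@volShape))
    stop("volume shape does not match the geometry's 'volShape'")
  if (!isTRUE(all.equal(vol@voxel, geom@voxel, tolerance = 1e-9)))
    stop("volume voxel sizes do not match the geometry")
  invisible(TRUE)
}
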