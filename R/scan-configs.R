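#' Circular cone-beam trajectory
#'
#' Generates \code{nproj} evenly spaced view angles starting at \code{ini},
#' covering \code{span} degrees end-exclusive (so span = 360, nproj = 4
#' gives 0, 90, 180, 270 degrees).  A shared misalignment may be applied to
#' every view.
#'
#' @param span total angular span (degrees).
#' @param nproj number of projections (>= 1).
#' @param ini initial angle (degrees).
#' @param misalignment \linkS4class{DetectorMisalignment} shared by all
#'   views.
#' @param geometry a \linkS4class{SystemGeometry}.
#' @return A \linkS4class{ViewSet}.
#' @export
circularViews <- function(span = 360, nproj, ini = 0,
                          misalignment = detectorMisalignment(), geometry) {
  nproj <- as.integer(nproj)
  if (is.na(nproj) || nproj < 1L) stop("'nproj' must be >= 1")
  th <- (ini + span * (seq_len(nproj) - 1) / nproj) * pi / 180
  viewSet(lapply(th, function(t) view(theta = t,
                                      misalignment = misalignment)),
          geometry)
}

#' Helical (spiral) trajectory
#'
#' Circular angles plus a cumulative bed translation: view k (0-based)
#' carries a z-shift of k * pitch / (n * thick) voxels, so one full rotation
#' (n views) advances the bed by exactly \code{pitch} mm.
#'
#' @param pitch bed travel per rotation (mm); 0 degenerates to a circular
#'   scan.
#' @param span total angular span (degrees).
#' @param n views per rotation.
#' @param thick slice thickness (mm), i.e. the z voxel size.
#' @param nproj total number of projections; defaults to n * span / 360.
#' @param ini initial angle (degrees).
#' @param misalignment shared \linkS4class{DetectorMisalignment}.
#' @param geometry a \linkS4class{SystemGeometry}.
#' @return A \linkS4class{ViewSet} whose views carry increasing
#'   \code{zShift}.
#' @export
helicalViews <- function(pitch, span = 360, n, thick, nproj = NULL, ini = 0,
                         misalignment = detectorMisalignment(), geometry) {
  if (thick <= 0) stop("'thick' must be > 0")
  if (n < 1) stop("'n' (views per rotation) must be >= 1")
  if (is.null(nproj)) nproj <- as.integer(round(n * span / 360))
  base <- circularViews(span, nproj, ini, misalignment, geometry)
  inc <- pitch / (n * thick)
  base@views <- lapply(seq_along(base@views), function(k) {
    v <- base@views[[k]]
    v@zShift <- (k - 1) * inc
    v
  })
  base
}

## ---- arbitrary positioning ------------------------------------------------

.normalize <- function(x) x / sqrt(sum(x^2))

# basis of the ideal detector frame at angle theta: x along the in-plane
# detector axis, y along +z, normal pointing back toward the source
.idealFrame <- function(theta) {
  d <- c(sin(theta), cos(theta), 0)          # origin -> detector direction
  list(ex = c(cos(theta), -sin(theta), 0), ey = c(0, 0, 1), n = -d, d = d)
}

#' Translate arbitrary source/detector poses into views
#'
#' Each pose is decomposed into the deviation of the detector from the ideal
#' circular-scan pose at the source's azimuth: (1) in-plane shifts chosen so
#' the source-object line pierces the stored detector coordinate origin;
#' (2) inclinations (roll about the detector's vertical axis, tilt about its
#' horizontal axis) and skew (in-plane) as the rotation between real and
#' ideal detector frames.  Per-view DSO/DDO overrides are set when the pose
#' distances differ from the geometry's.
#'
#' @param sources list (or n x 3 matrix) of 3D source positions (mm),
#'   currently restricted to the z = 0 plane.
#' @param poses list of detector poses, each a list with elements
#'   \code{center} (3D mm), \code{normal} and \code{xaxis} (3D directions;
#'   orthogonalised internally).
#' @param geometry a \linkS4class{SystemGeometry}.
#' @return A \linkS4class{ViewSet}.
#' @seealso \code{\link{viewPose}} for the inverse rendering.
#' @export
arbitraryToViews <- function(sources, poses, geometry) {
  if (is.matrix(sources)) sources <- asplit(sources, 1)
  if (length(sources) != length(poses))
    stop("'sources' and 'poses' must have the same length")
  vs <- mapply(function(S, P) {
    S <- as.numeric(S)
    if (abs(S[3]) > 1e-9)
      stop("source positions must lie in the z = 0 plane")
    dso <- sqrt(S[1]^2 + S[2]^2)
    if (dso <= 0) stop("degenerate pose: source at the origin")
    theta <- atan2(-S[1], -S[2])
    fr <- .idealFrame(theta)
    ex <- .normalize(as.numeric(P$xaxis))
    n <- .normalize(as.numeric(P$normal))
    ex <- .normalize(ex - sum(ex * n) * n)
    ey <- .pracross(n, ex)
    C <- as.numeric(P$center)
    dn <- sum(fr$d * n)
    if (abs(dn) < 1e-12)
      stop("degenerate pose: detector plane contains the source-object line")
    ddo <- sum(C * n) / dn
    # rotation of the real frame relative to the ideal one
    M <- rbind(c(sum(fr$ex * ex), sum(fr$ex * ey), sum(fr$ex * n)),
               c(sum(fr$ey * ex), sum(fr$ey * ey), sum(fr$ey * n)),
               c(sum(fr$n * ex), sum(fr$n * ey), sum(fr$n * n)))
    tilt <- -asin(M[2, 3])
    roll <- atan2(M[1, 3], M[3, 3])
    skew <- atan2(M[2, 1], M[2, 2])
    piercing <- ddo * fr$d
    pl <- c(sum((piercing - C) * ex), sum((piercing - C) * ey))
    view(theta = theta,
         misalignment = detectorMisalignment(xShift = -pl[1],
                                             yShift = -pl[2],
                                             skew = skew, roll = roll,
                                             tilt = tilt),
         dsoOverride = if (abs(dso - geometry@dso) > 1e-9) dso else NA_real_,
         ddoOverride = if (abs(ddo - geometry@ddo) > 1e-9) ddo else NA_real_)
  }, sources, poses, SIMPLIFY = FALSE)
  viewSet(vs, geometry)
}

.pracross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Render a view back into a 3D source/detector pose
#'
#' Exact inverse of \code{\link{arbitraryToViews}}: returns the source
#' position and the detector centre/axes implied by a view's angle,
#' misalignment and distance overrides.
#'
#' @param v a \linkS4class{View}.
#' @param geometry a \linkS4class{SystemGeometry}.
#' @return list with \code{source}, and a pose list (\code{center},
#'   \code{normal}, \code{xaxis}).
#' @export
viewPose <- function(v, geometry) {
  dso <- if (is.na(v@dsoOverride)) geometry@dso else v@dsoOverride
  ddo <- if (is.na(v@ddoOverride)) geometry@ddo else v@ddoOverride
  fr <- .idealFrame(v@theta)
  m <- v@misalignment
  Ry <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                          c(-sin(a), 0, cos(a)))
  Rx <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                          c(0, sin(a), cos(a)))
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  M <- Ry(m@roll) %*% Rx(m@tilt) %*% Rz(m@skew)
  B <- cbind(fr$ex, fr$ey, fr$n)   # ideal basis as columns (global coords)
  ex <- as.numeric(B %*% M[, 1])
  ey <- as.numeric(B %*% M[, 2])
  n <- as.numeric(B %*% M[, 3])
  piercing <- ddo * fr$d
  C <- piercing + m@xShift * ex + m@yShift * ey
  list(source = -dso * c(sin(v@theta), cos(v@theta), 0),
       pose = list(center = C, normal = n, xaxis = ex))
}

## ---- tomosynthesis --------------------------------------------------------

#' Tomosynthesis view generation on a virtual detector
#'
#' Builds the view set for linear tomosynthesis (source translated laterally
#' while the detector moves the opposite way) or arc tomosynthesis (static
#' detector, source on an arc about the focal-plane centre), realised on a
#' static virtual detector wider than the real one.  Structures in the
#' focal plane (depth \code{fp} mm from the isocentre toward the source)
#' project to the same region-of-interest-relative detector position in
#' every view.
#'
#' Per view i with source displacement Sx(i) (linear) the detector ROI of
#' real size is centred at the projection of the focal-plane centre,
#' -Dx(i) with Dx = Sx (DDO + FP) / (DSO - FP); for the arc flavor the
#' source moves to lateral offset Sx = sin(Sb) (DSO - FP) at reduced
#' distance DSO' = cos(Sb) (DSO - FP) + FP and the ROI is centred at
#' -tan(Sb) (DDO + FP).  The virtual detector width is the larger of the
#' closed-form large-detector size (2 Sx,max (1 + (DDO+FP)/(DSO-FP)) +
#' Dreal for linear; Dreal + 2 Sx,max for arc) and the exact ROI union.
#'
#' @param cfg a \linkS4class{TomoConfig}.
#' @param geom the real-detector \linkS4class{SystemGeometry};
#'   \code{geom@dso - cfg@fp} must be positive.
#' @return list with \code{views} (a \linkS4class{ViewSet} on the virtual
#'   geometry), \code{virtualGeom}, \code{rois} (data.frame of per-view ROI
#'   windows: centre in mm and pixels, half-open column range), and
#'   \code{dLarge} (virtual width, mm, per the closed form).
#' @export
tomosynthesisViews <- function(cfg, geom) {
  stopifnot(is(cfg, "TomoConfig"), is(geom, "SystemGeometry"))
  fp <- cfg@fp
  if (geom@dso - fp <= 0) stop("focal plane must lie below the source")
  nv <- cfg@nViews
  dReal <- geom@detCols * geom@detPixel[1]
  if (cfg@flavor == "linear") {
    sx <- if (nv == 1L) 0 else seq(-cfg@sxMax, cfg@sxMax, length.out = nv)
    dx <- sx * (geom@ddo + fp) / (geom@dso - fp)
    dLarge <- 2 * max(abs(sx)) * (1 + (geom@ddo + fp) / (geom@dso - fp)) +
      dReal
    # equivalent printed form 2 (Sx + Dx + Dreal / 2); both computed
    dLargeAlt <- 2 * (max(abs(sx)) + max(abs(dx)) + dReal / 2)
    if (abs(dLarge - dLargeAlt) > 1e-6 * max(dLarge, 1))
      warning("large-detector closed form and assembled form disagree")
    roiCenter <- -dx
    dsoV <- rep(geom@dso, nv)
  } else {
    sb <- if (nv == 1L) 0 else
      seq(-cfg@sBetaMax, cfg@sBetaMax, length.out = nv)
    sx <- sin(sb) * (geom@dso - fp)
    dsoV <- cos(sb) * (geom@dso - fp) + fp
    dLarge <- dReal + 2 * max(abs(sx))
    roiCenter <- -tan(sb) * (geom@ddo + fp)
  }
  need <- 2 * max(abs(roiCenter)) + dReal
  width <- max(dLarge, need)
  ncVirt <- as.integer(ceiling(width / geom@detPixel[1]))
  # keep the virtual centre on the same pixel-grid parity as the real one
  if ((ncVirt - geom@detCols) %% 2L == 1L) ncVirt <- ncVirt + 1L
  virtualGeom <- systemGeometry(geom@dso, geom@ddo, geom@detRows, ncVirt,
                                geom@detPixel, geom@volShape, geom@voxel)
  views <- lapply(seq_len(nv), function(i)
    view(theta = 0, sourceX = sx[i], roiCenterX = roiCenter[i],
         dsoOverride = if (cfg@flavor == "arc") dsoV[i] else NA_real_))
  vs <- viewSet(views, virtualGeom)
  centerPx <- roiCenter / geom@detPixel[1] + (ncVirt - 1) / 2
  x0 <- as.integer(round(centerPx - (geom@detCols - 1) / 2))
  rois <- data.frame(view = seq_len(nv), centerMm = roiCenter,
                     centerPx = centerPx, x0 = x0,
                     x1 = x0 + geom@detCols)
  list(views = vs, virtualGeom = virtualGeom, rois = rois, dLarge = dLarge)
}

## ---- wide field of view ---------------------------------------------------

#' Wide field-of-view acquisition
#'
#' Simulates a detector smaller than the scanned area.  In "tilting" mode a
#' static virtual detector is tiled by N real-detector-sized ROIs with a
#' fixed pixel overlap between consecutive positions: ROI n is centred at
#' Dx(n) = n Dreal - (n - 1) Overlap - Dreal/2 pixels from the virtual
#' detector's left edge.  The printed large-detector size
#' N (Dreal - (N - 1) Overlap) is also computed; when it disagrees with the
#' exact ROI union N Dreal - (N - 1) Overlap (any positive overlap and
#' N > 1) a consistency warning is raised and the union is used for the
#' virtual geometry.  In "linear_displacement" mode the volume is stepped
#' along z between positions, as in a helical scan.
#'
#' @param cfg a \linkS4class{WideFovConfig}.
#' @param geom the real-detector \linkS4class{SystemGeometry}.
#' @param theta gantry angle shared by the positions (radians).
#' @return list with \code{views}, \code{virtualGeom}, \code{rois}
#'   (per-position half-open pixel windows on the virtual detector, or
#'   full-detector windows in linear mode) and \code{dLarge} (pixels, as
#'   printed).
#' @export
wideFovViews <- function(cfg, geom, theta = 0) {
  stopifnot(is(cfg, "WideFovConfig"), is(geom, "SystemGeometry"))
  N <- cfg@nPositions
  ov <- cfg@overlap
  if (cfg@mode == "tilting") {
    dReal <- geom@detCols
    if (ov >= dReal) stop("'overlap' must be smaller than the detector size")
    dLarge <- N * (dReal - (N - 1L) * ov)
    union <- N * dReal - (N - 1L) * ov
    if (dLarge != union)
      warning(sprintf(
        "printed large-detector size (%d px) differs from the ROI union (%d px); using the union",
        dLarge, union))
    n <- seq_len(N)
    dx <- n * dReal - (n - 1L) * ov - dReal / 2   # px from the left edge
    virtualGeom <- systemGeometry(geom@dso, geom@ddo, geom@detRows,
                                  as.integer(union), geom@detPixel,
                                  geom@volShape, geom@voxel)
    centerMm <- (dx - union / 2) * geom@detPixel[1]
    views <- lapply(centerMm, function(cm)
      view(theta = theta, roiCenterX = cm))
    x0 <- as.integer(round(dx - dReal / 2))
    rois <- data.frame(view = n, centerPx = dx, centerMm = centerMm,
                       x0 = x0, x1 = x0 + as.integer(dReal))
    list(views = viewSet(views, virtualGeom), virtualGeom = virtualGeom,
         rois = rois, dLarge = dLarge)
  } else {
    dRealY <- geom@detRows
    if (ov >= dRealY) stop("'overlap' must be smaller than the detector size")
    # z step chosen so consecutive detector footprints overlap by 'overlap'
    # pixels at the isocentre plane
    stepVox <- (dRealY - ov) * geom@detPixel[2] *
      geom@dso / (geom@dso + geom@ddo) / geom@voxel[3]
    n <- seq_len(N)
    shifts <- (n - (N + 1) / 2) * stepVox
    views <- lapply(shifts, function(s) view(theta = theta, zShift = s))
    rois <- data.frame(view = n, centerPx = (geom@detCols - 1) / 2,
                       centerMm = 0, x0 = 0L, x1 = geom@detCols)
    list(views = viewSet(views, geom), virtualGeom = geom, rois = rois,
         dLarge = geom@detCols)
  }
}

#' Extract per-view regions of interest from a virtual-detector stack
#'
#' @param stack a \linkS4class{ProjectionStack} acquired on a virtual
#'   detector.
#' @param rois ROI table as returned by \code{\link{tomosynthesisViews}} or
#'   \code{\link{wideFovViews}}.
#' @param geometry the real-detector \linkS4class{SystemGeometry} the ROIs
#'   correspond to.
#' @return A \linkS4class{ProjectionStack} of real-detector-sized images.
#' @export
extractRois <- function(stack, rois, geometry) {
  d <- dim(stack@data)
  nv <- d[3]
  if (nrow(rois) != nv) stop("one ROI per view required")
  nc <- geometry@detCols
  out <- array(0, c(d[1], nc, nv))
  for (i in seq_len(nv)) {
    x0 <- rois$x0[i]; x1 <- rois$x1[i]
    if (x0 < 0L || x1 > d[2]) stop("ROI outside the virtual detector")
    out[, , i] <- stack@data[, (x0 + 1L):x1, i]
  }
  projectionStack(out, stack@pixel, stack@views)
}
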