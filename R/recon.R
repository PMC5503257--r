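#' FDK cosine weight map (W1)
#'
#' W1(x, y) = D / sqrt(D^2 + x^2 + y^2) over centred detector coordinates,
#' the cosine of the cone angle of each pixel.  By default D is the
#' source-detector distance DSO + DDO (the standard FDK pre-weight); the
#' source-isocentre reading D = DSO is available for compatibility with
#' formulations that state the weight in isocentre-scaled coordinates.
#'
#' @param geom a \linkS4class{SystemGeometry}.
#' @param distance "source-detector" (default) or "source-isocenter".
#' @return A detRows x detCols numeric matrix with values in (0, 1], equal
#'   to 1 at the detector centre.
#' @export
cosineWeightMap <- function(geom,
                            distance = c("source-detector",
                                         "source-isocenter")) {
  stopifnot(is(geom, "SystemGeometry"))
  distance <- match.arg(distance)
  D <- if (distance == "source-detector") geom@dso + geom@ddo else geom@dso
  x <- (seq_len(geom@detCols) - 1 - (geom@detCols - 1) / 2) * geom@detPixel[1]
  y <- (seq_len(geom@detRows) - 1 - (geom@detRows - 1) / 2) * geom@detPixel[2]
  outer(y, x, function(yy, xx) D / sqrt(D^2 + xx^2 + yy^2))
}

#' FDK distance weight (W2)
#'
#' W2 = (DSO / (DSO - v))^2 with v the voxel's depth coordinate measured
#' from the isocentre toward the source (mm).  For a voxel between source
#' and detector the weight is positive; a voxel in the source plane
#' (v = DSO) is a domain error.
#'
#' @param v source-ward depth coordinate(s), mm.
#' @param geom a \linkS4class{SystemGeometry}.
#' @return numeric weight(s).
#' @export
distanceWeight <- function(v, geom) {
  stopifnot(is(geom, "SystemGeometry"))
  den <- geom@dso - v
  if (any(den == 0)) stop("voxel at the source plane: weight undefined")
  (geom@dso / den)^2
}

# discrete ramp |f| on the padded grid of length m with sample spacing tau:
# frequencies k/(m*tau) for k = 0..m/2, mirrored
.rampResponse <- function(m, tau) {
  k <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1))
  abs(k) / (m * tau)
}

.padLength <- function(n) {
  m <- 1L
  while (m < 2L * n) m <- m * 2L
  m
}

#' Ramp filtering of a projection stack
#'
#' Filters every detector row along the detector x-axis with the discrete
#' ramp (frequency response |f|, zero DC), zero-padding each row to the
#' next power of two at least twice the detector width.  The "fft" backend
#' multiplies in the transform domain; the "convolution" backend convolves
#' in the spatial domain with the exact impulse response of the same
#' discrete ramp, so the two agree to rounding error.
#'
#' @param stack a \linkS4class{ProjectionStack}.
#' @param backend "fft" (default) or "convolution".
#' @return A filtered \linkS4class{ProjectionStack} (units 1/mm relative to
#'   the input).
#' @export
rampFilter <- function(stack, backend = c("fft", "convolution")) {
  stopifnot(is(stack, "ProjectionStack"))
  backend <- match.arg(backend)
  d <- dim(stack@data)
  nr <- d[1]; nc <- d[2]; nw <- d[3]
  m <- .padLength(nc)
  tau <- stack@pixel[1]
  ramp <- .rampResponse(m, tau)
  # rows of all views as an (nr * nw) x m padded matrix
  rows <- matrix(0, nr * nw, m)
  rows[, seq_len(nc)] <- matrix(aperm(stack@data, c(1, 3, 2)), nr * nw, nc)
  if (backend == "fft") {
    ft <- t(stats::mvfft(t(rows)))
    filt <- Re(t(stats::mvfft(t(ft * rep(ramp, each = nr * nw)),
                              inverse = TRUE))) / m
  } else {
    kern <- Re(stats::fft(ramp, inverse = TRUE)) / m  # impulse response
    filt <- cpp_circular_convolve_rows(rows, kern)
  }
  out <- aperm(array(filt[, seq_len(nc)], dim = c(nr, nw, nc)), c(1, 3, 2))
  projectionStack(out, stack@pixel, stack@views)
}

#' Impulse response of the discrete ramp filter
#'
#' Returns the spatial kernel the "convolution" backend of
#' \code{\link{rampFilter}} uses, centred on lag 0 (lags
#' -(m/2 - 1) .. m/2).  For unit sample spacing the central values approach
#' the classical band-limited ramp kernel h(0) = 1/4,
#' h(odd k) = -1/(pi k)^2, h(even k) = 0.
#'
#' @param n detector width (pixels); the kernel is computed on the padded
#'   length used for that width.
#' @param tau sample spacing (mm).
#' @return numeric vector with attribute \code{lags}.
#' @export
rampKernel <- function(n, tau = 1) {
  m <- .padLength(as.integer(n))
  kern <- Re(stats::fft(.rampResponse(m, tau), inverse = TRUE)) / m
  lags <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1))
  ord <- order(lags)
  structure(kern[ord], lags = lags[ord])
}

#' FDK-style filtered backprojection reconstruction
#'
#' Composes the FDK pipeline: cosine pre-weighting (W1), ramp filtering
#' along detector rows, and weighted voxel- or distance-driven
#' backprojection with the distance weight (W2) and the angular step, scaled
#' by the analytic full-scan normalisation 0.5 * (DSO + DDO) / DSO that maps
#' filtered values on the physical detector to isocentre-plane filtering.
#'
#' @param stack a \linkS4class{ProjectionStack} from a circular (full or
#'   partial) scan.
#' @param geometry optional \linkS4class{SystemGeometry}; defaults to the
#'   stack's.
#' @param policy a \linkS4class{BackprojectionPolicy}; \code{applyW2} is
#'   forced on.
#' @param backend ramp-filter backend, see \code{\link{rampFilter}}.
#' @return A reconstructed \linkS4class{Volume}.
#' @export
fdkReconstruct <- function(stack, geometry = NULL,
                           policy = backprojectionPolicy(),
                           backend = c("fft", "convolution")) {
  g <- if (is.null(geometry)) stack@views@geometry else geometry
  backend <- match.arg(backend)
  w1 <- cosineWeightMap(g)
  weighted <- stack
  weighted@data <- stack@data * as.vector(w1)
  filtered <- rampFilter(weighted, backend = backend)
  policy@applyW2 <- TRUE
  vol <- backprojectStack(filtered, g, policy)
  vol@data <- vol@data * (0.5 * (g@dso + g@ddo) / g@dso)
  vol
}
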