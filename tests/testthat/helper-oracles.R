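# Shared fixtures and independent oracles, all built in code.

# small geometry used by the dense-matrix tests: 8^3 volume, 12^2 detector
tinyGeom <- function() {
  systemGeometry(dso = 60, ddo = 30, detRows = 12, detCols = 12,
                 detPixel = 3, volShape = c(8, 8, 8), voxel = 2)
}

midGeom <- function() {
  systemGeometry(dso = 500, ddo = 250, detRows = 64, detCols = 64,
                 detPixel = 1.5, volShape = c(32, 32, 32), voxel = 1)
}

# centred physical coordinates of the voxel/pixel grids
centeredCoords <- function(n, d) ((seq_len(n) - 1) - (n - 1) / 2) * d

# ---- analytic pinhole oracle ----------------------------------------------
# Similar-triangle projection of a 3D point through the misalignment chain:
# ideal detector coordinates by magnification, then the inverse of the
# projector's real->ideal chain to get real-pixel coordinates.
pinholePredict <- function(p, theta, g, m = detectorMisalignment(),
                           sourceX = 0, dso = g@dso, ddo = g@ddo) {
  L <- dso + ddo
  ur <- p[1] * cos(theta) - p[2] * sin(theta)
  vr <- p[1] * sin(theta) + p[2] * cos(theta)
  mag <- L / (dso + vr)
  xid <- sourceX + (ur - sourceX) * mag
  yid <- p[3] * mag
  gl <- systemGeometry(dso, ddo, g@detRows, g@detCols, g@detPixel,
                       g@volShape, g@voxel)
  x1 <- applyInclination(xid, m@roll, gl)
  y1 <- applyInclination(yid, m@tilt, gl)
  ss <- applyShiftSkew(x1, y1, m, inverse = TRUE)
  c(x = ss$x / g@detPixel[1] + (g@detCols - 1) / 2,
    y = ss$y / g@detPixel[2] + (g@detRows - 1) / 2)
}

# centre-of-mass of the projection footprint around its peak (0-based px)
footprintCenter <- function(A, win = 2) {
  idx <- which(A == max(A), arr.ind = TRUE)[1, ]
  jr <- max(1, idx[1] - win):min(nrow(A), idx[1] + win)
  ic <- max(1, idx[2] - win):min(ncol(A), idx[2] + win)
  W <- A[jr, ic, drop = FALSE]
  c(x = sum(t(W) * ic) / sum(W) - 1, y = sum(W * jr) / sum(W) - 1)
}

# ---- dense system-matrix oracles ------------------------------------------
# Enumerate every (pixel, depth-sample, interpolation-cell) triple in plain
# R, independently of the C++ kernels.

.oracleChainToIdeal <- function(x, y, m, L) {
  s <- applyShiftSkew(x, y, m)
  gtmp <- systemGeometry(L / 2, L / 2, 2, 2, 1, c(2, 2, 2), 1)
  list(x = applyInclination(s$x, m@roll, gtmp, inverse = TRUE),
       y = applyInclination(s$y, m@tilt, gtmp, inverse = TRUE))
}

.oracleChainToReal <- function(x, y, m, L) {
  gtmp <- systemGeometry(L / 2, L / 2, 2, 2, 1, c(2, 2, 2), 1)
  x1 <- applyInclination(x, m@roll, gtmp)
  y1 <- applyInclination(y, m@tilt, gtmp)
  s <- applyShiftSkew(x1, y1, m, inverse = TRUE)
  list(x = s$x, y = s$y)
}

# overlap of [a, b] with unit cell centred at k
.cellOverlap <- function(a, b, k) pmax(0, pmin(b, k + 0.5) - pmax(a, k - 0.5))

# weights over integer cells for an interval in index units (normalised),
# mirroring the kernel's degenerate-interval fallback
.intervalWeights <- function(a, b, eps = 1e-9) {
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  if (b - a <= eps) {
    k0 <- floor(a)
    data.frame(cell = c(k0, k0 + 1), w = c(1 - (a - k0), a - k0))
  } else {
    cells <- floor(a + 0.5):floor(b + 0.5)
    data.frame(cell = cells, w = .cellOverlap(a, b, cells) / (b - a))
  }
}

denseProjectorMatrix <- function(g, vs, pol) {
  nu <- g@volShape[1]; nv <- g@volShape[2]; nz <- g@volShape[3]
  nr <- g@detRows; nc <- g@detCols
  nViews <- length(vs@views)
  nStep <- floor(2 * pol@rad / pol@step) + 1
  dd <- pol@mode == "distance_driven"
  A <- matrix(0, nr * nc * nViews, nu * nv * nz)
  volIdx <- function(iu, iv, iz) iu + nu * (iv + nv * iz) + 1  # 0-based in
  for (w in seq_len(nViews)) {
    v <- vs@views[[w]]
    m <- v@misalignment
    dso <- if (is.na(v@dsoOverride)) g@dso else v@dsoOverride
    ddo <- if (is.na(v@ddoOverride)) g@ddo else v@ddoOverride
    L <- dso + ddo
    ct <- cos(v@theta); st <- sin(v@theta)
    sx <- v@sourceX
    latAxis <- if (abs(ct) >= abs(st)) 0 else 1
    for (i in 0:(nc - 1)) for (j in 0:(nr - 1)) {
      xp <- (i - (nc - 1) / 2) * g@detPixel[1]
      yp <- (j - (nr - 1) / 2) * g@detPixel[2]
      id <- .oracleChainToIdeal(xp, yp, m, L)
      cosA <- L / sqrt(L^2 + id$x^2 + id$y^2)
      row <- j + nr * (i + nc * (w - 1)) + 1
      if (dd) {
        b1 <- .oracleChainToIdeal(xp - g@detPixel[1] / 2,
                                  yp - g@detPixel[2] / 2, m, L)
        b2 <- .oracleChainToIdeal(xp + g@detPixel[1] / 2,
                                  yp + g@detPixel[2] / 2, m, L)
      }
      for (k in 0:(nStep - 1)) {
        vdep <- -pol@rad + k * pol@step
        im <- (dso + vdep) / L
        if (!dd) {
          u <- sx + (id$x - sx) * im
          zc <- id$y * im - v@zShift * g@voxel[3]
          U <- u * ct + vdep * st
          V <- -u * st + vdep * ct
          fu <- U / g@voxel[1] + (nu - 1) / 2
          fv <- V / g@voxel[2] + (nv - 1) / 2
          fz <- zc / g@voxel[3] + (nz - 1) / 2
          u0 <- floor(fu); v0 <- floor(fv); z0 <- floor(fz)
          for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
            iu <- u0 + a; iv <- v0 + b; iz <- z0 + cc
            wt <- (if (a) fu - u0 else 1 - (fu - u0)) *
              (if (b) fv - v0 else 1 - (fv - v0)) *
              (if (cc) fz - z0 else 1 - (fz - z0))
            if (wt != 0 && iu >= 0 && iu < nu && iv >= 0 && iv < nv &&
                iz >= 0 && iz < nz)
              A[row, volIdx(iu, iv, iz)] <-
                A[row, volIdx(iu, iv, iz)] + wt * pol@step / cosA
          }
        } else {
          u1 <- sx + (b1$x - sx) * im
          u2 <- sx + (b2$x - sx) * im
          uc <- sx + (id$x - sx) * im
          z1 <- (b1$y * im - v@zShift * g@voxel[3]) / g@voxel[3] +
            (nz - 1) / 2
          z2 <- (b2$y * im - v@zShift * g@voxel[3]) / g@voxel[3] +
            (nz - 1) / 2
          if (latAxis == 0) {
            l1 <- (u1 * ct + vdep * st) / g@voxel[1] + (nu - 1) / 2
            l2 <- (u2 * ct + vdep * st) / g@voxel[1] + (nu - 1) / 2
            fixed <- (-uc * st + vdep * ct) / g@voxel[2] + (nv - 1) / 2
          } else {
            l1 <- (-u1 * st + vdep * ct) / g@voxel[2] + (nv - 1) / 2
            l2 <- (-u2 * st + vdep * ct) / g@voxel[2] + (nv - 1) / 2
            fixed <- (uc * ct + vdep * st) / g@voxel[1] + (nu - 1) / 2
          }
          lw <- .intervalWeights(l1, l2)
          zw <- .intervalWeights(z1, z2)
          j0 <- floor(fixed); tj <- fixed - j0
          for (li in seq_len(nrow(lw))) for (zi in seq_len(nrow(zw))) {
            zc <- zw$cell[zi]
            if (lw$w[li] <= 0 || zw$w[zi] <= 0) next
            if (zc < 0 || zc >= nz) next
            for (cc in 0:1) {
              jf <- j0 + cc
              wj <- if (cc) tj else 1 - tj
              if (wj == 0) next
              if (latAxis == 0) { iu <- lw$cell[li]; iv <- jf }
              else { iu <- jf; iv <- lw$cell[li] }
              if (iu < 0 || iu >= nu || iv < 0 || iv >= nv) next
              A[row, volIdx(iu, iv, zc)] <- A[row, volIdx(iu, iv, zc)] +
                lw$w[li] * zw$w[zi] * wj * pol@step / cosA
            }
          }
        }
      }
    }
  }
  A
}

denseBackprojMatrix <- function(g, vs, dtheta, applyW2 = FALSE,
                                mode = "voxel_driven") {
  nu <- g@volShape[1]; nv <- g@volShape[2]; nz <- g@volShape[3]
  nr <- g@detRows; nc <- g@detCols
  nViews <- length(vs@views)
  dd <- mode == "distance_driven"
  B <- matrix(0, nu * nv * nz, nr * nc * nViews)
  for (w in seq_len(nViews)) {
    v <- vs@views[[w]]
    m <- v@misalignment
    dso <- if (is.na(v@dsoOverride)) g@dso else v@dsoOverride
    ddo <- if (is.na(v@ddoOverride)) g@ddo else v@ddoOverride
    L <- dso + ddo
    ct <- cos(v@theta); st <- sin(v@theta)
    sx <- v@sourceX
    latAxis <- abs(ct) >= abs(st)
    for (iz in 0:(nz - 1)) for (iv in 0:(nv - 1)) for (iu in 0:(nu - 1)) {
      z <- (iz - (nz - 1) / 2) * g@voxel[3] + v@zShift * g@voxel[3]
      vphys <- (iv - (nv - 1) / 2) * g@voxel[2]
      uphys <- (iu - (nu - 1) / 2) * g@voxel[1]
      vr <- uphys * st + vphys * ct
      den <- dso + vr
      if (den <= 1e-9) next
      mag <- L / den
      w2 <- if (applyW2) (dso / den)^2 else 1
      rowv <- iu + nu * (iv + nv * iz) + 1
      add <- function(jj, ii, wt) {
        if (jj >= 0 && jj < nr && ii >= 0 && ii < nc && wt != 0)
          B[rowv, jj + nr * (ii + nc * (w - 1)) + 1] <<-
            B[rowv, jj + nr * (ii + nc * (w - 1)) + 1] + wt * dtheta[w] * w2
      }
      if (!dd) {
        ur <- uphys * ct - vphys * st
        re <- .oracleChainToReal(sx + (ur - sx) * mag, z * mag, m, L)
        fx <- re$x / g@detPixel[1] + (nc - 1) / 2
        fy <- re$y / g@detPixel[2] + (nr - 1) / 2
        x0 <- floor(fx); y0 <- floor(fy)
        for (a in 0:1) for (b in 0:1)
          add(y0 + a, x0 + b,
              (if (a) fy - y0 else 1 - (fy - y0)) *
                (if (b) fx - x0 else 1 - (fx - x0)))
      } else {
        if (latAxis) {
          ua <- uphys - g@voxel[1] / 2; ub <- uphys + g@voxel[1] / 2
          va <- vphys; vb <- vphys
        } else {
          ua <- uphys; ub <- uphys
          va <- vphys - g@voxel[2] / 2; vb <- vphys + g@voxel[2] / 2
        }
        ur1 <- ua * ct - va * st; vr1 <- ua * st + va * ct
        ur2 <- ub * ct - vb * st; vr2 <- ub * st + vb * ct
        den1 <- dso + vr1; den2 <- dso + vr2
        if (den1 <= 1e-9 || den2 <= 1e-9) next
        p1 <- .oracleChainToReal(sx + (ur1 - sx) * (L / den1),
                                 (z - g@voxel[3] / 2) * mag, m, L)
        p2 <- .oracleChainToReal(sx + (ur2 - sx) * (L / den2),
                                 (z + g@voxel[3] / 2) * mag, m, L)
        fx <- sort(c(p1$x, p2$x)) / g@detPixel[1] + (nc - 1) / 2
        fy <- sort(c(p1$y, p2$y)) / g@detPixel[2] + (nr - 1) / 2
        eps <- 1e-9
        if (fx[2] - fx[1] <= eps && fy[2] - fy[1] <= eps) {
          fxm <- mean(fx); fym <- mean(fy)
          x0 <- floor(fxm); y0 <- floor(fym)
          for (a in 0:1) for (b in 0:1)
            add(y0 + a, x0 + b,
                (if (a) fym - y0 else 1 - (fym - y0)) *
                  (if (b) fxm - x0 else 1 - (fxm - x0)))
        } else {
          xw <- .intervalWeights(fx[1], fx[2])
          yw <- .intervalWeights(fy[1], fy[2])
          for (xi in seq_len(nrow(xw))) for (yi in seq_len(nrow(yw)))
            add(yw$cell[yi], xw$cell[xi], xw$w[xi] * yw$w[yi])
        }
      }
    }
  }
  B
}

relErr <- function(a, b) {
  s <- max(abs(b))
  if (s == 0) max(abs(a - b)) else max(abs(a - b)) / s
}

uniformDeltaTheta <- function(vs) {
  th <- viewAngles(vs)
  if (length(th) == 1L) 2 * pi else diff(th)[1]
}
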