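test_that("projection is linear and zero volumes project to zero", {
  g <- tinyGeom()
  vs <- circularViews(360, 3, ini = 15, geometry = g)
  zero <- volume(array(0, g@volShape), g@voxel)
  expect_true(all(projectionData(projectVolume(zero, vs)) == 0))
  expect_true(all(projectionData(projectDistanceDriven(zero, vs)) == 0))

  set.seed(4)
  v1 <- volume(array(runif(512), g@volShape), g@voxel)
  v2 <- volume(array(runif(512), g@volShape), g@voxel)
  a <- 2.5; b <- -1.25
  mix <- volume(a * v1@data + b * v2@data, g@voxel)
  lhs <- projectionData(projectVolume(mix, vs))
  rhs <- a * projectionData(projectVolume(v1, vs)) +
    b * projectionData(projectVolume(v2, vs))
  expect_lt(relErr(lhs, rhs), 1e-12)
})

test_that("a single voxel projects where the pinhole oracle predicts", {
  g <- midGeom()
  set.seed(5)
  for (k in 1:8) {
    p <- runif(3, -6, 6)
    nvc <- nearestVoxelCenter(p, g)
    vol <- makePointGrid(list(nvc$center), g)
    m <- detectorMisalignment(
      xShift = runif(1, -3, 3), yShift = runif(1, -3, 3),
      skew = runif(1, -5, 5) * pi / 180, roll = runif(1, -5, 5) * pi / 180,
      tilt = runif(1, -5, 5) * pi / 180)
    th <- runif(1, 0, 2 * pi)
    stk <- projectVolume(vol, viewSet(list(view(th, m)), g))
    meas <- footprintCenter(projectionData(stk)[, , 1])
    pred <- pinholePredict(nvc$center, th, g, m)
    expect_lt(max(abs(meas - pred)), 0.5)
  }
})

test_that("the central ray through a voxelized ball integrates to the chord length", {
  # odd detector so one pixel sits exactly on the central ray
  g <- systemGeometry(500, 250, 65, 65, 1.5, c(64, 64, 64), 1)
  r <- 20; mu <- 1
  vol <- makeEllipsoidPhantom(list(ellipsoidSpec(semiAxes = c(r, r, r),
                                                 value = mu)), g)
  pol <- samplingPolicy(step = 0.5, geometry = g)
  stk <- projectVolume(vol, circularViews(360, 1, geometry = g), pol)
  central <- projectionData(stk)[33, 33, 1]
  expect_lt(abs(central - 2 * r * mu) / (2 * r * mu), 0.02)
})

test_that("projections shift with whole-voxel z translations of the volume", {
  g <- systemGeometry(500, 250, 64, 64, 1.5, c(32, 32, 32), 1)
  spec <- list(ellipsoidSpec(c(2, 1, -3), c(6, 5, 4), 0, 1))
  vol <- makeEllipsoidPhantom(spec, g)
  k <- 3
  volShift <- makeEllipsoidPhantom(
    list(ellipsoidSpec(c(2, 1, -3 + k * g@voxel[3]), c(6, 5, 4), 0, 1)), g)
  vs <- circularViews(360, 2, geometry = g)
  p0 <- projectionData(projectVolume(vol, vs))
  p1 <- projectionData(projectVolume(volShift, vs))
  # detector-row shift predicted by the isocentre magnification
  mag <- (g@dso + g@ddo) / g@dso
  rowShift <- k * mag * g@voxel[3] / g@detPixel[2]
  sh <- round(rowShift)
  expect_lt(abs(rowShift - sh), 0.35)  # setup chosen near-integer
  inner <- (1 + sh):64
  d <- abs(p1[inner, , ] - p0[inner - sh, , ])
  expect_lt(max(d) / max(p0), 0.08)  # within interpolation tolerance
})

# smooth z-axis-symmetric test object: Gaussian in radius and in z
smoothRadialPhantom <- function(g, sigmaR = 8, sigmaZ = 8) {
  sh <- g@volShape
  u <- centeredCoords(sh[1], g@voxel[1])
  v <- centeredCoords(sh[2], g@voxel[2])
  z <- centeredCoords(sh[3], g@voxel[3])
  r2 <- outer(u, v, function(a, b) a^2 + b^2)
  arr <- array(0, sh)
  for (k in seq_len(sh[3]))
    arr[, , k] <- exp(-r2 / (2 * sigmaR^2)) * exp(-z[k]^2 / (2 * sigmaZ^2))
  volume(arr, g@voxel)
}

test_that("projections of a z-symmetric phantom agree across angles", {
  g <- systemGeometry(500, 250, 64, 64, 1.5, c(32, 32, 32), 1)
  vol <- smoothRadialPhantom(g, sigmaR = 4, sigmaZ = 5)
  vs <- circularViews(360, 8, geometry = g)
  p <- projectionData(projectVolume(vol, vs))
  ref <- p[, , 1]
  keep <- ref > 0.1 * max(ref)
  for (i in 2:8) {
    dev <- abs(p[, , i][keep] - ref[keep]) / max(ref)
    expect_lt(max(dev), 0.02)
  }
})

test_that("zero misalignment equals the separately coded ideal projector exactly", {
  g <- tinyGeom()
  set.seed(6)
  vol <- volume(array(runif(512), g@volShape), g@voxel)
  vs <- circularViews(360, 5, ini = 7, geometry = g)
  pol <- samplingPolicy(geometry = g)
  got <- projectionData(projectVolume(vol, vs, pol))
  ref <- coneBeamSim:::cpp_project_ideal(
    as.numeric(vol@data), dim(vol@data), g@voxel, g@detRows, g@detCols,
    g@detPixel, viewAngles(vs), g@dso, g@ddo, pol@step, pol@rad)
  expect_identical(as.numeric(got), as.numeric(ref))
})

test_that("halving the integration step barely changes smooth projections", {
  g <- systemGeometry(500, 250, 32, 32, 3, c(32, 32, 32), 1)
  vol <- smoothRadialPhantom(g, sigmaR = 5, sigmaZ = 5)
  vs <- circularViews(360, 2, ini = 20, geometry = g)
  p1 <- projectionData(projectVolume(vol, vs, samplingPolicy(
    step = 1, geometry = g)))
  p2 <- projectionData(projectVolume(vol, vs, samplingPolicy(
    step = 0.5, geometry = g)))
  keep <- p2 > 0.2 * max(p2)
  expect_lt(max(abs(p1[keep] - p2[keep]) / p2[keep]), 0.01)
})

test_that("distance-driven overlap weights are a partition of unity", {
  g <- systemGeometry(400, 200, 24, 24, 2, c(16, 16, 16), 1.5)
  volc <- volume(array(1, c(16, 16, 16)), 1.5)
  vs <- circularViews(360, 5, ini = 10, geometry = g)
  # rad small enough that central rays stay inside the constant cube
  pol <- samplingPolicy(step = 1, rad = 7, geometry = g)
  pr <- projectionData(projectVolume(volc, vs, pol))
  pd <- projectionData(projectDistanceDriven(volc, vs, pol))
  cen <- 11:14
  expect_lt(max(abs(pr[cen, cen, ] - pd[cen, cen, ]) / pr[cen, cen, ]), 0.01)
})

test_that("both projection modes match independently built dense system matrices", {
  g <- tinyGeom()
  vs <- circularViews(360, 4, ini = 10, geometry = g)
  set.seed(7)
  vol <- volume(array(runif(512), g@volShape), g@voxel)
  for (mode in c("ray_driven", "distance_driven")) {
    pol <- samplingPolicy(step = 2, rad = 12, mode = mode, geometry = g)
    A <- denseProjectorMatrix(g, vs, pol)
    expected <- array(A %*% as.numeric(vol@data),
                      c(g@detRows, g@detCols, 4))
    got <- projectionData(projectVolume(vol, vs, pol))
    expect_lt(relErr(got, expected), 1e-5)
  }
})
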