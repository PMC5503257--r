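test_that("circular views are evenly spaced and end-exclusive", {
  g <- tinyGeom()
  vs <- circularViews(360, 4, geometry = g)
  expect_equal(viewAngles(vs), c(0, 90, 180, 270) * pi / 180)
  expect_equal(viewAngles(circularViews(360, 1, ini = 33, geometry = g)),
               33 * pi / 180)
  vs360 <- circularViews(360, 360, geometry = g)
  expect_equal(diff(viewAngles(vs360))[1], pi / 180)
  expect_error(circularViews(360, 0, geometry = g), ">= 1")
})

test_that("helical bed travel reproduces the pitch and degenerates to circular", {
  g <- tinyGeom()
  # whole-body style inputs: pitch 62 mm, 360 views/rotation, 0.125 mm slices
  hv <- helicalViews(pitch = 62, span = 360, n = 360, thick = 0.125,
                     geometry = g)
  zs <- vapply(hv@views, slot, numeric(1), "zShift")
  inc <- zs[2] - zs[1]
  expect_equal(inc, 62 / (360 * 0.125), tolerance = 1e-12)  # 1.3777... vox
  # after one full rotation the cumulative travel is exactly the pitch
  expect_equal(360 * inc * 0.125, 62, tolerance = 1e-12)
  # pitch 0 equals the circular scan exactly
  h0 <- helicalViews(pitch = 0, span = 360, n = 8, thick = 0.125,
                     geometry = g)
  cv <- circularViews(360, 8, geometry = g)
  expect_equal(viewAngles(h0), viewAngles(cv))
  expect_true(all(vapply(h0@views, slot, numeric(1), "zShift") == 0))
  # two rotations span twice the per-rotation travel in voxels
  h2 <- helicalViews(pitch = 10, span = 720, n = 36, thick = 0.5,
                     geometry = g)
  zs2 <- vapply(h2@views, slot, numeric(1), "zShift")
  expect_equal(length(zs2), 72L)
  expect_equal(max(zs2) - min(zs2), (72 - 1) / 72 * 2 * 10 / 0.5,
               tolerance = 1e-12)
  expect_equal(zs2[37] * 0.5, 10, tolerance = 1e-12)  # one rotation later
})

test_that("arbitrary poses decompose into the expected view parameters", {
  g <- systemGeometry(500, 250, 64, 64, 1, c(16, 16, 16), 1)
  # ideal circular pose at theta
  th <- 0.9
  d <- c(sin(th), cos(th), 0)
  ex <- c(cos(th), -sin(th), 0)
  ideal <- list(center = 250 * d, normal = -d, xaxis = ex)
  vs <- arbitraryToViews(list(-500 * d), list(ideal), g)
  v <- vs@views[[1]]
  expect_equal(v@theta, th, tolerance = 1e-12)
  m <- v@misalignment
  expect_equal(c(m@xShift, m@yShift, m@skew, m@roll, m@tilt), rep(0, 5),
               tolerance = 1e-9)
  # detector translated 5 mm along its own x-axis
  shifted <- list(center = 250 * d + 5 * ex, normal = -d, xaxis = ex)
  vsh <- arbitraryToViews(list(-500 * d), list(shifted), g)@views[[1]]
  expect_equal(vsh@misalignment@xShift, 5, tolerance = 1e-9)
  expect_equal(c(vsh@misalignment@skew, vsh@misalignment@roll,
                 vsh@misalignment@tilt), rep(0, 3), tolerance = 1e-9)
  # detector rotated 3 degrees about the u axis through its centre
  a <- 3 * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  tilted <- list(center = c(0, 250, 0),
                 normal = as.numeric(Rx %*% c(0, -1, 0)),
                 xaxis = as.numeric(Rx %*% c(1, 0, 0)))
  vt <- arbitraryToViews(list(c(0, -500, 0)), list(tilted), g)@views[[1]]
  expect_equal(vt@misalignment@tilt, a, tolerance = 1e-9)
  expect_equal(c(vt@misalignment@xShift, vt@misalignment@yShift,
                 vt@misalignment@skew, vt@misalignment@roll), rep(0, 4),
               tolerance = 1e-9)
})

test_that("pose -> view -> pose round trips are exact", {
  g <- systemGeometry(500, 250, 64, 64, 1, c(16, 16, 16), 1)
  set.seed(14)
  for (k in 1:10) {
    th <- runif(1, 0, 2 * pi)
    fr <- list(d = c(sin(th), cos(th), 0),
               ex = c(cos(th), -sin(th), 0), ey = c(0, 0, 1))
    # random small rotation of the detector frame + in-plane offsets
    ang <- runif(3, -0.1, 0.1)
    Ry <- rbind(c(cos(ang[1]), 0, sin(ang[1])), c(0, 1, 0),
                c(-sin(ang[1]), 0, cos(ang[1])))
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[2]), -sin(ang[2])),
                c(0, sin(ang[2]), cos(ang[2])))
    Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    B <- cbind(fr$ex, fr$ey, -fr$d)
    M <- Ry %*% Rx %*% Rz
    ex <- as.numeric(B %*% M[, 1])
    ey <- as.numeric(B %*% M[, 2])
    n <- as.numeric(B %*% M[, 3])
    C <- 250 * fr$d + runif(1, -8, 8) * ex + runif(1, -8, 8) * ey
    pose <- list(center = C, normal = n, xaxis = ex)
    vset <- arbitraryToViews(list(-500 * fr$d), list(pose), g)
    rt <- viewPose(vset@views[[1]], g)
    expect_lt(max(abs(rt$pose$center - C)), 1e-9)
    expect_lt(max(abs(rt$pose$normal - n)), 1e-9)
    expect_lt(max(abs(rt$pose$xaxis - ex)), 1e-9)
    expect_lt(max(abs(rt$source - (-500 * fr$d))), 1e-9)
  }
})

test_that("tomosynthesis configurations satisfy the printed size relations", {
  g <- systemGeometry(950, 100, 64, 64, 0.4, c(17, 17, 17), 1)
  # single central view: large detector equals the real detector
  t1 <- tomosynthesisViews(tomoConfig("linear", nViews = 1, sxMax = 0), g)
  expect_equal(t1$dLarge, 64 * 0.4)
  expect_equal(t1$rois$centerMm, 0)
  # linear with FP = 0: Dx = Sx * DDO / DSO
  cfg <- tomoConfig("linear", nViews = 5, fp = 0, sxMax = 100)
  tv <- tomosynthesisViews(cfg, g)
  sx <- vapply(tv$views@views, slot, numeric(1), "sourceX")
  expect_equal(sx, seq(-100, 100, length.out = 5))
  expect_equal(tv$rois$centerMm, -sx * 100 / 950, tolerance = 1e-12)
  expect_equal(tv$dLarge, 2 * 100 * (1 + 100 / 950) + 64 * 0.4,
               tolerance = 1e-12)
  # arc at zero angle: Sx = 0 and DSO' = DSO
  ta <- tomosynthesisViews(tomoConfig("arc", nViews = 1, sBetaMax = 0), g)
  va <- ta$views@views[[1]]
  expect_equal(va@sourceX, 0)
  expect_true(is.na(va@dsoOverride) || va@dsoOverride == g@dso)
  # arc flavor distances follow the arc about the focal-plane centre
  tb <- tomosynthesisViews(tomoConfig("arc", nViews = 3, fp = 50,
                                      sBetaMax = 5 * pi / 180), g)
  vfirst <- tb$views@views[[1]]
  sb <- -5 * pi / 180
  expect_equal(vfirst@sourceX, sin(sb) * (950 - 50), tolerance = 1e-12)
  expect_equal(vfirst@dsoOverride, cos(sb) * (950 - 50) + 50,
               tolerance = 1e-12)
  expect_error(tomosynthesisViews(
    tomoConfig("linear", nViews = 3, fp = 1000, sxMax = 10), g),
    "focal plane")
})

test_that("focal-plane points stay fixed across tomosynthesis views; off-plane points drift", {
  # odd-sized volume so voxel centres sit exactly on the focal plane
  g <- systemGeometry(950, 100, 64, 64, 0.4, c(17, 17, 17), 1)
  for (flavor in c("linear", "arc")) {
    cfg <- if (flavor == "linear")
      tomoConfig("linear", nViews = 9, fp = 0, sxMax = 150)
    else
      tomoConfig("arc", nViews = 9, fp = 0, sBetaMax = 5 * pi / 180)
    tv <- tomosynthesisViews(cfg, g)
    vg <- tv$virtualGeom
    onFp <- makePointGrid(list(c(3, 0, 2)), vg)
    offFp <- makePointGrid(list(c(3, -5, 2)), vg)
    pol <- samplingPolicy(step = 0.8, geometry = vg)
    rel <- function(vol) {
      stk <- projectVolume(vol, tv$views, pol)
      vapply(seq_len(nViews(stk)), function(i) {
        com <- footprintCenter(projectionData(stk)[, , i])
        com["x"] - tv$rois$centerPx[i]
      }, numeric(1))
    }
    drift <- rel(onFp)
    expect_lt(max(drift) - min(drift), 0.5)
    off <- rel(offFp)
    expect_true(all(diff(off) > 0) || all(diff(off) < 0))
  }
})

test_that("wide-FOV ROIs tile the virtual detector with the requested overlap", {
  g <- systemGeometry(500, 250, 64, 512, 0.5, c(16, 16, 16), 1)
  cfg <- wideFovConfig("tilting", nPositions = 2, overlap = 64)
  expect_warning(wf <- wideFovViews(cfg, g), "ROI union")
  expect_equal(wf$dLarge, 2 * (512 - 64))           # as printed
  expect_equal(wf$virtualGeom@detCols, 2L * 512L - 64L)  # exact union
  expect_equal(wf$rois$centerPx, c(256, 704))
  # consecutive ROIs overlap by exactly the requested pixels and the union
  # covers the virtual detector
  expect_equal(wf$rois$x0, c(0L, 448L))
  expect_equal(wf$rois$x1, c(512L, 960L))
  expect_equal(wf$rois$x0[2], wf$rois$x1[1] - 64L)
  expect_equal(wf$rois$x1[2], wf$virtualGeom@detCols)
  # N = 1 degenerates to the real detector, no warning
  w1 <- wideFovViews(wideFovConfig("tilting", nPositions = 1), g)
  expect_equal(w1$virtualGeom@detCols, 512L)
  expect_equal(w1$dLarge, 512)
  # general tiling closure for several N / overlap combinations
  for (N in c(3L, 4L)) for (ov in c(0L, 32L)) {
    wfN <- withCallingHandlers(
      wideFovViews(wideFovConfig("tilting", N, ov), g),
      warning = function(w) invokeRestart("muffleWarning"))
    expect_equal(wfN$rois$x0[1], 0L)
    expect_equal(wfN$rois$x1[N], wfN$virtualGeom@detCols)
    if (N > 1) {
      expect_true(all(wfN$rois$x1[-N] - wfN$rois$x0[-1] == ov))
    }
  }
  expect_error(wideFovViews(wideFovConfig("tilting", 2, overlap = 512), g),
               "overlap")
})

test_that("wide-FOV linear displacement steps the volume along z", {
  g <- systemGeometry(500, 250, 128, 64, 0.5, c(16, 16, 32), 1)
  wf <- wideFovViews(wideFovConfig("linear_displacement", 3, overlap = 8), g)
  zs <- vapply(wf$views@views, slot, numeric(1), "zShift")
  expect_equal(length(zs), 3L)
  expect_equal(mean(zs), 0)                    # symmetric about the centre
  step <- diff(zs)[1]
  expect_equal(diff(zs), rep(step, 2))
  # footprint advance at the isocentre equals (rows - overlap) pixels
  expect_equal(step * 1, (128 - 8) * 0.5 * 500 / 750, tolerance = 1e-12)
})
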