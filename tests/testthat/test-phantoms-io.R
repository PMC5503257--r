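test_that("ellipsoid voxelisation matches the analytic volume up to a surface term", {
  g <- systemGeometry(500, 250, 16, 16, 1, c(48, 48, 48), 1)
  expect_true(all(volumeData(makeEllipsoidPhantom(list(), g)) == 0))
  r <- 14
  ball <- makeEllipsoidPhantom(list(ellipsoidSpec(semiAxes = c(r, r, r))), g)
  count <- sum(volumeData(ball) > 0)
  analytic <- 4 / 3 * pi * r^3
  surface <- 4 * pi * r^2 * max(g@voxel)
  expect_lt(abs(count - analytic), surface)
  # disjoint ellipsoids never exceed the larger single value
  two <- makeEllipsoidPhantom(list(
    ellipsoidSpec(c(-10, 0, 0), c(5, 4, 4), 0, 1),
    ellipsoidSpec(c(10, 0, 0), c(5, 4, 4), 0, 2)), g)
  expect_equal(max(volumeData(two)), 2)
  # overlapping ellipsoids add
  over <- makeEllipsoidPhantom(list(
    ellipsoidSpec(c(0, 0, 0), c(5, 5, 5), 0, 1),
    ellipsoidSpec(c(0, 0, 0), c(3, 3, 3), 0, 0.5)), g)
  expect_equal(max(volumeData(over)), 1.5)
})

test_that("point grids land on the nearest voxel and round-trip within half a voxel", {
  g <- systemGeometry(500, 250, 16, 16, 1, c(17, 17, 17), 1)
  ctr <- makePointGrid(list(c(0, 0, 0)), g)
  expect_equal(sum(volumeData(ctr) != 0), 1L)
  expect_equal(volumeData(ctr)[9, 9, 9], 1)
  corners <- expand.grid(u = c(-6, 6), v = c(-6, 6), z = c(-6, 6))
  grid <- makePointGrid(as.matrix(corners), g)
  expect_equal(sum(volumeData(grid) != 0), 8L)
  set.seed(17)
  for (k in 1:20) {
    p <- runif(3, -7, 7)
    nvc <- nearestVoxelCenter(p, g)
    expect_true(all(abs(nvc$center - p) <= g@voxel / 2 + 1e-12))
  }
  expect_error(makePointGrid(list(c(100, 0, 0)), g), "outside")
})

test_that("native volume containers round-trip losslessly", {
  g <- tinyGeom()
  set.seed(18)
  vol <- volume(array(rnorm(512), g@volShape), g@voxel)
  path <- file.path(tempdir(), "vol.raw")
  writeVolume(vol, path)
  back <- readVolume(path)
  expect_identical(volumeData(back), volumeData(vol))
  expect_identical(back@voxel, vol@voxel)
  # big-endian flag honoured: payload bytes differ, values identical
  pb <- file.path(tempdir(), "vol_be.raw")
  writeVolume(vol, pb, byteOrder = "big")
  expect_identical(volumeData(readVolume(pb)), volumeData(vol))
  b1 <- readBin(path, "raw", 16)
  b2 <- readBin(pb, "raw", 16)
  expect_identical(b1[1:8], rev(b2[1:8]))  # explicit byte-swap oracle
  # truncated payloads are a format error
  writeBin(readBin(path, "raw", 100), file.path(tempdir(), "trunc.raw"))
  file.copy(paste0(path, ".json"), file.path(tempdir(), "trunc.raw.json"),
            overwrite = TRUE)
  expect_error(readVolume(file.path(tempdir(), "trunc.raw")), "truncated")
})

test_that("projection containers carry their per-view geometry", {
  g <- tinyGeom()
  vs <- helicalViews(pitch = 4, span = 360, n = 4, thick = 2, geometry = g)
  vs@views[[2]]@misalignment <- detectorMisalignment(xShift = 1.5,
                                                     tilt = 0.02)
  vs@views[[3]]@dsoOverride <- 55
  set.seed(19)
  stk <- projectionStack(array(rnorm(12 * 12 * 4), c(12, 12, 4)),
                         g@detPixel, vs)
  path <- file.path(tempdir(), "proj.raw")
  writeProjections(stk, path)
  back <- readProjections(path)
  expect_identical(projectionData(back), projectionData(stk))
  expect_equal(viewAngles(back), viewAngles(stk))
  expect_equal(back@views@views[[2]]@misalignment@xShift, 1.5)
  expect_equal(back@views@views[[2]]@misalignment@tilt, 0.02)
  expect_equal(vapply(back@views@views, slot, numeric(1), "zShift"),
               vapply(vs@views, slot, numeric(1), "zShift"))
  expect_equal(geometry(back)@dso, g@dso)
  expect_equal(back@views@views[[3]]@dsoOverride, 55)
  expect_true(is.na(back@views@views[[1]]@dsoOverride))
  # kind mismatch is a format error naming the content
  expect_error(readVolume(path), "not a volume")
})

test_that("float32 containers round-trip float32-representable data", {
  g <- tinyGeom()
  vals <- array(as.numeric(signif(seq_len(512), 6)) / 64, g@volShape)
  vol <- volume(vals, g@voxel)
  path <- file.path(tempdir(), "vol32.raw")
  writeVolume(vol, path, dtype = "float32")
  expect_equal(volumeData(readVolume(path)), vals, tolerance = 1e-7)
  expect_equal(file.info(path)$size, 512 * 4)
})

test_that("TIFF stacks are readable as volumes", {
  skip_if_not_installed("tiff")
  arr <- array(runif(6 * 5 * 4), c(6, 5, 4))
  path <- file.path(tempdir(), "stack.tif")
  # TIFF pages are (y, x); store transposed slices
  tiff::writeTIFF(lapply(seq_len(4), function(k) t(arr[, , k])), path,
                  bits.per.sample = 32L)
  vol <- readVolume(path)
  expect_equal(dim(volumeData(vol)), c(6L, 5L, 4L))
  expect_equal(volumeData(vol), arr, tolerance = 1e-6)
})

test_that("MetaImage headers are readable", {
  dir <- tempdir()
  raw <- file.path(dir, "mhd_payload.raw")
  arr <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  con <- file(raw, "wb")
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  close(con)
  hdr <- file.path(dir, "test.mhd")
  writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 4 3 2",
               "ElementSpacing = 0.5 0.5 1",
               "ElementType = MET_FLOAT",
               "ElementDataFile = mhd_payload.raw"), hdr)
  vol <- readVolume(hdr)
  expect_equal(dim(volumeData(vol)), c(4L, 3L, 2L))
  expect_equal(vol@voxel, c(0.5, 0.5, 1))
  expect_equal(volumeData(vol), arr, tolerance = 1e-6)
  # missing fields are format errors naming the field
  bad <- file.path(dir, "bad.mhd")
  writeLines(c("ObjectType = Image", "DimSize = 4 3 2"), bad)
  expect_error(readVolume(bad), "ElementType")
})

test_that("calibration files populate views and default absent columns", {
  dir <- tempdir()
  cal <- file.path(dir, "cal.txt")
  writeLines(c("theta_deg", "0", "90", "180", "270"), cal)
  g <- tinyGeom()
  vs <- readCalibration(cal, g)
  expect_equal(nViews(vs), 4L)
  expect_equal(viewAngles(vs), c(0, 90, 180, 270) * pi / 180)
  m <- vs@views[[1]]@misalignment
  expect_true(all(c(m@xShift, m@yShift, m@skew, m@roll, m@tilt) == 0))

  cal2 <- file.path(dir, "cal2.csv")
  writeLines(c("theta_deg,tilt_deg,x_shift_mm",
               "0,1.5,0.3", "90,-2,0"), cal2)
  vs2 <- readCalibration(cal2, g)
  expect_equal(vs2@views[[1]]@misalignment@tilt, 1.5 * pi / 180)
  expect_equal(vs2@views[[2]]@misalignment@tilt, -2 * pi / 180)
  expect_equal(vs2@views[[1]]@misalignment@xShift, 0.3)
  expect_equal(viewAngles(vs2)[2], pi / 2)

  bad <- file.path(dir, "bad_cal.txt")
  writeLines(c("theta_deg x_shift_mm", "0 1", "90"), bad)
  expect_error(readCalibration(bad, g), "malformed|elements")
})
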