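#' Volume and projection-stack containers on disk
#'
#' The native container is a raw binary payload (little- or big-endian
#' float32/float64, column-major) plus a JSON sidecar header
#' (\code{<path>.json}) holding the shape, element sizes, data type, byte
#' order, payload offset and, for projection stacks, the per-view geometry.
#' TIFF stacks (via the \pkg{tiff} package) and MetaImage (\code{.mhd})
#' headers are supported read-only for volumes.
#'
#' @param vol a \linkS4class{Volume}.
#' @param path file path; the sidecar header is written next to it.
#' @param dtype "float64" (lossless for R data, default) or "float32".
#' @param byteOrder "little" (default) or "big".
#' @return \code{readVolume} returns a \linkS4class{Volume};
#'   \code{writeVolume} returns \code{path} invisibly.
#' @name volume-io
NULL

.dtypeSize <- function(dtype)
  switch(dtype, float32 = 4L, float64 = 8L,
         stop(sprintf("unknown data type '%s' in header", dtype)))

.writeHeader <- function(path, header) {
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.readHeader <- function(path) {
  hpath <- paste0(path, ".json")
  if (!file.exists(hpath))
    stop(sprintf("missing header file '%s'", hpath))
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  for (f in c("shape", "dtype", "byte_order"))
    if (is.null(h[[f]]))
      stop(sprintf("header is missing required field '%s'", f))
  h
}

.readPayload <- function(path, h) {
  n <- prod(h$shape)
  size <- .dtypeSize(h$dtype)
  offset <- if (is.null(h$offset)) 0L else as.integer(h$offset)
  expect <- offset + n * size
  if (file.info(path)$size < expect)
    stop(sprintf("payload truncated: %d bytes present, %d expected",
                 file.info(path)$size, expect))
  con <- file(path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  endian <- if (identical(h$byte_order, "big")) "big" else "little"
  readBin(con, "double", n = n, size = size, endian = endian)
}

.writePayload <- function(path, data, dtype, byteOrder) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(data), con, size = .dtypeSize(dtype),
           endian = if (byteOrder == "big") "big" else "little")
}

#' @rdname volume-io
#' @export
writeVolume <- function(vol, path, dtype = c("float64", "float32"),
                        byteOrder = c("little", "big")) {
  stopifnot(is(vol, "Volume"))
  dtype <- match.arg(dtype)
  byteOrder <- match.arg(byteOrder)
  .writePayload(path, vol@data, dtype, byteOrder)
  .writeHeader(path, list(kind = "volume", shape = dim(vol@data),
                          voxel_mm = vol@voxel, dtype = dtype,
                          byte_order = byteOrder, offset = 0L))
  invisible(path)
}

#' @rdname volume-io
#' @export
readVolume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return(.readTiffVolume(path))
  if (ext == "mhd") return(.readMhdVolume(path))
  h <- .readHeader(path)
  if (!identical(h$kind, "volume"))
    stop(sprintf("container holds '%s', not a volume", h$kind))
  data <- array(.readPayload(path, h), dim = h$shape)
  voxel <- if (is.null(h$voxel_mm)) c(1, 1, 1) else as.numeric(h$voxel_mm)
  volume(data, voxel)
}

.readTiffVolume <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    t(p)  # TIFF rows are y; store (u, v) = (x, y)
  }))
  volume(arr, c(1, 1, 1))
}

.readMhdVolume <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) == 2L)
      kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  need <- c("DimSize", "ElementType", "ElementDataFile")
  for (f in need)
    if (is.null(kv[[f]]))
      stop(sprintf("MetaImage header is missing field '%s'", f))
  shape <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  dtype <- switch(kv$ElementType,
                  MET_FLOAT = "float32", MET_DOUBLE = "float64",
                  stop(sprintf("unsupported MetaImage ElementType '%s'",
                               kv$ElementType)))
  spacing <- if (is.null(kv$ElementSpacing)) rep(1, length(shape)) else
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]])
  endian <- if (identical(kv$BinaryDataByteOrderMSB, "True")) "big" else
    "little"
  raw <- file.path(dirname(path), kv$ElementDataFile)
  if (!file.exists(raw))
    stop(sprintf("MetaImage payload '%s' not found", raw))
  n <- prod(shape)
  con <- file(raw, "rb")
  on.exit(close(con))
  data <- readBin(con, "double", n = n, size = .dtypeSize(dtype),
                  endian = endian)
  if (length(data) < n) stop("payload truncated")
  volume(array(data, dim = shape), spacing)
}

.viewsToTable <- function(vs) {
  do.call(rbind, lapply(vs@views, function(v) {
    m <- v@misalignment
    data.frame(theta = v@theta, x_shift = m@xShift, y_shift = m@yShift,
               skew = m@skew, roll = m@roll, tilt = m@tilt,
               z_shift = v@zShift, dso = v@dsoOverride,
               ddo = v@ddoOverride, source_x = v@sourceX,
               roi_center_x = v@roiCenterX)
  }))
}

.tableToViews <- function(tab, geometry) {
  n <- nrow(tab)
  # all-NA columns are dropped by the JSON serialiser; restore defaults
  gcol <- function(name, default = 0) {
    x <- tab[[name]]
    if (is.null(x)) rep(default, n) else as.numeric(x)
  }
  theta <- gcol("theta"); xs <- gcol("x_shift"); ys <- gcol("y_shift")
  skew <- gcol("skew"); roll <- gcol("roll"); tilt <- gcol("tilt")
  zs <- gcol("z_shift"); srcx <- gcol("source_x")
  dso <- gcol("dso", NA_real_); ddo <- gcol("ddo", NA_real_)
  roi <- gcol("roi_center_x", NA_real_)
  views <- lapply(seq_len(n), function(i)
    view(theta = theta[i],
         misalignment = detectorMisalignment(xs[i], ys[i], skew[i],
                                             roll[i], tilt[i]),
         zShift = zs[i], dsoOverride = dso[i], ddoOverride = ddo[i],
         sourceX = srcx[i], roiCenterX = roi[i]))
  viewSet(views, geometry)
}

.geomToList <- function(g)
  list(dso = g@dso, ddo = g@ddo, det_rows = g@detRows, det_cols = g@detCols,
       det_pixel = g@detPixel, vol_shape = g@volShape, voxel = g@voxel)

.listToGeom <- function(l)
  systemGeometry(l$dso, l$ddo, l$det_rows, l$det_cols,
                 as.numeric(l$det_pixel), as.integer(l$vol_shape),
                 as.numeric(l$voxel))

#' @rdname volume-io
#' @param stack a \linkS4class{ProjectionStack}.
#' @export
writeProjections <- function(stack, path, dtype = c("float64", "float32"),
                             byteOrder = c("little", "big")) {
  stopifnot(is(stack, "ProjectionStack"))
  dtype <- match.arg(dtype)
  byteOrder <- match.arg(byteOrder)
  .writePayload(path, stack@data, dtype, byteOrder)
  .writeHeader(path, list(kind = "projections", shape = dim(stack@data),
                          pixel_mm = stack@pixel, dtype = dtype,
                          byte_order = byteOrder, offset = 0L,
                          geometry = .geomToList(stack@views@geometry),
                          views = .viewsToTable(stack@views)))
  invisible(path)
}

#' @rdname volume-io
#' @export
readProjections <- function(path) {
  h <- .readHeader(path)
  if (!identical(h$kind, "projections"))
    stop(sprintf("container holds '%s', not projections", h$kind))
  data <- array(.readPayload(path, h), dim = h$shape)
  g <- .listToGeom(h$geometry)
  vs <- .tableToViews(as.data.frame(h$views), g)
  projectionStack(data, as.numeric(h$pixel_mm), vs)
}

#' Read a per-view calibration file
#'
#' One delimited-text line per view with named columns; recognised columns
#' are \code{theta_deg}, \code{x_shift_mm}, \code{y_shift_mm},
#' \code{skew_deg}, \code{roll_deg}, \code{tilt_deg}, \code{z_shift_vox},
#' \code{dso_mm}, \code{ddo_mm} and \code{roi_center_x_mm}.  Missing
#' columns default to the ideal values; angles are converted from degrees
#' to radians.
#'
#' @param path calibration file path (whitespace- or comma-delimited with a
#'   header line).
#' @param geometry the shared \linkS4class{SystemGeometry}.
#' @return A \linkS4class{ViewSet}.
#' @export
readCalibration <- function(path, geometry) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("malformed calibration file: %s",
                                     conditionMessage(e))))
  if (is.null(tab$theta_deg))
    stop("calibration file must have a 'theta_deg' column")
  n <- nrow(tab)
  col <- function(name, default) {
    x <- tab[[name]]
    if (is.null(x)) rep(default, n) else {
      if (any(is.na(x)))
        stop(sprintf("malformed calibration value in column '%s' (line %d)",
                     name, which(is.na(x))[1] + 1L))
      x
    }
  }
  deg <- pi / 180
  views <- lapply(seq_len(n), function(i) {
    view(theta = col("theta_deg", 0)[i] * deg,
         misalignment = detectorMisalignment(
           xShift = col("x_shift_mm", 0)[i],
           yShift = col("y_shift_mm", 0)[i],
           skew = col("skew_deg", 0)[i] * deg,
           roll = col("roll_deg", 0)[i] * deg,
           tilt = col("tilt_deg", 0)[i] * deg),
         zShift = col("z_shift_vox", 0)[i],
         dsoOverride = col("dso_mm", NA_real_)[i],
         ddoOverride = col("ddo_mm", NA_real_)[i],
         roiCenterX = col("roi_center_x_mm", NA_real_)[i])
  })
  viewSet(views, geometry)
}
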