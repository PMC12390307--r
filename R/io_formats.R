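#' On-disk formats and the capture-frame container
#'
#' A capture frame bundles everything one smartphone snapshot provides: the
#' RGB image (H x W x 3), the low-resolution LiDAR depth grid (meters, `NA`
#' invalid), the 3x4 projection matrix and the unit gravity vector (pointing
#' toward the earth, camera/world frame). Depth files come in two dialects:
#' 16-bit grayscale PNG in millimeters (0 = invalid) and a plain-text float
#' matrix in meters (non-finite = invalid). Masks are 8-bit 0/255 PNG.
#' Intrinsics, gravity, configuration and results are JSON.
#'
#' @name io-formats
NULL

DEPTH_RANGE_M <- c(0.25, 5.0)

#' Construct and validate a capture frame
#'
#' @param rgb H x W x 3 numeric array in `[0, 1]` (may be `NULL` for
#'   depth-only work; resolutions then default to the depth grid scaled).
#' @param depth_low h x w depth matrix in meters, `NA` = invalid. Finite
#'   negative values are a validation error; positive values outside the
#'   sensor range 0.25–5 m are marked invalid.
#' @param projection 3x4 projection matrix (rank 3).
#' @param gravity unit 3-vector pointing toward the earth.
#' @param meta optional list (capture id etc.).
#' @param rgb_shape c(H, W) of the RGB grid; required when `rgb` is `NULL`
#'   (the pipeline reconstructs the point map at this resolution).
#' @return object of class `capture_frame`.
#' @export
capture_frame <- function(rgb, depth_low, projection, gravity, meta = list(),
                          rgb_shape = NULL) {
  stopifnot(is.matrix(depth_low))
  if (any(depth_low[is.finite(depth_low)] < 0))
    stop("validation error: negative depth values")
  depth_low[!is.finite(depth_low)] <- NA_real_
  depth_low[!is.na(depth_low) &
              (depth_low < DEPTH_RANGE_M[1] | depth_low > DEPTH_RANGE_M[2])] <- NA_real_
  if (abs(sqrt(sum(gravity^2)) - 1) > 1e-6)
    stop("validation error: gravity must be a unit vector")
  if (!is.matrix(projection) || nrow(projection) != 3 || ncol(projection) != 4 ||
      qr(projection)$rank < 3)
    stop("validation error: projection must be a rank-3 3x4 matrix")
  if (!is.null(rgb)) stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  shape <- if (!is.null(rgb)) dim(rgb)[1:2]
    else if (!is.null(rgb_shape)) as.integer(rgb_shape)
    else dim(depth_low)
  structure(list(rgb = rgb, depth_low = depth_low,
                 projection = projection, gravity = as.numeric(gravity),
                 meta = c(meta, list(rgb_shape = shape,
                                     depth_shape = dim(depth_low)))),
            class = "capture_frame")
}

#' Load a capture frame from disk
#'
#' @param paths named list with elements `rgb` (PNG, optional), `depth`
#'   (PNG or text), `projection` (JSON: either a 3x4 `P` or `fx,fy,cx,cy`),
#'   `gravity` (JSON with a `gravity` 3-vector).
#' @param depth_units `"mm16"` for the 16-bit PNG millimeter dialect,
#'   `"m"` for the plain-text meter dialect.
#' @return a [capture_frame()].
#' @export
load_frame <- function(paths, depth_units = c("mm16", "m")) {
  depth_units <- match.arg(depth_units)
  for (nm in c("depth", "projection", "gravity"))
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]]))
      stop("load error: missing file for '", nm, "': ",
           if (is.null(paths[[nm]])) "<unset>" else paths[[nm]])
  rgb <- NULL
  if (!is.null(paths$rgb)) {
    if (!file.exists(paths$rgb)) stop("load error: missing file: ", paths$rgb)
    rgb <- png::readPNG(paths$rgb)
    if (length(dim(rgb)) == 2) rgb <- array(rep(rgb, 3), c(dim(rgb), 3))
    if (dim(rgb)[3] > 3) rgb <- rgb[, , 1:3]
  }
  depth <- read_depth(paths$depth, depth_units)
  proj <- read_projection(paths$projection)
  grav <- jsonlite::read_json(paths$gravity, simplifyVector = TRUE)
  grav <- if (is.list(grav)) as.numeric(grav$gravity) else as.numeric(grav)
  capture_frame(rgb, depth, proj, grav,
                meta = list(source = unlist(paths[c("rgb", "depth")])))
}

#' Read a depth grid
#'
#' @param path PNG (`mm16` dialect) or whitespace-separated text (`m`
#'   dialect) file.
#' @param units `"mm16"` or `"m"`.
#' @return depth matrix in meters, `NA` = invalid.
#' @export
read_depth <- function(path, units = c("mm16", "m")) {
  units <- match.arg(units)
  if (units == "mm16") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    mm <- round(img * 65535)
    mm[mm == 0] <- NA_real_
    mm / 1000
  } else {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    m[!is.finite(m)] <- NA_real_
    m
  }
}

#' Write a depth grid
#'
#' `mm16` writes a 16-bit grayscale PNG holding millimeters (0 = invalid);
#' `m` writes a whitespace-separated text matrix of meters (NaN = invalid).
#' Round trip through `mm16` is exact to 0.5 mm.
#'
#' @param depth matrix in meters (`NA` invalid). @param path output file.
#' @param units dialect, as in [read_depth()].
#' @return `path`, invisibly.
#' @export
write_depth <- function(depth, path, units = c("mm16", "m")) {
  units <- match.arg(units)
  if (units == "mm16") {
    mm <- round(depth * 1000)
    mm[!is.finite(mm)] <- 0
    if (any(mm < 0 | mm > 65535)) stop("depth out of range for 16-bit millimeters")
    .write_png16(matrix(as.integer(mm), nrow(depth), ncol(depth)), path)
  } else {
    d2 <- depth
    d2[!is.finite(d2)] <- NaN
    utils::write.table(format(d2, digits = 9, trim = TRUE, scientific = TRUE),
                       path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

# ---- minimal 16-bit grayscale PNG encoder ---------------------------------
# No installed package writes 16-bit PNG (png::writePNG is 8-bit), so the
# millimeter depth dialect carries its own encoder: IHDR/IDAT/IEND chunks,
# filter type None; memCompress() supplies the zlib stream for IDAT.

# CRC-32 (PNG polynomial), table-driven in double arithmetic to dodge R's
# signed 32-bit integers; depth-map-sized inputs keep the loop cheap
.crc32d <- local({
  tab <- NULL
  function(bytes) {
    if (is.null(tab)) {
      t <- numeric(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          lo <- c %% 2
          c <- floor(c / 2)
          if (lo == 1) c <- .xor32(c, 3988292384)  # 0xEDB88320
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    c <- 4294967295
    b <- as.integer(bytes)
    for (i in seq_along(b)) {
      idx <- .xor8(c %% 256, b[i])
      c <- .xor32(floor(c / 256), tab[idx + 1])
    }
    c <- .xor32(c, 4294967295)
    as.raw(c(floor(c / 16777216) %% 256, floor(c / 65536) %% 256,
             floor(c / 256) %% 256, c %% 256))
  }
})

.xor32 <- function(a, b) {
  hi <- bitwXor(as.integer(floor(a / 65536)), as.integer(floor(b / 65536)))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi * 65536 + lo
}
.xor8 <- function(a, b) bitwXor(as.integer(a), as.integer(b))

.u32be <- function(x) as.raw(c(floor(x / 16777216) %% 256, floor(x / 65536) %% 256,
                               floor(x / 256) %% 256, x %% 256))

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.u32be(length(data)), body, .crc32d(body))
}

.write_png16 <- function(mm, path) {
  H <- nrow(mm); W <- ncol(mm)
  # scanlines: filter byte 0 + big-endian 16-bit samples
  v <- t(mm)                             # row-major sample order
  hi <- as.raw(v %/% 256L); lo <- as.raw(v %% 256L)
  samples <- as.vector(rbind(hi, lo))
  dim(samples) <- NULL
  scan <- matrix(samples, nrow = 2 * W)
  raw_img <- as.vector(rbind(as.raw(0L), scan))
  zlib <- memCompress(raw_img, type = "gzip")  # emits a zlib stream
  ihdr <- c(.u32be(W), .u32be(H), as.raw(c(16, 0, 0, 0, 0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(.png_chunk("IHDR", ihdr), con)
  writeBin(.png_chunk("IDAT", zlib), con)
  writeBin(.png_chunk("IEND", raw()), con)
  invisible(path)
}

# ---- masks, intrinsics, gravity -------------------------------------------

#' Read / write a binary mask as 0/255 PNG
#'
#' @param mask logical matrix. @param path PNG file.
#' @return `read_mask`: logical matrix; `write_mask`: `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Read a projection/intrinsics JSON file
#'
#' Accepts either `{"P": [[...3x4...]]}` or `{"fx":, "fy":, "cx":, "cy":}`.
#'
#' @param path JSON file.
#' @return 3x4 projection matrix.
#' @export
read_projection <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$P)) {
    P <- as.matrix(j$P)
    storage.mode(P) <- "double"
    return(P)
  }
  projection_matrix(j$fx, j$fy, j$cx, j$cy)
}

#' Write intrinsics and gravity JSON files
#'
#' @param P 3x4 projection matrix. @param gravity unit 3-vector.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_projection <- function(P, path) {
  jsonlite::write_json(list(P = P), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_projection
#' @export
write_gravity <- function(gravity, path) {
  jsonlite::write_json(list(gravity = gravity), path, digits = NA)
  invisible(path)
}

# ---- results ---------------------------------------------------------------

#' Write / read a DBH result record as JSON
#'
#' The record carries the corrected diameter `d_cm`, the intermediates
#' `d_tilde_cm`, `p_tilde_cm`, `l_tilde_cm`, `n_bh`, the orientation,
#' anchor, alignment angles, warnings and provenance. Round-trips
#' losslessly (full double precision is written).
#'
#' @param result a `dbh_result` (see [estimate_dbh()]). @param path JSON file.
#' @return `write_result`: `path`, invisibly; `read_result`: the record.
#' @export
write_result <- function(result, path) {
  if (!dir.exists(dirname(path)))
    stop("I/O error: directory does not exist: ", dirname(path))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "dbh_result")
}
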