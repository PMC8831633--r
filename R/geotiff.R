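# Minimal single-band GeoTIFF I/O.
#
# No raster I/O package is available in this stack, so the subset of the
# format this pipeline needs is implemented directly: single band, strip
# organised, uncompressed, little- or big-endian baseline TIFF with the
# GeoTIFF ModelPixelScale/ModelTiepoint/GeoKeyDirectory tags and the GDAL
# NoData convention (ASCII tag 42113). Value layers are stored as float32,
# mask/category layers as uint8. Tiled, compressed or multi-band files are
# rejected with a clear error; reprojection is out of scope by design.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L,
                     `12` = 8L, `16` = 8L)

read_tiff_values <- function(raw, off, type, count, endian) {
  size <- TIFF_TYPE_SIZES[[as.character(type)]]
  bytes <- raw[(off + 1L):(off + size * count)]
  switch(as.character(type),
    `1` = as.integer(bytes),
    `2` = {
      s <- rawToChar(bytes[bytes != as.raw(0)])
      s
    },
    `3` = readBin(bytes, "integer", n = count, size = 2L, signed = FALSE,
                  endian = endian),
    `4` = readBin(bytes, "integer", n = count, size = 4L, endian = endian),
    `11` = readBin(bytes, "numeric", n = count, size = 4L, endian = endian),
    `12` = readBin(bytes, "numeric", n = count, size = 8L, endian = endian),
    stop("unsupported TIFF field type: ", type))
}

#' Read a single-band GeoTIFF
#'
#' Reads an uncompressed, strip-organised, single-band georeferenced TIFF.
#' The file's NoData cells (GDAL NoData tag) become `NA` in the returned
#' layer; grid geometry is populated from the GeoTIFF tags.
#'
#' @param path path to a `.tif` file.
#' @param variable_id,period_id,units optional labels attached to the layer;
#'   defaults parse nothing from the filename.
#' @return a [raster_layer()].
#' @export
read_geotiff <- function(path, variable_id = "", period_id = "", units = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little"
            else if (order_tag == "MM") "big"
            else stop("not a TIFF file (bad byte order mark): ", path)
  magic <- readBin(raw[3:4], "integer", size = 2L, signed = FALSE,
                   endian = endian)
  if (magic != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- readBin(raw[5:8], "integer", size = 4L, endian = endian)

  n_entries <- readBin(raw[(ifd_off + 1L):(ifd_off + 2L)], "integer",
                       size = 2L, signed = FALSE, endian = endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e0 <- ifd_off + 2L + (i - 1L) * 12L
    entry <- raw[(e0 + 1L):(e0 + 12L)]
    tag <- readBin(entry[1:2], "integer", size = 2L, signed = FALSE,
                   endian = endian)
    type <- readBin(entry[3:4], "integer", size = 2L, signed = FALSE,
                    endian = endian)
    count <- readBin(entry[5:8], "integer", size = 4L, endian = endian)
    size <- TIFF_TYPE_SIZES[as.character(type)]
    if (is.na(size)) next  # unknown field type: skip tag
    nbytes <- size * count
    if (nbytes <= 4L) {
      vals <- switch(as.character(type),
        `1` = as.integer(entry[9:(8L + count)]),
        `2` = rawToChar(entry[9:(8L + count)][entry[9:(8L + count)] != as.raw(0)]),
        `3` = readBin(entry[9:12], "integer", n = count, size = 2L,
                      signed = FALSE, endian = endian),
        `4` = readBin(entry[9:12], "integer", n = count, size = 4L,
                      endian = endian),
        `11` = readBin(entry[9:12], "numeric", n = count, size = 4L,
                       endian = endian))
    } else {
      off <- readBin(entry[9:12], "integer", size = 4L, endian = endian)
      vals <- read_tiff_values(raw, off, type, count, endian)
    }
    tags[[as.character(tag)]] <- vals
  }

  need <- function(code, what) {
    v <- tags[[as.character(code)]]
    if (is.null(v)) stop("TIFF missing required tag ", what, ": ", path)
    v
  }
  width <- need(256, "ImageWidth")
  height <- need(257, "ImageLength")
  bits <- tags[["258"]] %||% 1L
  spp <- tags[["277"]] %||% 1L
  if (spp != 1L) stop("multi-band TIFF without band selector: ", path)
  comp <- tags[["259"]] %||% 1L
  if (comp != 1L) stop("compressed TIFF not supported: ", path)
  if (!is.null(tags[["322"]])) stop("tiled TIFF not supported: ", path)
  fmt <- (tags[["339"]] %||% 1L)[1L]
  bits <- bits[1L]

  strip_off <- need(273, "StripOffsets")
  strip_cnt <- need(279, "StripByteCounts")
  vals <- numeric(0)
  for (s in seq_along(strip_off)) {
    bytes <- raw[(strip_off[s] + 1L):(strip_off[s] + strip_cnt[s])]
    vals <- c(vals, switch(paste(fmt, bits),
      "1 8" = as.numeric(as.integer(bytes)),
      "2 8" = as.numeric(readBin(bytes, "integer", n = length(bytes),
                                 size = 1L, signed = TRUE)),
      "1 16" = as.numeric(readBin(bytes, "integer", n = length(bytes) / 2L,
                                  size = 2L, signed = FALSE, endian = endian)),
      "2 16" = as.numeric(readBin(bytes, "integer", n = length(bytes) / 2L,
                                  size = 2L, signed = TRUE, endian = endian)),
      "2 32" = as.numeric(readBin(bytes, "integer", n = length(bytes) / 4L,
                                  size = 4L, endian = endian)),
      "3 32" = readBin(bytes, "numeric", n = length(bytes) / 4L, size = 4L,
                       endian = endian),
      "3 64" = readBin(bytes, "numeric", n = length(bytes) / 8L, size = 8L,
                       endian = endian),
      stop(sprintf("unsupported sample format/bits: %d/%d", fmt, bits))))
  }
  if (length(vals) != width * height)
    stop("pixel payload does not match image dimensions: ", path)
  values <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)

  scale <- tags[["33550"]]
  tie <- tags[["33922"]]
  if (is.null(scale) || is.null(tie))
    stop("TIFF missing geotransform (ModelPixelScale/ModelTiepoint): ", path)
  gt <- c(tie[4] - tie[1] * scale[1], scale[1], 0,
          tie[5] + tie[2] * scale[2], 0, -scale[2])

  crs_tag <- "EPSG:4326"
  gk <- tags[["34735"]]
  if (!is.null(gk) && length(gk) >= 4L) {
    nkeys <- gk[4]
    for (k in seq_len(nkeys)) {
      key <- gk[4L * k + 1L]
      if (key == 2048L) crs_tag <- paste0("EPSG:", gk[4L * k + 4L])
    }
  }

  nodata <- NA_real_
  nd_str <- tags[["42113"]]
  if (!is.null(nd_str)) {
    nodata <- suppressWarnings(as.numeric(trimws(nd_str)))
    if (!is.na(nodata)) {
      nd_cmp <- if (fmt == 3L && bits == 32L) as_float32(nodata) else nodata
      values[values == nd_cmp] <- NA_real_
      nodata <- nd_cmp
    }
  }

  grid <- csi_grid(height, width, geotransform = gt, crs_tag = crs_tag,
                   nodata_value = if (is.na(nodata)) -3.4e38 else nodata)
  raster_layer(values, grid, variable_id = variable_id,
               period_id = period_id, units = units)
}

# Build one little-endian IFD entry (12 raw bytes) plus any out-of-line
# payload. `value` already encoded per TIFF type.
tiff_entry <- function(tag, type, values) {
  size <- TIFF_TYPE_SIZES[[as.character(type)]]
  count <- if (type == 2L) length(values) else length(values)
  payload <- switch(as.character(type),
    `2` = values,  # raw, already NUL-terminated
    `3` = writeBin(as.integer(values), raw(), size = 2L, endian = "little"),
    `4` = writeBin(as.integer(values), raw(), size = 4L, endian = "little"),
    `12` = writeBin(as.numeric(values), raw(), size = 8L, endian = "little"))
  n <- if (type == 2L) length(values) else length(values)
  list(tag = as.integer(tag), type = as.integer(type), count = n,
       payload = payload, inline = length(payload) <= 4L)
}

#' Write a raster layer as a single-band GeoTIFF
#'
#' Writes an uncompressed little-endian file with grid geometry
#' (ModelPixelScale + ModelTiepoint), an EPSG GeoKey, and the GDAL NoData
#' tag. `NA` cells are stored as the grid's NoData sentinel. Value layers
#' use float32 storage; mask/category layers should use `dtype = "uint8"`
#' (NoData sentinel 255).
#'
#' @param layer a [raster_layer()].
#' @param path output path; parent directory must exist.
#' @param dtype `"float32"` or `"uint8"`.
#' @param nodata override the NoData sentinel written to the file; defaults
#'   to the grid's sentinel (float32) or 255 (uint8).
#' @return invisibly, `path`.
#' @export
write_geotiff <- function(layer, path, dtype = c("float32", "uint8"),
                          nodata = NULL) {
  stopifnot(inherits(layer, "raster_layer"))
  dtype <- match.arg(dtype)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  g <- layer$grid
  vals <- t(layer$values)  # row-major order for TIFF strips

  if (dtype == "float32") {
    nd <- as_float32(nodata %||% g$nodata_value)
    v <- as.numeric(vals)
    v[is.na(v)] <- nd
    pixel_bytes <- writeBin(v, raw(), size = 4L, endian = "little")
    bits <- 32L; sfmt <- 3L
  } else {
    nd <- as.integer(nodata %||% 255L)
    v <- as.integer(round(as.numeric(vals)))
    v[is.na(v)] <- nd
    if (any(v < 0L | v > 255L)) stop("uint8 layer values outside 0..255")
    pixel_bytes <- as.raw(v)
    bits <- 8L; sfmt <- 1L
  }

  gt <- g$geotransform
  scale <- c(gt[2], -gt[6], 0)
  tiepoint <- c(0, 0, 0, gt[1], gt[4], 0)
  epsg <- 4326L
  if (grepl("^EPSG:\\d+$", g$crs_tag))
    epsg <- as.integer(sub("^EPSG:", "", g$crs_tag))
  # GeoKey directory: version 1.1.0, 3 keys: model type = geographic,
  # raster type = PixelIsArea, geographic CRS code.
  geokeys <- c(1L, 1L, 0L, 3L,
               1024L, 0L, 1L, 2L,
               1025L, 0L, 1L, 1L,
               2048L, 0L, 1L, epsg)
  nd_ascii <- c(charToRaw(format(nd, scientific = TRUE, digits = 17)),
                as.raw(0))

  entries <- list(
    tiff_entry(256, 4, g$n_cols),
    tiff_entry(257, 4, g$n_rows),
    tiff_entry(258, 3, bits),
    tiff_entry(259, 3, 1L),
    tiff_entry(262, 3, 1L),
    tiff_entry(273, 4, 8L),                      # single strip at offset 8
    tiff_entry(277, 3, 1L),
    tiff_entry(278, 4, g$n_rows),
    tiff_entry(279, 4, length(pixel_bytes)),
    tiff_entry(284, 3, 1L),
    tiff_entry(339, 3, sfmt),
    tiff_entry(33550, 12, scale),
    tiff_entry(33922, 12, tiepoint),
    tiff_entry(34735, 3, geokeys),
    tiff_entry(42113, 2, nd_ascii)
  )

  data_len <- length(pixel_bytes)
  if (data_len %% 2L == 1L) pixel_bytes <- c(pixel_bytes, as.raw(0))
  ifd_off <- 8L + length(pixel_bytes)
  ifd_len <- 2L + 12L * length(entries) + 4L
  extra_off <- ifd_off + ifd_len

  header <- c(charToRaw("II"),
              writeBin(42L, raw(), size = 2L, endian = "little"),
              writeBin(ifd_off, raw(), size = 4L, endian = "little"))

  ifd <- writeBin(length(entries), raw(), size = 2L, endian = "little")
  extra <- raw(0)
  for (e in entries) {
    ent <- c(writeBin(e$tag, raw(), size = 2L, endian = "little"),
             writeBin(e$type, raw(), size = 2L, endian = "little"),
             writeBin(e$count, raw(), size = 4L, endian = "little"))
    if (e$inline) {
      ent <- c(ent, e$payload, raw(4L - length(e$payload)))
    } else {
      pay <- e$payload
      if (length(pay) %% 2L == 1L) pay <- c(pay, as.raw(0))
      ent <- c(ent, writeBin(extra_off + length(extra), raw(), size = 4L,
                             endian = "little"))
      extra <- c(extra, pay)
    }
    ifd <- c(ifd, ent)
  }
  ifd <- c(ifd, writeBin(0L, raw(), size = 4L, endian = "little"))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, pixel_bytes, ifd, extra), con)
  invisible(path)
}
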