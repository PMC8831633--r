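#' Spatial grid definition
#'
#' A grid fixes the spatial frame every layer of an analysis must share:
#' shape, affine geotransform, CRS tag, and the NoData sentinel used when a
#' layer is written to disk. All multi-layer operations in this package
#' require bit-identical grids (shape exact, transform to 1e-9 degrees);
#' there is deliberately no resampling or reprojection anywhere — inputs on
#' different grids are an error, because silent resampling would corrupt
#' per-pixel statistics.
#'
#' @param n_rows,n_cols positive integer grid shape.
#' @param geotransform GDAL-style 6-number affine map
#'   `c(origin_x, pixel_width, 0, origin_y, 0, -pixel_height)` in degrees.
#'   Rotation terms must be zero.
#' @param crs_tag text CRS identifier; geographic WGS84 assumed by default.
#' @param nodata_value sentinel written for NoData cells on disk. In memory
#'   NoData is always `NA`.
#' @return an object of class `csi_grid`.
#' @export
csi_grid <- function(n_rows, n_cols,
                     geotransform = c(-180, 360 / n_cols, 0, 90, 0, -180 / n_rows),
                     crs_tag = "EPSG:4326",
                     nodata_value = -3.4e38) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows <= 0L || n_cols <= 0L) stop("grid shape must be positive")
  geotransform <- as.numeric(geotransform)
  if (length(geotransform) != 6L) stop("geotransform must have 6 elements")
  if (geotransform[2] == 0 || geotransform[6] == 0)
    stop("pixel width and height must be nonzero")
  if (geotransform[3] != 0 || geotransform[5] != 0)
    stop("rotated grids are not supported")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 geotransform = geotransform, crs_tag = crs_tag,
                 nodata_value = nodata_value),
            class = "csi_grid")
}

#' Compare two grids for equality
#'
#' Shape and CRS must match exactly; the geotransform must agree to
#' `tol` degrees (default 1e-9). Anything looser would hide resampling bugs.
#'
#' @param a,b `csi_grid` objects.
#' @param tol numeric tolerance on the transform, degrees.
#' @return `TRUE`/`FALSE`.
#' @export
grid_equal <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "csi_grid"), inherits(b, "csi_grid"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    identical(a$crs_tag, b$crs_tag) &&
    all(abs(a$geotransform - b$geotransform) <= tol)
}

# Name of the first grid field differing between a and b, for error messages.
grid_diff_field <- function(a, b, tol = 1e-9) {
  if (a$n_rows != b$n_rows) return("n_rows")
  if (a$n_cols != b$n_cols) return("n_cols")
  if (any(abs(a$geotransform - b$geotransform) > tol)) return("geotransform")
  if (!identical(a$crs_tag, b$crs_tag)) return("crs_tag")
  "none"
}

#' Raster layer: one variable's field at one time
#'
#' Values live in an `n_rows x n_cols` numeric matrix; NoData cells are `NA`
#' in memory and are excluded from every statistic. The NoData sentinel only
#' appears in files.
#'
#' @param values numeric matrix of shape `grid$n_rows x grid$n_cols`;
#'   `NA` marks NoData.
#' @param grid a [csi_grid()].
#' @param variable_id e.g. `"bio1"`..`"bio19"`, or a derived id such as
#'   `"sd"`, `"csi"`, `"mask"`, `"category"`.
#' @param period_id time-period label (e.g. `"T1"`..`"T12"`, `"2021-2040"`).
#' @param units `"degC"`, `"mm"` or `"dimensionless"`.
#' @return an object of class `raster_layer`.
#' @export
raster_layer <- function(values, grid, variable_id,
                         period_id = "", units = "") {
  stopifnot(inherits(grid, "csi_grid"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop(sprintf("values shape %dx%d does not match grid %dx%d",
                 nrow(values), ncol(values), grid$n_rows, grid$n_cols))
  structure(list(grid = grid, values = values, variable_id = variable_id,
                 period_id = period_id, units = units),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer> %s %s  %dx%d  valid %d/%d",
              x$variable_id, x$period_id, x$grid$n_rows, x$grid$n_cols,
              length(v), length(x$values)))
  if (length(v)) cat(sprintf("  range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Number of valid (non-NoData) pixels in a layer
#' @param layer a `raster_layer`.
#' @return integer count.
#' @export
n_valid <- function(layer) sum(!is.na(layer$values))

#' Assert that layers share one grid
#'
#' Every multi-layer operation calls this before touching pixels. Fails
#' naming the first offending layer and the differing grid field.
#'
#' @param layers list of `raster_layer` objects (length >= 1).
#' @return invisibly `TRUE`; errors on misalignment.
#' @export
assert_aligned <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  ref <- layers[[1L]]$grid
  for (i in seq_along(layers)) {
    g <- layers[[i]]$grid
    if (!grid_equal(ref, g)) {
      stop(sprintf(
        "layer %d (%s %s) is misaligned with layer 1: grids differ in '%s'",
        i, layers[[i]]$variable_id, layers[[i]]$period_id,
        grid_diff_field(ref, g)))
    }
  }
  invisible(TRUE)
}

#' Raster stack: one variable across ordered time periods
#'
#' @param layers list of `raster_layer` objects sharing one `variable_id`
#'   across at least two distinct `period_id`s, all on one grid.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 2L)
  assert_aligned(layers)
  vids <- vapply(layers, function(l) l$variable_id, character(1))
  if (length(unique(vids)) != 1L)
    stop("all layers in a stack must share one variable_id")
  pids <- vapply(layers, function(l) l$period_id, character(1))
  if (anyDuplicated(pids))
    stop("period_ids must be unique within a stack")
  structure(list(grid = layers[[1L]]$grid, layers = layers,
                 variable_id = vids[1L], period_ids = pids),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %s  %d periods (%s)  %dx%d\n",
              x$variable_id, length(x$layers),
              paste(x$period_ids, collapse = ", "),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Ensemble cube: one variable x period across GCM members
#'
#' Members flagged unavailable (the "NA" cells of a GCM availability table)
#' carry no layer and are skipped, never imputed.
#'
#' @param members named list of `raster_layer` objects, one per available GCM.
#' @param availability named logical vector over the full GCM roster;
#'   defaults to `TRUE` for every supplied member.
#' @param variable_id,period_id labels for the cube.
#' @return an object of class `ensemble_cube`.
#' @export
ensemble_cube <- function(members, availability = NULL,
                          variable_id = NULL, period_id = NULL) {
  stopifnot(is.list(members))
  if (is.null(availability))
    availability <- stats::setNames(rep(TRUE, length(members)), names(members))
  avail_names <- names(availability)[availability]
  if (length(avail_names) < 1L) stop("at least one available member required")
  if (!all(avail_names %in% names(members)))
    stop("available members missing a layer: ",
         paste(setdiff(avail_names, names(members)), collapse = ", "))
  members <- members[avail_names]
  assert_aligned(members)
  structure(list(grid = members[[1L]]$grid, members = members,
                 availability = availability,
                 variable_id = variable_id %||% members[[1L]]$variable_id,
                 period_id = period_id %||% members[[1L]]$period_id),
            class = "ensemble_cube")
}

#' Variable catalog: which variables exist for which periods
#'
#' Drives workflow behaviour instead of silent assumptions: e.g. in
#' paleoclimate map sets bio2, bio3, bio5, bio6 and bio7 are missing from
#' the oldest periods, so they are excluded from a past index that spans
#' all periods.
#'
#' @param map_set `"past"` or `"future"`.
#' @param entries named list: variable_id -> character vector of period_ids
#'   where the variable is present.
#' @param units named character vector of units per variable.
#' @return an object of class `variable_catalog`.
#' @export
variable_catalog <- function(map_set, entries, units = NULL) {
  map_set <- match.arg(map_set, c("past", "future"))
  stopifnot(is.list(entries), length(entries) >= 1L, !is.null(names(entries)))
  if (is.null(units))
    units <- stats::setNames(rep("", length(entries)), names(entries))
  structure(list(map_set = map_set, entries = entries,
                 units = units[names(entries)]),
            class = "variable_catalog")
}

#' Variables present in every one of the given periods
#'
#' @param catalog a [variable_catalog()].
#' @param period_ids periods that must all be covered.
#' @return character vector of variable ids.
#' @export
catalog_complete_variables <- function(catalog, period_ids) {
  stopifnot(inherits(catalog, "variable_catalog"))
  keep <- vapply(catalog$entries, function(p) all(period_ids %in% p),
                 logical(1))
  names(catalog$entries)[keep]
}

#' Serialize / deserialize a variable catalog as JSON
#'
#' @param catalog a [variable_catalog()].
#' @param path file path.
#' @return `read_catalog_json` returns a `variable_catalog`.
#' @export
write_catalog_json <- function(catalog, path) {
  stopifnot(inherits(catalog, "variable_catalog"))
  jsonlite::write_json(
    list(map_set = catalog$map_set, entries = catalog$entries,
         units = as.list(catalog$units)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_catalog_json
#' @export
read_catalog_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  variable_catalog(x$map_set,
                   entries = as.list(x$entries),
                   units = unlist(x$units))
}
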