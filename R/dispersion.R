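# Per-pixel temporal dispersion and GCM-ensemble reduction.

#' Dispersion configuration
#'
#' @param statistic `"sd"` (sample SD, n-1 denominator) or `"range"`
#'   (max - min) across time periods.
#' @param min_valid minimum number of non-NoData periods a pixel needs for a
#'   dispersion value; pixels below it are NoData. Must be >= 2: a single
#'   observation carries no dispersion information, and keeping such pixels
#'   would paint once-emerged glacial shelves as spuriously stable.
#' @return a `dispersion_config`.
#' @export
dispersion_config <- function(statistic = c("sd", "range"), min_valid = 2L) {
  statistic <- match.arg(statistic)
  min_valid <- as.integer(min_valid)
  if (min_valid < 2L) stop("min_valid must be >= 2")
  structure(list(statistic = statistic, sd_denominator = "sample",
                 min_valid = min_valid),
            class = "dispersion_config")
}

#' Ensemble reduction configuration
#'
#' @param reducer `"median"` (default) or `"mean"`, applied per pixel over
#'   available GCM members only. The even-count median is the midpoint of
#'   the two central values.
#' @return an `ensemble_config`.
#' @export
ensemble_config <- function(reducer = c("median", "mean")) {
  structure(list(reducer = match.arg(reducer)), class = "ensemble_config")
}

# Stack layers into a (pixels x periods) matrix, pixels in column-major order.
stack_matrix <- function(layers) {
  n_px <- length(layers[[1L]]$values)
  m <- vapply(layers, function(l) as.numeric(l$values), numeric(n_px))
  if (!is.matrix(m)) m <- matrix(m, nrow = n_px)  # single-pixel grid
  m
}

pixelwise_dispersion <- function(stack, config, stat) {
  stopifnot(inherits(stack, "raster_stack"),
            inherits(config, "dispersion_config"))
  if (length(stack$layers) < 2L)
    stop("dispersion needs a stack with >= 2 layers")
  assert_aligned(stack$layers)
  m <- stack_matrix(stack$layers)
  nv <- rowSums(!is.na(m))
  out <- switch(stat,
    sd = matrixStats::rowSds(m, na.rm = TRUE),
    range = matrixStats::rowMaxs(m, na.rm = TRUE) -
            matrixStats::rowMins(m, na.rm = TRUE))
  out[nv < config$min_valid] <- NA_real_
  out[!is.finite(out)] <- NA_real_
  raster_layer(matrix(out, stack$grid$n_rows, stack$grid$n_cols),
               stack$grid, variable_id = stat,
               period_id = paste(range(stack$period_ids), collapse = ".."),
               units = stack$layers[[1L]]$units)
}

#' Per-pixel sample standard deviation across time periods
#'
#' For each pixel, the sample SD (denominator n-1) over the non-NoData
#' period values, if at least `min_valid` of them exist; NoData otherwise.
#' High values mark climatically unstable pixels.
#'
#' @param stack a [raster_stack()] with >= 2 aligned layers.
#' @param config a [dispersion_config()].
#' @return a [raster_layer()] with `variable_id = "sd"`.
#' @export
pixelwise_sd <- function(stack, config = dispersion_config("sd")) {
  pixelwise_dispersion(stack, config, "sd")
}

#' Per-pixel range (max - min) across time periods
#'
#' @inheritParams pixelwise_sd
#' @return a [raster_layer()] with `variable_id = "range"`.
#' @export
pixelwise_range <- function(stack, config = dispersion_config("range")) {
  pixelwise_dispersion(stack, config, "range")
}

#' Reduce a GCM ensemble to one layer per pixel
#'
#' Per pixel, the median (or mean) over the available, non-NoData member
#' values. A pixel is NoData only where no member has a valid value.
#' Members flagged unavailable never contribute and are never imputed.
#'
#' @param cube an [ensemble_cube()].
#' @param config an [ensemble_config()].
#' @return a [raster_layer()] labelled like the cube.
#' @export
ensemble_reduce <- function(cube, config = ensemble_config("median")) {
  stopifnot(inherits(cube, "ensemble_cube"),
            inherits(config, "ensemble_config"))
  if (length(cube$members) < 1L) stop("empty ensemble cube")
  assert_aligned(cube$members)
  m <- stack_matrix(cube$members)
  out <- if (config$reducer == "median")
    matrixStats::rowMedians(m, na.rm = TRUE)
  else
    rowMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  raster_layer(matrix(out, cube$grid$n_rows, cube$grid$n_cols), cube$grid,
               variable_id = cube$variable_id, period_id = cube$period_id,
               units = cube$members[[1L]]$units)
}
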