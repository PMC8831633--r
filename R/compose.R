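# Normalization, index composition, categorization, histograms.

#' Min-max normalize a layer to [0, 1]
#'
#' `(x - min) / (max - min)` over valid pixels; NoData preserved. A constant
#' layer normalizes to all zeros with a warning (there is no dispersion
#' information to rescale).
#'
#' @param layer a [raster_layer()] with >= 1 valid pixel.
#' @return the normalized [raster_layer()].
#' @export
normalize01 <- function(layer) {
  stopifnot(inherits(layer, "raster_layer"))
  v <- layer$values
  ok <- !is.na(v)
  if (!any(ok)) stop("cannot normalize an all-NoData layer")
  lo <- min(v[ok]); hi <- max(v[ok])
  out <- layer
  if (hi == lo) {
    warning("constant layer normalized to all zeros: ", layer$variable_id)
    v[ok] <- 0
  } else {
    v[ok] <- (v[ok] - lo) / (hi - lo)
  }
  out$values <- v
  out$units <- "dimensionless"
  out
}

#' Compose the Climate Stability Index from selected dispersion layers
#'
#' Per-pixel sum of the kept (already normalized) dispersion layers,
#' re-normalized to [0, 1]: 0 marks the most climatically stable pixels,
#' 1 the most unstable. NoData propagation is strict — a pixel missing any
#' kept layer is NoData, because a partial sum over fewer variables is not
#' comparable across pixels.
#'
#' @param sd_layers named list of normalized dispersion [raster_layer()]s,
#'   keyed by variable id.
#' @param kept character vector of variable ids to sum (subset of
#'   `names(sd_layers)`).
#' @param provenance optional list recorded alongside the index (map-set
#'   label, statistic, reducer, threshold, seeds).
#' @return a `csi_result`: `csi` ([raster_layer()], `variable_id = "csi"`)
#'   plus `kept` and `provenance`.
#' @export
compose_csi <- function(sd_layers, kept, provenance = list()) {
  stopifnot(is.list(sd_layers), length(kept) >= 1L)
  if (!all(kept %in% names(sd_layers)))
    stop("kept variables missing from sd_layers: ",
         paste(setdiff(kept, names(sd_layers)), collapse = ", "))
  use <- sd_layers[sort(unique(kept))]  # fixed order: permutation-invariant sum
  assert_aligned(use)
  g <- use[[1L]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (l in use) acc <- acc + l$values  # NA propagates strictly
  total <- raster_layer(acc, g, variable_id = "csi", units = "dimensionless")
  csi <- normalize01(total)
  csi$variable_id <- "csi"
  structure(list(csi = csi, kept = kept,
                 provenance = c(provenance, list(n_kept = length(kept)))),
            class = "csi_result")
}

#' @export
print.csi_result <- function(x, ...) {
  cat(sprintf("<csi_result> %d kept variables (%s)\n", length(x$kept),
              paste(x$kept, collapse = ", ")))
  print(x$csi)
  invisible(x)
}

#' Break scheme for index categorization
#'
#' @param breaks strictly ascending upper bin boundaries in (0, 1], the last
#'   equal to 1. With `n` boundaries, bin `i` is `(breaks[i-1], breaks[i]]`
#'   and bin 1 is `[0, breaks[1]]`.
#' @return a `break_scheme`.
#' @export
break_scheme <- function(breaks) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 1L || any(diff(breaks) <= 0))
    stop("breaks must be strictly ascending")
  if (breaks[1] <= 0 || abs(breaks[length(breaks)] - 1) > 1e-12)
    stop("breaks must lie in (0, 1] with the last boundary equal to 1")
  structure(list(n_categories = length(breaks), breaks = breaks),
            class = "break_scheme")
}

#' Equal-interval break scheme over [0, 1]
#'
#' @param n_categories number of categories (the published maps use 32).
#' @return a [break_scheme()].
#' @export
equal_interval_breaks <- function(n_categories = 32L) {
  break_scheme(seq_len(n_categories) / n_categories)
}

#' Categorize an index layer by a break scheme
#'
#' Half-open bins, lower-exclusive / upper-inclusive, with the first bin
#' closed at 0. NoData preserved.
#'
#' @param csi a [raster_layer()] with valid values in [0, 1].
#' @param scheme a [break_scheme()].
#' @return a [raster_layer()] of integer categories 1..n,
#'   `variable_id = "category"`.
#' @export
categorize <- function(csi, scheme) {
  stopifnot(inherits(csi, "raster_layer"), inherits(scheme, "break_scheme"))
  v <- csi$values
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 1))
    stop("categorize expects values in [0, 1]")
  cat_idx <- matrix(NA_real_, nrow(v), ncol(v))
  cat_idx[ok] <- findInterval(v[ok], c(0, scheme$breaks), left.open = TRUE,
                              rightmost.closed = FALSE)
  cat_idx[ok & v == 0] <- 1
  raster_layer(cat_idx, csi$grid, variable_id = "category",
               period_id = csi$period_id, units = "dimensionless")
}

#' Histogram of an index layer
#'
#' Equal-width bins over [0, 1]; counts sum to the number of valid pixels
#' and empty bins are reported with count 0.
#'
#' @param layer a [raster_layer()] with values in [0, 1].
#' @param n_bins number of bins (>= 1).
#' @return data.frame with `bin_lower`, `bin_upper`, `count`.
#' @export
csi_histogram <- function(layer, n_bins = 32L) {
  stopifnot(inherits(layer, "raster_layer"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  v <- layer$values[!is.na(layer$values)]
  if (!length(v)) stop("histogram of an all-NoData layer")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- findInterval(v, edges, left.open = TRUE, rightmost.closed = FALSE)
  idx[v == 0] <- 1L
  idx <- pmin(idx, n_bins)  # value exactly 1 belongs to the last bin
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_lower = edges[-(n_bins + 1L)], bin_upper = edges[-1L],
             count = counts)
}

#' Write a histogram table as CSV
#'
#' @param hist data.frame from [csi_histogram()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_histogram_csv <- function(hist, path) {
  utils::write.csv(hist, path, row.names = FALSE)
  invisible(path)
}
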