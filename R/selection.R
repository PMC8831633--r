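# Collinearity-based variable selection.
#
# The index should not double-count near-duplicate variables (e.g. annual
# mean temperature and mean temperature of the coldest quarter), so before
# composition the candidate layers are screened: sample random land points,
# compute the pairwise Pearson matrix over sampled values, group variables
# whose |r| exceeds a threshold (connected components), and keep one random
# representative per group.

#' Selection configuration
#'
#' @param n_points number of random sample points (default 10000, suited to
#'   global grids; scale down for small synthetic worlds — sampling errors
#'   out rather than silently shrinking when fewer valid pixels exist).
#' @param method correlation method; only `"pearson"` is supported.
#' @param r_th correlation threshold in (0, 1); pairs with `|r| > r_th` are
#'   grouped (default 0.8; 0.7 and 0.9 are the usual sensitivity sweep).
#' @param sampling_seed,selection_seed independent seeds for point sampling
#'   and the random per-group pick, both logged in the result.
#' @return a `selection_config`.
#' @export
selection_config <- function(n_points = 10000L, method = "pearson",
                             r_th = 0.8, sampling_seed = 1L,
                             selection_seed = 2L) {
  method <- match.arg(method, "pearson")
  if (!(r_th > 0 && r_th < 1)) stop("r_th must be in (0, 1)")
  if (n_points < 2L) stop("n_points must be >= 2")
  structure(list(n_points = as.integer(n_points), method = method,
                 r_th = r_th, sampling_seed = as.integer(sampling_seed),
                 selection_seed = as.integer(selection_seed)),
            class = "selection_config")
}

#' Sample random pixels from a keep-mask
#'
#' Uniform sampling without replacement from mask = 1 pixels; deterministic
#' given the seed. Errors (never silently reduces) if fewer valid pixels
#' exist than requested.
#'
#' @param mask a keep-mask [raster_layer()].
#' @param n_points number of points.
#' @param seed RNG seed.
#' @return integer matrix with columns `row`, `col`.
#' @export
sample_points <- function(mask, n_points, seed) {
  stopifnot(inherits(mask, "raster_layer"))
  valid <- which(!is.na(mask$values) & mask$values == 1)
  if (length(valid) < n_points)
    stop(sprintf("requested %d sample points but only %d valid pixels",
                 n_points, length(valid)))
  idx <- with_seed(seed, sample(valid, n_points, replace = FALSE))
  cbind(row = ((idx - 1L) %% mask$grid$n_rows) + 1L,
        col = ((idx - 1L) %/% mask$grid$n_rows) + 1L)
}

#' Values of a layer at sampled points
#'
#' @param layer a [raster_layer()].
#' @param points integer matrix from [sample_points()].
#' @return numeric vector (NA where the layer is NoData).
#' @export
layer_values_at <- function(layer, points) {
  layer$values[cbind(points[, "row"], points[, "col"])]
}

#' Pairwise Pearson correlation matrix over sampled points
#'
#' Pearson r for each pair of layers over the sampled values; points where
#' either member of a pair is NoData are dropped pairwise. Errors naming any
#' layer that is constant at the sampled points (its correlation is
#' undefined).
#'
#' @param layers named list of >= 2 aligned [raster_layer()] objects; names
#'   default to the layers' `variable_id`s.
#' @param points integer matrix from [sample_points()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(layers, points) {
  stopifnot(is.list(layers), length(layers) >= 2L)
  assert_aligned(layers)
  ids <- names(layers) %||% vapply(layers, function(l) l$variable_id,
                                   character(1))
  if (is.null(names(layers))) names(layers) <- ids
  m <- vapply(layers, layer_values_at, numeric(nrow(points)),
              points = points)
  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("layer constant at sampled points (Pearson r undefined): ",
         paste(ids[!is.finite(sds) | sds == 0], collapse = ", "))
  r <- stats::cor(m, use = "pairwise.complete.obs", method = "pearson")
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  r
}

#' Group variables by correlation exceedance
#'
#' Connected components of the graph with an edge between variables i and j
#' iff `|r_ij| > r_th`. Components are the order-independent closure of
#' pairwise exceedance: if A~B and B~C exceed the threshold, {A, B, C} is
#' one group even if A~C does not.
#'
#' @param corr symmetric correlation matrix with named dimensions.
#' @param r_th threshold in (0, 1).
#' @param absolute group on `|r|` (default) rather than signed r; strongly
#'   anti-correlated variables are equally redundant.
#' @return named list of character vectors, a partition of the variable ids.
#' @export
correlated_groups <- function(corr, r_th, absolute = TRUE) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  ids <- rownames(corr) %||% paste0("v", seq_len(nrow(corr)))
  n <- nrow(corr)
  x <- if (absolute) abs(corr) else corr
  parent <- seq_len(n)
  root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (x[i, j] > r_th) {
      ri <- root(i); rj <- root(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), root, integer(1))
  groups <- split(ids, roots)
  names(groups) <- vapply(groups, function(g) g[[1L]], character(1))
  groups[order(match(names(groups), ids))]
}

#' Keep one random representative per correlated group
#'
#' Singleton groups are kept verbatim; from each larger group one member is
#' drawn uniformly at random, deterministic given the seed.
#'
#' @param groups partition from [correlated_groups()].
#' @param seed RNG seed.
#' @return character vector of kept variable ids (one per group).
#' @export
select_variables <- function(groups, seed) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  with_seed(seed, vapply(groups, function(g) {
    if (length(g) == 1L) g else g[sample.int(length(g), 1L)]
  }, character(1), USE.NAMES = FALSE))
}

#' Full collinearity screen
#'
#' Runs [sample_points()], [correlation_matrix()], [correlated_groups()] and
#' [select_variables()] with the seeds in `config`, returning everything a
#' reader needs to audit or replay the screen.
#'
#' @param layers named list of aligned candidate [raster_layer()] objects
#'   (typically the normalized dispersion layers).
#' @param mask keep-mask to sample within.
#' @param config a [selection_config()].
#' @return a `selection_result`: `sampled_points`, `corr_matrix`, `groups`,
#'   `kept`, `config`.
#' @export
remove_collinearity <- function(layers, mask, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  pts <- sample_points(mask, config$n_points, config$sampling_seed)
  corr <- correlation_matrix(layers, pts)
  groups <- correlated_groups(corr, config$r_th)
  kept <- select_variables(groups, config$selection_seed)
  structure(list(sampled_points = pts, corr_matrix = corr, groups = groups,
                 kept = kept, config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d candidates -> %d kept (r_th = %g)\n",
              nrow(x$corr_matrix), length(x$kept), x$config$r_th))
  for (g in x$groups) {
    mark <- if (length(g) > 1L) sprintf(" -> kept %s",
                                        intersect(x$kept, g)) else ""
    cat("  {", paste(g, collapse = ", "), "}", mark, "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a selection result as JSON (and the matrix as CSV)
#'
#' @param result a `selection_result`.
#' @param path output JSON path.
#' @param csv_path optional path for the correlation matrix as CSV.
#' @return invisibly, `path`.
#' @export
write_selection_json <- function(result, path, csv_path = NULL) {
  stopifnot(inherits(result, "selection_result"))
  obj <- list(
    n_points = result$config$n_points,
    method = result$config$method,
    r_th = result$config$r_th,
    sampling_seed = result$config$sampling_seed,
    selection_seed = result$config$selection_seed,
    sampled_points = unname(apply(result$sampled_points, 1L, as.list)),
    variables = rownames(result$corr_matrix),
    corr_matrix = unname(apply(result$corr_matrix, 1L, as.list)),
    groups = unname(lapply(result$groups, as.list)),
    kept = as.list(result$kept))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    df <- as.data.frame(result$corr_matrix)
    utils::write.csv(cbind(variable = rownames(result$corr_matrix), df),
                     csv_path, row.names = FALSE)
  }
  invisible(path)
}
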