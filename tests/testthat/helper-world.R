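# Shared fixtures, all generated in code. Worlds are cached per session so
# several test files can reuse one generation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small world: 30x40 grid, one SSP, default structure. ~0.5 s to build.
small_world <- function() {
  cached("small_world",
         make_world(world_spec(n_rows = 30L, n_cols = 40L,
                               ssps = "SSP2-4.5", seed = 7L)))
}

# Past-only world at moderate size for selection/validation structure tests.
past_world <- function() {
  cached("past_world",
         make_world(world_spec(n_rows = 48L, n_cols = 64L,
                               ssps = character(0), seed = 19L)))
}

# A layer with the given values on a fresh grid.
test_layer <- function(values, variable_id = "bio1", period_id = "T1",
                       grid = NULL) {
  values <- as.matrix(values)
  g <- grid %||% csi_grid(nrow(values), ncol(values))
  raster_layer(values, g, variable_id, period_id, units = "degC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stack where pixel (1,1) takes the given per-period values and the rest of
# the grid is filled with a constant.
pixel_stack <- function(pixel_values, nr = 2L, nc = 2L, fill = 1) {
  g <- csi_grid(nr, nc)
  raster_stack(lapply(seq_along(pixel_values), function(t) {
    m <- matrix(fill, nr, nc)
    m[1, 1] <- pixel_values[t]
    raster_layer(m, g, "bio1", paste0("T", t), units = "degC")
  }))
}

# Random stack with optional NoData holes, reproducible.
random_stack <- function(n_periods = 12L, nr = 20L, nc = 20L,
                         na_frac = 0.1, seed = 1L) {
  g <- csi_grid(nr, nc)
  set.seed(seed)
  raster_stack(lapply(seq_len(n_periods), function(t) {
    m <- matrix(rnorm(nr * nc, mean = 10, sd = 3), nr, nc)
    m[sample(length(m), round(na_frac * length(m)))] <- NA
    raster_layer(m, g, "bio1", paste0("T", t), units = "degC")
  }))
}

# Independent brute-force oracles (deliberately plain loops).
oracle_pixelwise <- function(stack, fun, min_valid = 2L) {
  g <- stack$grid
  out <- matrix(NA_real_, g$n_rows, g$n_cols)
  for (i in seq_len(g$n_rows)) for (j in seq_len(g$n_cols)) {
    x <- vapply(stack$layers, function(l) l$values[i, j], numeric(1))
    x <- x[!is.na(x)]
    if (length(x) >= min_valid) out[i, j] <- fun(x)
  }
  out
}

oracle_reduce <- function(cube, fun) {
  g <- cube$grid
  out <- matrix(NA_real_, g$n_rows, g$n_cols)
  for (i in seq_len(g$n_rows)) for (j in seq_len(g$n_cols)) {
    x <- vapply(cube$members, function(l) l$values[i, j], numeric(1))
    x <- x[!is.na(x)]
    if (length(x) >= 1L) out[i, j] <- fun(x)
  }
  out
}

# Textbook Pearson r, written out from the sum formula.
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Random correlation matrix from n observations of p variables.
random_corr <- function(p = 6L, n = 15L, seed = 1L) {
  set.seed(seed)
  stats::cor(matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("v", seq_len(p)))))
}

# Canonical partition representation for comparing groupings.
canon_partition <- function(groups)
  sort(unname(vapply(groups, function(g) paste(sort(g), collapse = "+"),
                     character(1))))

# Does partition `fine` refine partition `coarse`? (every fine group is a
# subset of some coarse group)
refines <- function(fine, coarse) {
  all(vapply(fine, function(f)
    any(vapply(coarse, function(c) all(f %in% c), logical(1))), logical(1)))
}
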