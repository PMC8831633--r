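test_that("grid equality is exact on shape and 1e-9-tight on the transform", {
  g <- csi_grid(10, 10)
  expect_true(grid_equal(g, g))
  g2 <- csi_grid(10, 11)
  expect_false(grid_equal(g, g2))
  g3 <- g
  g3$geotransform[1] <- g3$geotransform[1] + 1e-6
  expect_false(grid_equal(g, g3))
  g4 <- g
  g4$geotransform[1] <- g4$geotransform[1] + 1e-12
  expect_true(grid_equal(g, g4))
})

test_that("geotiff round-trip preserves values, NoData mask and grid", {
  # float32-exact values round-trip bit-for-bit
  l <- test_layer(matrix(c(1.5, -2.25, 0.125, 4, NA, 6, 7, 8, 1e6), 3, 3))
  p <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(l, p)
  r <- read_geotiff(p)
  expect_identical(is.na(r$values), is.na(l$values))
  expect_identical(r$values[!is.na(r$values)], l$values[!is.na(l$values)])
  expect_true(grid_equal(r$grid, l$grid))

  # a random 50x50 layer: after one float32 quantization, exact round-trip
  set.seed(4)
  vals <- matrix(rnorm(2500, 5, 100), 50, 50)
  vals[sample(2500, 100)] <- NA
  q <- read_geotiff({
    pq <- withr::local_tempfile(fileext = ".tif")
    write_geotiff(test_layer(vals), pq); pq
  })
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(q, p2)
  r2 <- read_geotiff(p2)
  expect_identical(is.na(r2$values), is.na(q$values))
  expect_equal(max(abs(r2$values - q$values), na.rm = TRUE), 0)
})

test_that("explicit NoData sentinel and uint8 masks survive a round-trip", {
  g <- csi_grid(4, 4, nodata_value = -9999)
  m <- matrix(1:16, 4, 4); m[2, 3] <- NA
  p <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(raster_layer(m, g, "bio1"), p)
  r <- read_geotiff(p)
  expect_identical(which(is.na(r$values)), which(is.na(m)))
  expect_equal(r$grid$nodata_value, -9999)

  mk <- matrix(c(1, 0, NA, 1), 2, 2)
  pm <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(test_layer(mk, variable_id = "mask"), pm, dtype = "uint8")
  rm_ <- read_geotiff(pm)
  expect_identical(rm_$values, mk)

  # all-NoData layer stays readable and all-NoData
  pa <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(test_layer(matrix(NA_real_, 3, 3)), pa)
  expect_equal(n_valid(read_geotiff(pa)), 0L)
})

test_that("write/read/write produces identical pixel payloads", {
  l <- read_geotiff({
    p0 <- withr::local_tempfile(fileext = ".tif")
    write_geotiff(test_layer(matrix(runif(36), 6, 6)), p0); p0
  })
  p1 <- withr::local_tempfile(fileext = ".tif")
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(l, p1)
  write_geotiff(read_geotiff(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("python tifffile agrees on the pixel payload of our files", {
  set.seed(9)
  vals <- matrix(round(rnorm(30, 10, 2), 3), 5, 6)
  vals[c(3, 17)] <- NA
  p <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(test_layer(vals), p)
  cmd <- sprintf(
    "import tifffile, numpy as np; a = tifffile.imread(%s).astype(np.float64); a[a < -1e37] = np.nan; print(repr(a.shape)); print(np.nansum(a))",
    shQuote(p))
  out <- suppressWarnings(system2("python", c("-c", shQuote(cmd)),
                                  stdout = TRUE, stderr = FALSE))
  expect_equal(out[1], "(5, 6)")
  expect_equal(as.numeric(out[2]),
               sum(read_geotiff(p)$values, na.rm = TRUE), tolerance = 1e-12)
})

test_that("our reader handles a tifffile-written georeferenced float32 file", {
  p <- withr::local_tempfile(fileext = ".tif")
  cmd <- sprintf(paste0(
    "import tifffile, numpy as np; a = np.arange(12, dtype=np.float32).reshape(3, 4); ",
    "tifffile.imwrite(%s, a, extratags=[",
    "(33550, 'd', 3, (0.5, 0.25, 0.0)), ",
    "(33922, 'd', 6, (0.0, 0.0, 0.0, -10.0, 40.0, 0.0))])"),
    shQuote(p))
  res <- suppressWarnings(system2("python", c("-c", shQuote(cmd))))
  expect_equal(res, 0L)
  r <- read_geotiff(p)
  expect_equal(dim(r$values), c(3L, 4L))
  expect_equal(as.numeric(t(r$values)), as.numeric(0:11))
  expect_equal(r$grid$geotransform, c(-10, 0.5, 0, 40, 0, -0.25))
})

test_that("reading errors are specific", {
  expect_error(read_geotiff(file.path(tempdir(), "nope.tif")), "no such file")
  # a plain TIFF without geo tags is rejected
  p <- withr::local_tempfile(fileext = ".tif")
  cmd <- sprintf(
    "import tifffile, numpy as np; tifffile.imwrite(%s, np.zeros((2, 2), dtype=np.float32))",
    shQuote(p))
  suppressWarnings(system2("python", c("-c", shQuote(cmd))))
  expect_error(read_geotiff(p), "geotransform")
  expect_error(write_geotiff(test_layer(matrix(1, 2, 2)),
                             file.path(tempdir(), "no_dir_here", "x.tif")),
               "directory")
})

test_that("assert_aligned names the offending layer and field", {
  g <- csi_grid(10, 10)
  a <- raster_layer(matrix(0, 10, 10), g, "bio1", "T1")
  b <- raster_layer(matrix(0, 10, 10), g, "bio2", "T2")
  expect_silent(assert_aligned(list(a, b)))
  c_ <- raster_layer(matrix(0, 10, 11), csi_grid(10, 11), "bio3", "T3")
  expect_error(assert_aligned(list(a, b, c_)), "layer 3.*n_cols")
  d <- b
  d$grid$geotransform[1] <- d$grid$geotransform[1] + 1e-6
  expect_error(assert_aligned(list(a, d)), "geotransform")
})

test_that("stack and cube constructors enforce their invariants", {
  g <- csi_grid(3, 3)
  l1 <- raster_layer(matrix(1, 3, 3), g, "bio1", "T1")
  l2 <- raster_layer(matrix(2, 3, 3), g, "bio1", "T2")
  expect_error(raster_stack(list(l1)), "")
  expect_error(raster_stack(list(l1, l1)), "unique")
  expect_error(raster_stack(list(l1, raster_layer(matrix(1, 3, 3), g, "bio2", "T2"))),
               "variable_id")
  expect_error(ensemble_cube(list(), availability = logical(0)), "")
  cube <- ensemble_cube(list(A = l1, B = l2),
                        availability = c(A = TRUE, B = FALSE, C = FALSE))
  expect_named(cube$members, "A")  # absent members dropped, never imputed
})

test_that("variable catalog round-trips through JSON unchanged", {
  cat_ <- variable_catalog("past",
                           entries = list(bio1 = paste0("T", 1:12),
                                          bio2 = paste0("T", 4:12)),
                           units = c(bio1 = "degC", bio2 = "degC"))
  p <- withr::local_tempfile(fileext = ".json")
  write_catalog_json(cat_, p)
  back <- read_catalog_json(p)
  expect_identical(back$map_set, cat_$map_set)
  expect_identical(back$entries, cat_$entries)
  expect_identical(back$units, cat_$units)
})
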