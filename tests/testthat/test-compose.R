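test_that("normalize01 rescales to [0,1], preserves NoData and ranks", {
  l <- test_layer(matrix(c(2, 4, 6, NA), 2, 2))
  n <- normalize01(l)
  expect_equal(as.numeric(n$values[1:3]), c(0, 0.5, 1))
  expect_true(is.na(n$values[2, 2]))

  expect_warning(nc <- normalize01(test_layer(matrix(7, 3, 3))), "constant")
  expect_true(all(nc$values == 0))

  set.seed(21)
  r <- test_layer(matrix(rnorm(400), 20, 20))
  nr <- normalize01(r)
  expect_equal(min(nr$values), 0)
  expect_equal(max(nr$values), 1)
  expect_identical(order(r$values), order(nr$values)) # rank-preserving
  expect_error(normalize01(test_layer(matrix(NA_real_, 2, 2))), "all-NoData")
})

test_that("index composition: identity, commutativity, brute-force oracle", {
  g <- csi_grid(15, 15)
  set.seed(31)
  mk <- function(id) {
    m <- matrix(runif(225), 15, 15)
    m[sample(225, 20)] <- NA
    normalize01(raster_layer(m, g, id))
  }
  layers <- list(a = mk("a"), b = mk("b"), c = mk("c"))

  solo <- compose_csi(layers, "a")
  expect_equal(solo$csi$values, layers$a$values) # already spans [0,1]

  c123 <- compose_csi(layers, c("a", "b", "c"))
  c321 <- compose_csi(layers, c("c", "b", "a"))
  expect_identical(c123$csi$values, c321$csi$values)

  # sum-then-normalize oracle, per pixel
  s <- layers$a$values + layers$b$values + layers$c$values
  ok <- !is.na(s)
  expected <- (s - min(s[ok])) / (max(s[ok]) - min(s[ok]))
  expect_lt(max(abs(c123$csi$values - expected), na.rm = TRUE), 1e-6)
  # strict NoData propagation: any missing kept layer voids the pixel
  expect_identical(is.na(c123$csi$values),
                   is.na(layers$a$values) | is.na(layers$b$values) |
                     is.na(layers$c$values))
  expect_equal(min(c123$csi$values, na.rm = TRUE), 0)
  expect_equal(max(c123$csi$values, na.rm = TRUE), 1)
  expect_error(compose_csi(layers, character(0)), "")
  expect_error(compose_csi(layers, c("a", "zz")), "zz")
})

test_that("the index is invariant to affine rescaling of a variable's raw values", {
  w <- small_world()
  cfg <- selection_config(n_points = 400, sampling_seed = 9,
                          selection_seed = 10)
  base <- csi_past(w, config = cfg)

  w2 <- w
  w2$past$bio12$layers <- lapply(w$past$bio12$layers, function(l) {
    l$values <- l$values * 10 + 5; l
  })
  rescaled <- csi_past(w2, config = cfg)
  expect_identical(rescaled$selection$kept, base$selection$kept)
  expect_lt(max(abs(rescaled$csi$csi$values - base$csi$csi$values),
                na.rm = TRUE), 1e-6)
})

test_that("categorization respects the published top-bin boundaries", {
  # past-style scheme: 32 categories, top bin 0.71-1
  past_scheme <- break_scheme(c(seq(0.71 / 31, 0.71, length.out = 31), 1))
  expect_equal(past_scheme$n_categories, 32)
  g <- csi_grid(1, 4)
  vals <- raster_layer(matrix(c(0.80, 0.71, 0.715, 0), 1, 4), g, "csi")
  cats <- categorize(vals, past_scheme)
  expect_equal(cats$values[1, 1], 32)  # 0.80 in 0.71-1
  expect_equal(cats$values[1, 2], 31)  # boundary is upper-inclusive below
  expect_equal(cats$values[1, 3], 32)
  expect_equal(cats$values[1, 4], 1)   # value 0 -> category 1

  # future-style scheme: top bin 0.356-1
  fut_scheme <- break_scheme(c(seq(0.356 / 31, 0.356, length.out = 31), 1))
  vals2 <- raster_layer(matrix(c(0.40, 0.356, 1, 0.01), 1, 4), g, "csi")
  cats2 <- categorize(vals2, fut_scheme)
  expect_equal(cats2$values[1, 1], 32)  # 0.40 in 0.356-1
  expect_equal(cats2$values[1, 2], 31)
  expect_equal(cats2$values[1, 3], 32)

  expect_error(categorize(raster_layer(matrix(1.5, 1, 1), csi_grid(1, 1),
                                       "csi"), past_scheme), "\\[0, 1\\]")
  expect_error(break_scheme(c(0.5, 0.4, 1)), "ascending")
  expect_error(break_scheme(c(0.5, 0.9)), "equal to 1")
})

test_that("categorize after normalize01 never introduces NoData", {
  set.seed(13)
  l <- test_layer(matrix(rnorm(144), 12, 12))
  l$values[sample(144, 30)] <- NA
  cats <- categorize(normalize01(l), equal_interval_breaks(32))
  expect_identical(is.na(cats$values), is.na(l$values))
  expect_true(all(cats$values >= 1 & cats$values <= 32, na.rm = TRUE))
})

test_that("histograms cover [0,1] with equal bins, zeros included", {
  g <- csi_grid(5, 5)
  h <- csi_histogram(raster_layer(matrix(0.5, 5, 5), g, "csi"), 10)
  expect_equal(nrow(h), 10)
  expect_equal(sum(h$count), 25)
  expect_equal(h$count[5], 25)     # 0.5 falls in (0.4, 0.5]
  expect_equal(sum(h$count == 0), 9)

  set.seed(17)
  m <- matrix(runif(400), 20, 20); m[sample(400, 40)] <- NA
  lay <- raster_layer(m, csi_grid(20, 20), "csi")
  h2 <- csi_histogram(lay, 32)
  expect_equal(sum(h2$count), n_valid(lay))
  expect_equal(h2$bin_lower, seq(0, 31 / 32, by = 1 / 32))
  expect_error(csi_histogram(lay, 0), "n_bins")
})
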