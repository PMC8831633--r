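test_that("point sampling is seeded, exhaustive at capacity, and mask-respecting", {
  set.seed(33)
  m <- matrix(1, 15, 15); m[sample(225, 80)] <- 0
  mask <- test_layer(m, variable_id = "mask")

  p1 <- sample_points(mask, 50, seed = 123)
  p2 <- sample_points(mask, 50, seed = 123)
  expect_identical(p1, p2)
  expect_false(identical(p1, sample_points(mask, 50, seed = 124)))

  n_all <- sum(m == 1)
  full <- sample_points(mask, n_all, seed = 1)
  expect_equal(nrow(unique(full)), n_all)  # every valid pixel exactly once
  for (seed in 1:5) {
    pts <- sample_points(mask, 40, seed = seed)
    expect_true(all(m[pts] == 1))
  }
  expect_error(sample_points(mask, n_all + 1, seed = 1), "only")
})

test_that("correlation matrix matches the textbook Pearson formula", {
  g <- csi_grid(1, 5)
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(2.0, 2.9, 1.1, 6.3, 5.5)
  layers <- list(a = raster_layer(matrix(x, 1, 5), g, "a"),
                 b = raster_layer(matrix(y, 1, 5), g, "b"),
                 neg_a = raster_layer(matrix(-x, 1, 5), g, "neg_a"))
  pts <- cbind(row = rep(1L, 5), col = 1:5)
  r <- correlation_matrix(layers, pts)
  expect_equal(diag(r), c(a = 1, b = 1, neg_a = 1))
  expect_lt(abs(r["a", "b"] - oracle_pearson(x, y)), 1e-12)
  expect_equal(r["a", "neg_a"], -1)
  expect_lt(max(abs(r - t(r))), 1e-12)

  layers$const <- raster_layer(matrix(2, 1, 5), g, "const")
  expect_error(correlation_matrix(layers, pts), "const")
})

test_that("NoData points are dropped pairwise", {
  g <- csi_grid(1, 6)
  x <- c(1, 2, 3, 4, 5, NA)
  y <- c(2, 4, 5, 8, NA, 12)
  layers <- list(a = raster_layer(matrix(x, 1, 6), g, "a"),
                 b = raster_layer(matrix(y, 1, 6), g, "b"))
  pts <- cbind(row = rep(1L, 6), col = 1:6)
  r <- correlation_matrix(layers, pts)
  expect_equal(r["a", "b"], oracle_pearson(x, y))
})

test_that("grouping is connected components of |r| > threshold", {
  r <- diag(3); dimnames(r) <- list(c("A", "B", "C"), c("A", "B", "C"))
  # all below threshold -> singletons
  r_low <- r; r_low[r_low == 0] <- 0.5
  expect_equal(canon_partition(correlated_groups(r_low, 0.8)),
               c("A", "B", "C"))
  # all above -> one group
  r_hi <- r; r_hi[r_hi == 0] <- 0.9
  expect_equal(canon_partition(correlated_groups(r_hi, 0.8)), "A+B+C")
  # chain A-B, B-C strong, A-C weak -> still one component
  r_ch <- r
  r_ch["A", "B"] <- r_ch["B", "A"] <- 0.9
  r_ch["B", "C"] <- r_ch["C", "B"] <- 0.9
  r_ch["A", "C"] <- r_ch["C", "A"] <- 0.1
  expect_equal(canon_partition(correlated_groups(r_ch, 0.8)), "A+B+C")
  # strong negative correlation groups under |r| but not under signed r
  r_neg <- r
  r_neg["A", "B"] <- r_neg["B", "A"] <- -0.95
  expect_equal(canon_partition(correlated_groups(r_neg, 0.8)),
               c("A+B", "C"))
  expect_equal(canon_partition(correlated_groups(r_neg, 0.8,
                                                 absolute = FALSE)),
               c("A", "B", "C"))
})

test_that("per-group pick is seeded, valid, and uniform over many seeds", {
  groups <- list(s1 = "x", g = c("a", "b", "c", "d"))
  expect_identical(select_variables(list(a = "a", b = "b"), 1), c("a", "b"))
  k1 <- select_variables(groups, 99)
  expect_identical(k1, select_variables(groups, 99))
  expect_length(k1, 2)
  expect_true(k1[2] %in% groups$g)

  picks <- vapply(1:10000, function(s)
    select_variables(list(g = c("a", "b", "c", "d")), s), character(1))
  freq <- table(picks) / 10000
  expect_true(all(abs(freq - 0.25) <= 0.02))
})

test_that("raising the threshold refines the partition", {
  for (seed in 1:25) {
    r <- random_corr(p = 6L, n = 12L, seed = seed)
    g_lo <- correlated_groups(r, 0.7)
    g_hi <- correlated_groups(r, 0.9)
    expect_true(refines(g_hi, g_lo))
    expect_equal(length(select_variables(g_lo, 1)), length(g_lo))
  }
})

test_that("the screen recovers planted correlation blocks on a synthetic world", {
  w <- past_world()
  res <- csi_past(w, config = selection_config(n_points = 1000,
                                               sampling_seed = 5,
                                               selection_seed = 6))
  expect_equal(canon_partition(res$selection$groups),
               canon_partition(w$truth$expected_groups_past))
  expect_equal(length(res$selection$kept), length(res$selection$groups))
  # stable across reruns with identical seeds and input
  res2 <- csi_past(w, config = selection_config(n_points = 1000,
                                                sampling_seed = 5,
                                                selection_seed = 6))
  expect_identical(res$selection$kept, res2$selection$kept)
})

test_that("selection results serialize to JSON and CSV", {
  w <- small_world()
  mask <- build_land_mask(w$template)
  layers <- lapply(w$past[c("bio1", "bio4", "bio10")], function(s)
    normalize01(apply_land_mask(pixelwise_sd(s), mask)))
  res <- remove_collinearity(layers, mask,
                             selection_config(n_points = 200,
                                              sampling_seed = 3,
                                              selection_seed = 4))
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_selection_json(res, jp, csv_path = cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$kept, res$kept)
  expect_equal(back$r_th, 0.8)
  expect_equal(nrow(utils::read.csv(cp)), 3)
})
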