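test_that("worlds are bit-identical under one seed and differ across seeds", {
  sp <- world_spec(n_rows = 16L, n_cols = 20L, ssps = "SSP1-2.6", seed = 5L)
  w1 <- make_world(sp)
  w2 <- make_world(sp)
  expect_identical(w1$past$bio1$layers[[1]]$values,
                   w2$past$bio1$layers[[1]]$values)
  expect_identical(w1$template$values, w2$template$values)
  expect_identical(
    w1$future[["SSP1-2.6"]]$cubes$bio1[[1]]$members[[1]]$values,
    w2$future[["SSP1-2.6"]]$cubes$bio1[[1]]$members[[1]]$values)
  w3 <- make_world(world_spec(n_rows = 16L, n_cols = 20L,
                              ssps = "SSP1-2.6", seed = 6L))
  expect_false(identical(w1$past$bio1$layers[[1]]$values,
                         w3$past$bio1$layers[[1]]$values))
  expect_gt(length(w1$truth$seeds), 10)  # per-field seeds are logged
})

test_that("planted block correlation is calibrated to the target", {
  w <- past_world()
  mask <- build_land_mask(w$template)
  sd_norm <- lapply(w$past[c("bio1", "bio10", "bio11",
                             "bio12", "bio16", "bio17", "bio4", "bio15")],
                    function(s) normalize01(apply_land_mask(pixelwise_sd(s),
                                                            mask)))
  pts <- sample_points(mask, sum(mask$values == 1, na.rm = TRUE), seed = 1)
  r <- correlation_matrix(sd_norm, pts)
  within <- c(r["bio1", "bio10"], r["bio1", "bio11"], r["bio10", "bio11"],
              r["bio12", "bio16"], r["bio12", "bio17"], r["bio16", "bio17"])
  expect_true(all(abs(within) >= 0.90 & abs(within) <= 0.99))
  between <- abs(c(r["bio1", "bio12"], r["bio10", "bio16"],
                   r["bio11", "bio17"], r["bio4", "bio15"],
                   r["bio1", "bio4"], r["bio12", "bio15"]))
  expect_true(all(between < 0.5))
  expect_true(all(between < min(abs(within))))
})

test_that("an amplitude-free world is constant in time with SD exactly 0", {
  w <- make_world(world_spec(n_rows = 10L, n_cols = 12L,
                             ssps = character(0), amplitude_scale = 0,
                             seed = 3L))
  sd_l <- pixelwise_sd(w$past$bio1)
  expect_true(all(sd_l$values[!is.na(sd_l$values)] == 0))
})

test_that("sea-level scenario plants the stated NoData patterns", {
  w <- small_world()
  tr <- w$truth
  spec <- w$spec
  st <- w$past$bio1
  for (i in seq_along(st$period_ids)) {
    pid <- st$period_ids[i]
    v <- st$layers[[i]]$values
    expect_true(all(is.na(v[tr$sea])))                      # permanent sea
    if (pid %in% spec$warm_period_ids)
      expect_true(all(is.na(v[tr$warm_lowland])))           # submerged
    else
      expect_true(all(!is.na(v[tr$warm_lowland])))
    if (identical(pid, spec$lgm_period))
      expect_true(all(!is.na(v[tr$shelf_lgm])))             # emerged at LGM
    else
      expect_true(all(is.na(v[tr$shelf_lgm])))
    if (pid %in% spec$glacial_period_ids)
      expect_true(all(!is.na(v[tr$shelf_multi])))
  }
  # the current-land template equals stable land plus warm lowland
  expect_identical(!is.na(w$template$values), tr$land)
})

test_that("catalogs encode the availability gaps and serialize", {
  spec <- world_spec(n_rows = 8L, n_cols = 8L)
  cat_past <- make_catalog(spec, "past")
  full <- catalog_complete_variables(cat_past, spec$past_periods)
  expect_length(full, 14)
  expect_length(setdiff(names(cat_past$entries), full), 5)
  expect_setequal(setdiff(names(cat_past$entries), full),
                  c("bio2", "bio3", "bio5", "bio6", "bio7"))

  no_gaps <- world_spec(n_rows = 8L, n_cols = 8L, past_absent = list())
  expect_length(catalog_complete_variables(make_catalog(no_gaps, "past"),
                                           no_gaps$past_periods), 19)

  p <- withr::local_tempfile(fileext = ".json")
  write_catalog_json(cat_past, p)
  back <- read_catalog_json(p)
  expect_identical(back$entries, cat_past$entries)
})

test_that("GCM availability follows the roster gaps", {
  w <- small_world()  # SSP2-4.5
  cubes <- w$future[["SSP2-4.5"]]$cubes$bio1
  counts <- vapply(cubes, function(cb) length(cb$members), integer(1))
  expect_equal(unname(counts), c(7L, 8L, 8L, 8L))
  expect_false("GFDL-ESM4" %in% names(cubes[[2]]$members))
  expect_false("IPSL-CM6A-LR" %in% names(cubes[[1]]$members))

  spec <- world_spec(n_rows = 8L, n_cols = 8L)
  av <- spec$gcm_availability
  expect_equal(sum(!av[["SSP5-8.5"]][["2021-2040"]]), 2) # GFDL + MRI
  expect_equal(sum(!av[["SSP1-2.6"]][["2081-2100"]]), 0)
})

test_that("spec validation rejects impossible worlds", {
  expect_error(world_spec(target_r = 1), "infeasible")
  expect_error(world_spec(blocks = list(a = c("bio1", "bio2"),
                                        b = c("bio2", "bio3"))), "disjoint")
  expect_error(world_spec(blocks = list(a = "bio99")), "declared")
})
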