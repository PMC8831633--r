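# Synthetic-world generator.
#
# Produces inputs shaped like a global paleoclimate/future-scenario raster
# collection, with *known* statistical structure so every pipeline stage has
# a ground truth: spatially autocorrelated fields, planted inter-variable
# correlation blocks with an analytically derived target |r|, a global
# temporal trajectory providing drift plus spatially varying temporal noise,
# sea-level driven NoData patterns (shelf pixels emerged only at glacial low
# stands; lowland pixels submerged during warm periods), and a GCM roster
# with availability gaps.
#
# Construction sketch (details in the methods vignette). For variable v in
# correlation block b with target within-block correlation rho:
#   F_v = sqrt(rho) L_b + sqrt(1 - rho) E_v      (standardized smooth fields)
#   A_v(x) = unit_amp_v * max(1 + cv F_v(x), 0.05)   (dispersion amplitude)
#   v_t(x) = mu_v(x) + A_v(x) d_t(x),  d_t(x) = e_t + tau w_{b,t}(x)
# Because mu_v is constant in t, the temporal sample SD is exactly
# A_v(x) sd_t(d_t(x)); the shared latent L_b makes within-block SD layers
# correlate near rho while between-block correlations stay near 0.

BIOCLIM_UNITS <- c(
  bio1 = "degC", bio2 = "degC", bio3 = "dimensionless", bio4 = "degC",
  bio5 = "degC", bio6 = "degC", bio7 = "degC", bio8 = "degC",
  bio9 = "degC", bio10 = "degC", bio11 = "degC", bio12 = "mm",
  bio13 = "mm", bio14 = "mm", bio15 = "dimensionless", bio16 = "mm",
  bio17 = "mm", bio18 = "mm", bio19 = "mm")

# Unit-dependent field scales: baseline level, spatial relief of the mean
# field, and dispersion amplitude.
unit_scales <- function(units) {
  switch(units,
    degC = c(base = 10, relief = 8, amp = 2),
    mm = c(base = 1200, relief = 400, amp = 60),
    c(base = 50, relief = 15, amp = 5))
}

# Default GCM availability (roster x SSP x period): a 9-member ensemble in
# which one model is absent from two scenarios throughout, and two more are
# absent from single scenario/period combinations.
default_gcm_availability <- function(ssps, periods) {
  gcms <- c("BCC-CSM2-MR", "CNRM-CM6-1", "CNRM-ESM2-1", "CanESM5",
            "GFDL-ESM4", "IPSL-CM6A-LR", "MIROC-ES2L", "MIROC6",
            "MRI-ESM2-0")
  av <- list()
  for (ssp in ssps) for (p in periods) {
    a <- stats::setNames(rep(TRUE, length(gcms)), gcms)
    if (ssp %in% c("SSP2-4.5", "SSP5-8.5")) a["GFDL-ESM4"] <- FALSE
    if (p == periods[1L]) {  # first future window has two extra gaps
      if (ssp == "SSP2-4.5") a["IPSL-CM6A-LR"] <- FALSE
      if (ssp == "SSP5-8.5") a["MRI-ESM2-0"] <- FALSE
    }
    av[[ssp]][[p]] <- a
  }
  av
}

#' Specification of a synthetic input world
#'
#' Defaults state a scaled-down analogue of a global 2.5 arc-min collection:
#' a 80 x 120 geographic grid, 19 bioclimatic variables of which five are
#' missing from the three oldest periods, 12 past time periods spanning
#' glacial cycles, a present baseline plus four 20-year future windows under
#' four SSP scenarios with a 9-member GCM ensemble (with availability gaps),
#' two planted correlation blocks at target |r| = 0.95, and a sea-level
#' scenario in which 10% of pixels are shelf (emerged only at glacial low
#' stands, most of them only at the glacial maximum) and 5% are lowland
#' (submerged during the three warm periods).
#'
#' @param n_rows,n_cols grid shape.
#' @param variables named character vector of units per variable id.
#' @param past_periods,future_periods ordered period labels; the first
#'   future period is the present baseline (single layer, no ensemble).
#' @param past_absent named list: variable id -> past periods where absent.
#' @param blocks named list of variable-id vectors forced to high mutual
#'   correlation; must be disjoint.
#' @param target_r target within-block |r| in (0, 1).
#' @param kernel_sd Gaussian smoothing radius (pixels) giving fields their
#'   spatial autocorrelation.
#' @param amp_cv coefficient of variation of the dispersion-amplitude field.
#' @param temporal_noise tau, the spatially varying share of the temporal
#'   deviations (0 = globally uniform trajectory).
#' @param amplitude_scale global multiplier on all dispersion amplitudes
#'   (0 makes every variable constant in time).
#' @param sea_fraction,shelf_fraction,warm_submerged_fraction pixel
#'   fractions of permanent sea, glacial shelf, and warm-period-submerged
#'   lowland (the rest is stable land).
#' @param lgm_only_fraction share of shelf pixels emerged only at the
#'   glacial maximum (a single period).
#' @param glacial_period_ids,lgm_period,warm_period_ids past periods with
#'   sea level below / at minimum / above present.
#' @param ssps SSP scenario labels.
#' @param gcm_availability availability map `ssp -> period -> named logical`;
#'   default [default_gcm_availability()].
#' @param gcm_noise relative inter-GCM noise level (0 = identical members).
#' @param seed master seed; every random field derives its own logged seed
#'   from it.
#' @return a `world_spec`.
#' @export
world_spec <- function(n_rows = 80L, n_cols = 120L,
                       variables = BIOCLIM_UNITS,
                       past_periods = paste0("T", 1:12),
                       future_periods = c("1970-2000", "2021-2040",
                                          "2041-2060", "2061-2080",
                                          "2081-2100"),
                       past_absent = list(
                         bio2 = paste0("T", 1:3), bio3 = paste0("T", 1:3),
                         bio5 = paste0("T", 1:3), bio6 = paste0("T", 1:3),
                         bio7 = paste0("T", 1:3)),
                       blocks = list(
                         temp = c("bio1", "bio10", "bio11"),
                         prec = c("bio12", "bio16", "bio17")),
                       target_r = 0.95,
                       kernel_sd = 3,
                       amp_cv = 0.25,
                       temporal_noise = 0.25,
                       amplitude_scale = 1,
                       sea_fraction = 0.35,
                       shelf_fraction = 0.10,
                       warm_submerged_fraction = 0.05,
                       lgm_only_fraction = 0.7,
                       glacial_period_ids = c("T1", "T3", "T5", "T6", "T7",
                                              "T8", "T9"),
                       lgm_period = "T9",
                       warm_period_ids = c("T2", "T4", "T10"),
                       ssps = c("SSP1-2.6", "SSP2-4.5", "SSP3-7.0",
                                "SSP5-8.5"),
                       gcm_availability = NULL,
                       gcm_noise = 0.15,
                       seed = 42L) {
  stopifnot(is.character(variables), !is.null(names(variables)))
  block_members <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(block_members))
    stop("correlation blocks must be disjoint")
  if (!all(block_members %in% names(variables)))
    stop("block members must be declared variables")
  if (length(blocks) && any(lengths(blocks) < 1L))
    stop("each block needs at least one variable")
  if (!(target_r > 0 && target_r < 1))
    stop("infeasible correlation target: |r| must be in (0, 1)")
  if (is.null(gcm_availability) && length(future_periods) > 1L)
    gcm_availability <- default_gcm_availability(ssps, future_periods[-1L])
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    variables = variables, past_periods = past_periods,
    future_periods = future_periods, past_absent = past_absent,
    blocks = blocks, target_r = target_r, kernel_sd = kernel_sd,
    amp_cv = amp_cv, temporal_noise = temporal_noise,
    amplitude_scale = amplitude_scale,
    sea_fraction = sea_fraction, shelf_fraction = shelf_fraction,
    warm_submerged_fraction = warm_submerged_fraction,
    lgm_only_fraction = lgm_only_fraction,
    glacial_period_ids = glacial_period_ids, lgm_period = lgm_period,
    warm_period_ids = warm_period_ids, ssps = ssps,
    gcm_availability = gcm_availability, gcm_noise = gcm_noise,
    seed = as.integer(seed)), class = "world_spec")
}

# Standardized spatially autocorrelated field: white noise convolved with a
# periodic Gaussian kernel via FFT, then rescaled to mean 0, sd 1.
smooth_field <- function(n_rows, n_cols, kernel_sd, seed) {
  z <- with_seed(seed, matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols))
  if (kernel_sd <= 0) return((z - mean(z)) / stats::sd(z))
  di <- pmin(0:(n_rows - 1L), n_rows - 0:(n_rows - 1L))
  dj <- pmin(0:(n_cols - 1L), n_cols - 0:(n_cols - 1L))
  k <- exp(-outer(di^2, dj^2, `+`) / (2 * kernel_sd^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k / sum(k)), inverse = TRUE)) /
    length(z)
  (f - mean(f)) / stats::sd(f)
}

# Standardized temporal trajectory over the period labels: drift plus noise.
temporal_profile <- function(n_periods, kind = c("cycle", "trend"), seed) {
  kind <- match.arg(kind)
  t <- seq_len(n_periods)
  base <- if (kind == "cycle") sin(2 * pi * t / max(6, n_periods / 2))
          else (t - mean(t)) / stats::sd(t)
  e <- base + 0.8 * with_seed(seed, stats::rnorm(n_periods))
  (e - mean(e)) / stats::sd(e)
}

#' Generate a synthetic input world
#'
#' Builds the complete input set for both workflows: per-variable past time
#' stacks with sea-level NoData patterns, per-SSP future ensembles with
#' availability gaps, the current-land template, and a truth record holding
#' the planted structure (block membership, latent fields, per-field seeds,
#' sea masks) for oracle tests. Deterministic given `spec$seed`.
#'
#' @param spec a [world_spec()].
#' @return a `csi_world` with elements `grid`, `template`, `past` (list of
#'   [raster_stack()]), `future` (per SSP: `present` layers and `cubes`),
#'   `catalog_past`, `catalog_future`, `spec`, `truth`.
#' @export
make_world <- function(spec = world_spec()) {
  stopifnot(inherits(spec, "world_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols
  grid <- csi_grid(nr, nc)
  vars <- names(spec$variables)
  seeds <- list()
  sf <- function(tag, k) {
    s <- derive_seed(spec$seed, k)
    seeds[[tag]] <<- s
    smooth_field(nr, nc, spec$kernel_sd, s)
  }
  kcount <- 0L
  nxt <- function() { kcount <<- kcount + 1L; kcount }

  # --- topography and sea-level masks ------------------------------------
  elev <- sf("elevation", nxt())
  qs <- stats::quantile(elev, c(spec$sea_fraction,
                                spec$sea_fraction + spec$shelf_fraction,
                                spec$sea_fraction + spec$shelf_fraction +
                                  spec$warm_submerged_fraction))
  sea <- elev < qs[1]
  shelf <- elev >= qs[1] & elev < qs[2]
  warm_lowland <- elev >= qs[2] & elev < qs[3]
  land <- elev >= qs[2]  # current land: lowland + stable
  shelf_idx <- which(shelf)
  lgm_seed <- derive_seed(spec$seed, nxt())
  seeds[["lgm_split"]] <- lgm_seed
  lgm_only_idx <- with_seed(lgm_seed,
    sample(shelf_idx, round(spec$lgm_only_fraction * length(shelf_idx))))
  shelf_lgm <- matrix(FALSE, nr, nc); shelf_lgm[lgm_only_idx] <- TRUE
  shelf_multi <- shelf & !shelf_lgm

  past_valid <- function(pid) {
    v <- land
    if (pid %in% spec$warm_period_ids) v <- v & !warm_lowland
    if (pid %in% spec$glacial_period_ids) v <- v | shelf_multi
    if (identical(pid, spec$lgm_period)) v <- v | shelf_lgm
    v
  }

  template <- raster_layer(ifelse(land, elev, NA_real_), grid,
                           variable_id = "template",
                           period_id = spec$past_periods[length(spec$past_periods)],
                           units = "dimensionless")

  # --- block structure ----------------------------------------------------
  block_of <- stats::setNames(rep(NA_character_, length(vars)), vars)
  for (b in names(spec$blocks)) block_of[spec$blocks[[b]]] <- b
  singles <- vars[is.na(block_of)]
  block_of[singles] <- paste0("single_", singles)
  block_ids <- unique(block_of)

  latent <- lapply(stats::setNames(block_ids, block_ids), function(b)
    sf(paste0("latent_", b), nxt()))
  f_field <- list(); amp <- list(); mu <- list()
  for (v in vars) {
    ev <- sf(paste0("indep_", v), nxt())
    b <- block_of[[v]]
    f <- if (b %in% names(spec$blocks))
      sqrt(spec$target_r) * latent[[b]] + sqrt(1 - spec$target_r) * ev
    else ev
    sc <- unit_scales(spec$variables[[v]])
    f_field[[v]] <- f
    amp[[v]] <- sc[["amp"]] * spec$amplitude_scale *
      pmax(1 + spec$amp_cv * f, 0.05)
    mu[[v]] <- sc[["base"]] + sc[["relief"]] * sf(paste0("mu_", v), nxt())
  }

  make_stack <- function(v, periods, e, w_fields, valid_masks) {
    layers <- lapply(seq_along(periods), function(t) {
      d <- e[t] + spec$temporal_noise * w_fields[[t]]
      vals <- mu[[v]] + amp[[v]] * d
      vals[!valid_masks[[t]]] <- NA_real_
      raster_layer(vals, grid, variable_id = v, period_id = periods[t],
                   units = spec$variables[[v]])
    })
    raster_stack(layers)
  }

  # --- past map set -------------------------------------------------------
  e_past <- temporal_profile(length(spec$past_periods), "cycle",
                             derive_seed(spec$seed, nxt()))
  w_past <- lapply(stats::setNames(block_ids, block_ids), function(b)
    lapply(seq_along(spec$past_periods), function(t)
      sf(paste0("w_past_", b, "_", t), nxt())))
  valid_past_all <- lapply(spec$past_periods, past_valid)
  names(valid_past_all) <- spec$past_periods

  past <- list()
  for (v in vars) {
    periods <- setdiff(spec$past_periods, spec$past_absent[[v]] %||% character(0))
    if (length(periods) < 2L) next
    ti <- match(periods, spec$past_periods)
    past[[v]] <- make_stack(v, periods, e_past[ti],
                            w_past[[block_of[[v]]]][ti],
                            valid_past_all[periods])
  }

  # --- future map sets ----------------------------------------------------
  future <- list()
  fp <- spec$future_periods
  if (length(fp) >= 2L) {
    e_fut <- temporal_profile(length(fp), "trend",
                              derive_seed(spec$seed, nxt()))
    w_fut <- lapply(stats::setNames(block_ids, block_ids), function(b)
      lapply(seq_along(fp), function(t) sf(paste0("w_fut_", b, "_", t), nxt())))
    valid_fut <- lapply(fp, function(p) land)
    names(valid_fut) <- fp
    truth_fut <- lapply(stats::setNames(vars, vars), function(v)
      make_stack(v, fp, e_fut, w_fut[[block_of[[v]]]], valid_fut))

    for (ssp in spec$ssps) {
      gnoise <- list()
      for (p in fp[-1L]) {
        roster <- spec$gcm_availability[[ssp]][[p]]
        gnoise[[p]] <- lapply(stats::setNames(names(roster), names(roster)),
          function(g) if (roster[[g]])
            sf(paste0("gcm_", ssp, "_", p, "_", g), nxt()) else NULL)
      }
      cubes <- list()
      present <- list()
      for (v in vars) {
        sc <- unit_scales(spec$variables[[v]])
        present[[v]] <- truth_fut[[v]]$layers[[1L]]
        cubes[[v]] <- list()
        for (p in fp[-1L]) {
          truth_layer <- truth_fut[[v]]$layers[[match(p, fp)]]
          roster <- spec$gcm_availability[[ssp]][[p]]
          members <- list()
          for (g in names(roster)[roster]) {
            vals <- truth_layer$values +
              spec$gcm_noise * sc[["amp"]] * gnoise[[p]][[g]]
            vals[!land] <- NA_real_
            members[[g]] <- raster_layer(vals, grid, variable_id = v,
                                         period_id = p,
                                         units = spec$variables[[v]])
          }
          cubes[[v]][[p]] <- ensemble_cube(members, availability = roster,
                                           variable_id = v, period_id = p)
        }
      }
      future[[ssp]] <- list(present = present, cubes = cubes)
    }
  }

  # --- catalogs and truth record -------------------------------------------
  catalog_past <- make_catalog(spec, "past")
  catalog_future <- make_catalog(spec, "future")

  past_candidates <- catalog_complete_variables(catalog_past,
                                                spec$past_periods)
  expected_groups <- c(
    unname(lapply(spec$blocks, function(b) intersect(past_candidates, b))),
    as.list(setdiff(past_candidates, unlist(spec$blocks))))
  expected_groups <- expected_groups[lengths(expected_groups) > 0L]

  structure(list(
    grid = grid, template = template, past = past, future = future,
    catalog_past = catalog_past, catalog_future = catalog_future,
    spec = spec,
    truth = list(block_of = block_of, blocks = spec$blocks,
                 expected_groups_past = expected_groups,
                 latent = latent, f_field = f_field, amp = amp,
                 elevation = elev, sea = sea, shelf = shelf,
                 shelf_lgm = shelf_lgm, shelf_multi = shelf_multi,
                 warm_lowland = warm_lowland, land = land,
                 seeds = seeds)), class = "csi_world")
}

#' @export
print.csi_world <- function(x, ...) {
  cat(sprintf("<csi_world> %dx%d  %d past stacks, %d SSP ensembles\n",
              x$grid$n_rows, x$grid$n_cols, length(x$past),
              length(x$future)))
  invisible(x)
}

#' Build the variable catalog implied by a world spec
#'
#' @param spec a [world_spec()].
#' @param map_set `"past"` or `"future"`.
#' @return a [variable_catalog()].
#' @export
make_catalog <- function(spec, map_set = c("past", "future")) {
  map_set <- match.arg(map_set)
  vars <- names(spec$variables)
  entries <- if (map_set == "past") {
    lapply(stats::setNames(vars, vars), function(v)
      setdiff(spec$past_periods, spec$past_absent[[v]] %||% character(0)))
  } else {
    lapply(stats::setNames(vars, vars), function(v) spec$future_periods)
  }
  variable_catalog(map_set, entries, units = spec$variables)
}

#' Write a synthetic world to disk as a GeoTIFF tree
#'
#' Past layers are written as `past/<variable>_<period>.tif`, the template
#' as `template.tif`, future layers as
#' `future/<ssp>/<variable>_<period>_<gcm>.tif` (the present baseline with
#' gcm label `"obs"`), plus `catalog_past.json`, `catalog_future.json` and
#' `world_spec.json`.
#'
#' @param world a `csi_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "csi_world"))
  dir.create(file.path(dir, "past"), recursive = TRUE, showWarnings = FALSE)
  write_geotiff(world$template, file.path(dir, "template.tif"))
  for (v in names(world$past))
    for (l in world$past[[v]]$layers)
      write_geotiff(l, file.path(dir, "past",
                                 sprintf("%s_%s.tif", v, l$period_id)))
  for (ssp in names(world$future)) {
    d <- file.path(dir, "future", ssp)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    fu <- world$future[[ssp]]
    for (v in names(fu$present))
      write_geotiff(fu$present[[v]],
                    file.path(d, sprintf("%s_%s_obs.tif", v,
                                         fu$present[[v]]$period_id)))
    for (v in names(fu$cubes)) for (p in names(fu$cubes[[v]])) {
      cube <- fu$cubes[[v]][[p]]
      for (g in names(cube$members))
        write_geotiff(cube$members[[g]],
                      file.path(d, sprintf("%s_%s_%s.tif", v, p, g)))
    }
  }
  write_catalog_json(world$catalog_past, file.path(dir, "catalog_past.json"))
  write_catalog_json(world$catalog_future,
                     file.path(dir, "catalog_future.json"))
  sp <- world$spec
  sp$variables <- as.list(sp$variables)  # keep names in JSON
  sp$gcm_availability <- lapply(sp$gcm_availability,
                                function(x) lapply(x, as.list))
  jsonlite::write_json(unclass(sp), file.path(dir, "world_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
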