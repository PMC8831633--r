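# Workflow wiring: the past and future map-set pipelines, file output with
# the standard naming pattern, run manifests, and replay.

#' Past map-set workflow
#'
#' Runs, in order: candidate choice from the catalog (variables present in
#' every period), per-variable temporal dispersion, current-land masking
#' (template = the most recent period), per-variable min-max normalization,
#' collinearity screen, index composition. Also derives the
#' interglacial-affected flag and the deletion mask.
#'
#' @param world a `csi_world` from [make_world()] or [read_world()].
#' @param statistic `"sd"` or `"range"`.
#' @param config a [selection_config()].
#' @param min_valid minimum valid periods per pixel (see
#'   [dispersion_config()]).
#' @param output_dir if non-`NULL`, writes the standard file set there (see
#'   [write_past_outputs()]).
#' @return list with `csi` (a `csi_result`), `selection`, `sd_raw`,
#'   `sd_norm`, `land_mask`, `intergl_affected`, `deletion_mask`, and
#'   `files` (written paths, if any).
#' @export
csi_past <- function(world, statistic = c("sd", "range"),
                     config = selection_config(), min_valid = 2L,
                     output_dir = NULL) {
  stopifnot(inherits(world, "csi_world"))
  statistic <- match.arg(statistic)
  spec <- world$spec
  candidates <- catalog_complete_variables(world$catalog_past,
                                           spec$past_periods)
  candidates <- intersect(candidates, names(world$past))
  if (length(candidates) < 2L)
    stop("past workflow needs >= 2 catalog-complete variables")

  dcfg <- dispersion_config(statistic, min_valid)
  disp_fun <- if (statistic == "sd") pixelwise_sd else pixelwise_range
  mask <- build_land_mask(world$template)

  sd_raw <- lapply(stats::setNames(candidates, candidates), function(v)
    apply_land_mask(disp_fun(world$past[[v]], dcfg), mask))
  sd_norm <- lapply(sd_raw, normalize01)

  sel <- remove_collinearity(sd_norm, mask, config)
  csi <- compose_csi(sd_norm, sel$kept,
                     provenance = list(map_set = "past",
                                       statistic = statistic,
                                       r_th = config$r_th,
                                       n_points = config$n_points,
                                       sampling_seed = config$sampling_seed,
                                       selection_seed = config$selection_seed))
  flag <- flag_interglacial_affected(world$past[candidates],
                                     spec$warm_period_ids, mask)
  delmask <- build_deletion_mask(world$past[candidates], mask)

  out <- list(csi = csi, selection = sel, sd_raw = sd_raw, sd_norm = sd_norm,
              land_mask = mask, intergl_affected = flag,
              deletion_mask = delmask, files = character(0))
  if (!is.null(output_dir)) out$files <- write_past_outputs(out, output_dir)
  out
}

#' Future map-set workflow for one SSP scenario
#'
#' Runs, in order: per variable x future period, ensemble reduction over the
#' available GCM members; stacking of the present baseline plus the reduced
#' future layers; per-variable temporal dispersion; normalization; the
#' collinearity screen; composition.
#'
#' @param world a `csi_world`.
#' @param ssp scenario label, one of `names(world$future)`.
#' @param reducer `"median"` or `"mean"` over GCM members.
#' @inheritParams csi_past
#' @return list with `csi`, `selection`, `sd_raw`, `sd_norm`, `land_mask`,
#'   `member_counts` (available GCMs per variable x period), `files`.
#' @export
csi_future <- function(world, ssp, reducer = c("median", "mean"),
                       statistic = c("sd", "range"),
                       config = selection_config(), min_valid = 2L,
                       output_dir = NULL) {
  stopifnot(inherits(world, "csi_world"))
  reducer <- match.arg(reducer)
  statistic <- match.arg(statistic)
  if (!ssp %in% names(world$future))
    stop("unknown SSP scenario: ", ssp)
  fu <- world$future[[ssp]]
  ecfg <- ensemble_config(reducer)
  dcfg <- dispersion_config(statistic, min_valid)
  disp_fun <- if (statistic == "sd") pixelwise_sd else pixelwise_range

  vars <- names(fu$cubes)
  member_counts <- list()
  sd_raw <- list()
  for (v in vars) {
    layers <- c(list(fu$present[[v]]),
                lapply(fu$cubes[[v]], ensemble_reduce, config = ecfg))
    member_counts[[v]] <- vapply(fu$cubes[[v]],
                                 function(cb) length(cb$members), integer(1))
    sd_raw[[v]] <- disp_fun(raster_stack(layers), dcfg)
  }
  mask <- build_land_mask(fu$present[[1L]])
  sd_norm <- lapply(sd_raw, normalize01)
  sel <- remove_collinearity(sd_norm, mask, config)
  csi <- compose_csi(sd_norm, sel$kept,
                     provenance = list(map_set = paste0("future:", ssp),
                                       statistic = statistic,
                                       reducer = reducer,
                                       r_th = config$r_th,
                                       n_points = config$n_points,
                                       sampling_seed = config$sampling_seed,
                                       selection_seed = config$selection_seed))
  out <- list(csi = csi, selection = sel, sd_raw = sd_raw, sd_norm = sd_norm,
              land_mask = mask, member_counts = member_counts,
              files = character(0))
  if (!is.null(output_dir))
    out$files <- write_future_outputs(out, ssp, output_dir)
  out
}

#' Write the past map-set file set
#'
#' Writes `sd_past_<bio>.tif` (raw dispersion, masked),
#' `sd_past_<bio>_norm.tif` (normalized), `csi_past.tif`,
#' `intergl_affected.tif` (1 = land submerged in >= 1 warm period),
#' `lgm_del_mask.tif` (1 = pixel removed by the current-land mask),
#' `selection.json`, `corr_matrix.csv` and `histogram.csv`.
#'
#' @param result list from [csi_past()].
#' @param output_dir directory (created if needed).
#' @return character vector of written paths.
#' @export
write_past_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(p) { paths <<- c(paths, p); p }
  for (v in names(result$sd_raw)) {
    write_geotiff(result$sd_raw[[v]],
                  w(file.path(output_dir, sprintf("sd_past_%s.tif", v))))
    write_geotiff(result$sd_norm[[v]],
                  w(file.path(output_dir, sprintf("sd_past_%s_norm.tif", v))))
  }
  write_geotiff(result$csi$csi, w(file.path(output_dir, "csi_past.tif")))
  write_geotiff(result$intergl_affected,
                w(file.path(output_dir, "intergl_affected.tif")),
                dtype = "uint8")
  write_geotiff(result$deletion_mask,
                w(file.path(output_dir, "lgm_del_mask.tif")),
                dtype = "uint8")
  write_selection_json(result$selection,
                       w(file.path(output_dir, "selection.json")),
                       csv_path = w(file.path(output_dir, "corr_matrix.csv")))
  write_histogram_csv(csi_histogram(result$csi$csi, 32L),
                      w(file.path(output_dir, "histogram.csv")))
  paths
}

#' Write the future map-set file set for one SSP
#'
#' Writes `sd_future_<ssp>_<bio>.tif`, `sd_future_<ssp>_<bio>_norm.tif`,
#' `csi_future_<ssp>.tif`, `selection_<ssp>.json`, `corr_matrix_<ssp>.csv`
#' and `histogram_<ssp>.csv`.
#'
#' @param result list from [csi_future()].
#' @param ssp scenario label used in file names.
#' @param output_dir directory (created if needed).
#' @return character vector of written paths.
#' @export
write_future_outputs <- function(result, ssp, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(p) { paths <<- c(paths, p); p }
  for (v in names(result$sd_raw)) {
    write_geotiff(result$sd_raw[[v]],
                  w(file.path(output_dir,
                              sprintf("sd_future_%s_%s.tif", ssp, v))))
    write_geotiff(result$sd_norm[[v]],
                  w(file.path(output_dir,
                              sprintf("sd_future_%s_%s_norm.tif", ssp, v))))
  }
  write_geotiff(result$csi$csi,
                w(file.path(output_dir, sprintf("csi_future_%s.tif", ssp))))
  write_selection_json(
    result$selection,
    w(file.path(output_dir, sprintf("selection_%s.json", ssp))),
    csv_path = w(file.path(output_dir, sprintf("corr_matrix_%s.csv", ssp))))
  write_histogram_csv(csi_histogram(result$csi$csi, 32L),
                      w(file.path(output_dir,
                                  sprintf("histogram_%s.csv", ssp))))
  paths
}

#' Run configuration
#'
#' One object holding every choice of a pipeline run; it is logged verbatim
#' into the run manifest, which makes any run replayable.
#'
#' @param map_set `"past"` or `"future:<ssp>"`.
#' @param input_dir directory holding a GeoTIFF world written by
#'   [write_world()]; `NULL` means generate a synthetic world from
#'   `world_seed`.
#' @param statistic,reducer,r_th,n_points,min_valid method choices.
#' @param sampling_seed,selection_seed,world_seed logged RNG seeds.
#' @param output_dir where outputs are written.
#' @return a `run_config`.
#' @export
run_config <- function(map_set = "past", input_dir = NULL,
                       statistic = "sd", reducer = "median", r_th = 0.8,
                       n_points = 2000L, min_valid = 2L,
                       sampling_seed = 1L, selection_seed = 2L,
                       world_seed = 42L, output_dir = tempfile("csi_run_")) {
  if (!identical(map_set, "past") && !grepl("^future:", map_set))
    stop("map_set must be 'past' or 'future:<ssp>'")
  structure(list(map_set = map_set, input_dir = input_dir,
                 statistic = statistic, reducer = reducer, r_th = r_th,
                 n_points = as.integer(n_points),
                 min_valid = as.integer(min_valid),
                 sampling_seed = as.integer(sampling_seed),
                 selection_seed = as.integer(selection_seed),
                 world_seed = as.integer(world_seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run a full pipeline from a configuration
#'
#' Fail-fast preflight (every referenced input file must exist before any
#' computation starts), then the past or future workflow, file output, and a
#' JSON run manifest (`manifest.json`) logging every seed, config field and
#' input checksum. Outputs go only under `config$output_dir`.
#'
#' @param config a [run_config()].
#' @param world optional pre-built `csi_world`; otherwise read from
#'   `config$input_dir` or generated from `config$world_seed`.
#' @return the workflow result list (see [csi_past()] / [csi_future()]),
#'   plus `manifest` (path).
#' @export
run_pipeline <- function(config, world = NULL) {
  stopifnot(inherits(config, "run_config"))
  input_checksums <- character(0)
  if (is.null(world)) {
    if (!is.null(config$input_dir)) {
      world <- read_world(config$input_dir)
      files <- list.files(config$input_dir, recursive = TRUE,
                          full.names = TRUE)
      input_checksums <- tools::md5sum(files)
      names(input_checksums) <- substring(names(input_checksums),
                                          nchar(config$input_dir) + 2L)
    } else {
      world <- make_world(world_spec(seed = config$world_seed))
    }
  }
  scfg <- selection_config(n_points = config$n_points, r_th = config$r_th,
                           sampling_seed = config$sampling_seed,
                           selection_seed = config$selection_seed)
  res <- if (identical(config$map_set, "past")) {
    csi_past(world, statistic = config$statistic, config = scfg,
             min_valid = config$min_valid, output_dir = config$output_dir)
  } else {
    csi_future(world, ssp = sub("^future:", "", config$map_set),
               reducer = config$reducer, statistic = config$statistic,
               config = scfg, min_valid = config$min_valid,
               output_dir = config$output_dir)
  }
  manifest <- list(
    config = unclass(config),
    kept = res$selection$kept,
    member_counts = res$member_counts,
    input_checksums = as.list(input_checksums),
    output_checksums = as.list(tools::md5sum(res$files)))
  names(manifest$output_checksums) <- basename(res$files)
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  res$manifest <- manifest_path
  res$files <- c(res$files, manifest_path)
  res
}

#' Replay a run from its manifest
#'
#' Re-executes the run a manifest describes, writing to `output_dir`.
#' With synthetic input (no `input_dir`) the world is regenerated from the
#' logged seed, so the replay is bit-for-bit identical.
#'
#' @param manifest_path path to a `manifest.json` from [run_pipeline()].
#' @param output_dir where the replay writes (defaults to a fresh tempdir).
#' @return as [run_pipeline()].
#' @export
replay_manifest <- function(manifest_path, output_dir = tempfile("csi_rep_")) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cf <- m$config
  config <- run_config(map_set = cf$map_set, input_dir = cf$input_dir,
                       statistic = cf$statistic, reducer = cf$reducer,
                       r_th = cf$r_th, n_points = cf$n_points,
                       min_valid = cf$min_valid,
                       sampling_seed = cf$sampling_seed,
                       selection_seed = cf$selection_seed,
                       world_seed = cf$world_seed, output_dir = output_dir)
  run_pipeline(config)
}

#' Read a GeoTIFF world tree written by [write_world()]
#'
#' Fail-fast: every file implied by the catalogs and GCM availability map is
#' checked for existence before anything is read.
#'
#' @param dir directory written by [write_world()].
#' @return a `csi_world` (without the synthetic truth record).
#' @export
read_world <- function(dir) {
  spec_path <- file.path(dir, "world_spec.json")
  if (!file.exists(spec_path)) stop("not a world directory: ", dir)
  sj <- jsonlite::read_json(spec_path, simplifyVector = TRUE)
  spec <- world_spec(
    n_rows = sj$n_rows, n_cols = sj$n_cols,
    variables = unlist(sj$variables),
    past_periods = sj$past_periods, future_periods = sj$future_periods,
    past_absent = lapply(sj$past_absent, as.character),
    blocks = lapply(sj$blocks, as.character),
    target_r = sj$target_r, kernel_sd = sj$kernel_sd,
    amp_cv = sj$amp_cv, temporal_noise = sj$temporal_noise,
    amplitude_scale = sj$amplitude_scale,
    sea_fraction = sj$sea_fraction, shelf_fraction = sj$shelf_fraction,
    warm_submerged_fraction = sj$warm_submerged_fraction,
    lgm_only_fraction = sj$lgm_only_fraction,
    glacial_period_ids = sj$glacial_period_ids,
    lgm_period = sj$lgm_period, warm_period_ids = sj$warm_period_ids,
    ssps = sj$ssps,
    gcm_availability = lapply(sj$gcm_availability,
                              function(x) lapply(x, unlist)),
    gcm_noise = sj$gcm_noise, seed = sj$seed)

  # preflight: enumerate every expected file first
  expected <- file.path(dir, "template.tif")
  for (v in names(spec$variables)) {
    periods <- setdiff(spec$past_periods,
                       spec$past_absent[[v]] %||% character(0))
    if (length(periods) >= 2L)
      expected <- c(expected,
                    file.path(dir, "past", sprintf("%s_%s.tif", v, periods)))
  }
  for (ssp in spec$ssps) for (v in names(spec$variables)) {
    expected <- c(expected,
                  file.path(dir, "future", ssp,
                            sprintf("%s_%s_obs.tif", v,
                                    spec$future_periods[1L])))
    for (p in spec$future_periods[-1L]) {
      roster <- spec$gcm_availability[[ssp]][[p]]
      expected <- c(expected,
                    file.path(dir, "future", ssp,
                              sprintf("%s_%s_%s.tif", v, p,
                                      names(roster)[roster])))
    }
  }
  missing <- expected[!file.exists(expected)]
  if (length(missing))
    stop("preflight failed, missing input file(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)",
                                           length(missing) - 5L))

  template <- read_geotiff(file.path(dir, "template.tif"),
                           variable_id = "template",
                           period_id = spec$past_periods[length(spec$past_periods)])
  past <- list()
  for (v in names(spec$variables)) {
    periods <- setdiff(spec$past_periods,
                       spec$past_absent[[v]] %||% character(0))
    if (length(periods) < 2L) next
    past[[v]] <- raster_stack(lapply(periods, function(p)
      read_geotiff(file.path(dir, "past", sprintf("%s_%s.tif", v, p)),
                   variable_id = v, period_id = p,
                   units = spec$variables[[v]])))
  }
  future <- list()
  for (ssp in spec$ssps) {
    present <- list(); cubes <- list()
    for (v in names(spec$variables)) {
      present[[v]] <- read_geotiff(
        file.path(dir, "future", ssp,
                  sprintf("%s_%s_obs.tif", v, spec$future_periods[1L])),
        variable_id = v, period_id = spec$future_periods[1L],
        units = spec$variables[[v]])
      cubes[[v]] <- list()
      for (p in spec$future_periods[-1L]) {
        roster <- spec$gcm_availability[[ssp]][[p]]
        members <- lapply(
          stats::setNames(names(roster)[roster], names(roster)[roster]),
          function(g) read_geotiff(
            file.path(dir, "future", ssp, sprintf("%s_%s_%s.tif", v, p, g)),
            variable_id = v, period_id = p, units = spec$variables[[v]]))
        cubes[[v]][[p]] <- ensemble_cube(members, availability = roster,
                                         variable_id = v, period_id = p)
      }
    }
    future[[ssp]] <- list(present = present, cubes = cubes)
  }
  structure(list(grid = template$grid, template = template, past = past,
                 future = future,
                 catalog_past = make_catalog(spec, "past"),
                 catalog_future = make_catalog(spec, "future"),
                 spec = spec, truth = NULL),
            class = "csi_world")
}
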