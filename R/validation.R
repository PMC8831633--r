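# Robustness validation: pairwise Pearson comparison of index maps computed
# under alternative methodological choices (dispersion statistic, ensemble
# reducer, correlation threshold).

#' Pearson correlation between two aligned maps
#'
#' Pearson r over the pixels valid in both layers (pairwise deletion).
#' Errors if fewer than 3 jointly valid pixels exist or either layer is
#' constant on the joint domain.
#'
#' @param a,b aligned [raster_layer()] objects.
#' @return a single correlation value in [-1, 1].
#' @export
compare_maps <- function(a, b) {
  assert_aligned(list(a, b))
  ok <- !is.na(a$values) & !is.na(b$values)
  if (sum(ok) < 3L) stop("fewer than 3 jointly valid pixels")
  x <- a$values[ok]; y <- b$values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("layer constant on the jointly valid domain (Pearson r undefined)")
  stats::cor(x, y, method = "pearson")
}

#' Seeded sample of jointly valid pixel value pairs
#'
#' For external scatterplotting of map comparisons: `n` jointly valid pixel
#' value pairs drawn uniformly without replacement, deterministic given the
#' seed.
#'
#' @param a,b aligned [raster_layer()] objects.
#' @param n number of pairs; must not exceed the jointly valid pixel count.
#' @param seed RNG seed.
#' @return data.frame with columns `a` and `b`.
#' @export
scatter_sample <- function(a, b, n, seed) {
  assert_aligned(list(a, b))
  ok <- which(!is.na(a$values) & !is.na(b$values))
  if (n > length(ok))
    stop(sprintf("requested %d pairs but only %d jointly valid pixels",
                 n, length(ok)))
  idx <- with_seed(seed, sample(ok, n, replace = FALSE))
  data.frame(a = a$values[idx], b = b$values[idx])
}

validation_row <- function(category, pair, r) {
  data.frame(category = category, pair = pair, r = r,
             stringsAsFactors = FALSE)
}

#' Run the full robustness-validation sweep
#'
#' Computes the index for every combination of dispersion statistic (past
#' map set), ensemble reducer (future map sets) and correlation threshold,
#' under shared sampling/selection seeds, then emits the pairwise Pearson
#' comparison table in three categories:
#' * `"SD vs range"` — past index per threshold, SD vs range;
#' * `"mean vs median"` — future index per SSP per threshold;
#' * `"threshold (r)"` — all threshold pairs within one configuration.
#'
#' @param world a synthetic (or equivalently structured) input world from
#'   [make_world()].
#' @param statistics dispersion statistics to sweep for the past map set.
#' @param reducers ensemble reducers to sweep for the future map sets.
#' @param thresholds correlation thresholds to sweep.
#' @param ssps SSP labels to include (default: all in the world).
#' @param n_points,sampling_seed,selection_seed selection settings shared by
#'   every sweep cell.
#' @param min_valid minimum valid periods per pixel for dispersion.
#' @return a `validation_matrix`: data.frame with columns `category`,
#'   `pair`, `r`, plus a `metadata` attribute describing the sweep.
#' @export
run_validation <- function(world,
                           statistics = c("sd", "range"),
                           reducers = c("median", "mean"),
                           thresholds = c(0.7, 0.8, 0.9),
                           ssps = NULL,
                           n_points = 2000L,
                           sampling_seed = 101L, selection_seed = 202L,
                           min_valid = 2L) {
  stopifnot(inherits(world, "csi_world"))
  ssps <- ssps %||% names(world$future)
  cfg <- function(th) selection_config(n_points = n_points, r_th = th,
                                       sampling_seed = sampling_seed,
                                       selection_seed = selection_seed)

  past <- list()   # past[[statistic]][[threshold-label]] -> csi layer
  for (st in statistics) {
    for (th in thresholds) {
      res <- csi_past(world, statistic = st, config = cfg(th),
                      min_valid = min_valid)
      past[[st]][[format(th)]] <- res$csi$csi
    }
  }
  future <- list() # future[[ssp]][[reducer]][[threshold-label]]
  for (ssp in ssps) {
    for (red in reducers) {
      for (th in thresholds) {
        res <- csi_future(world, ssp = ssp, reducer = red, config = cfg(th),
                          min_valid = min_valid)
        future[[ssp]][[red]][[format(th)]] <- res$csi$csi
      }
    }
  }

  rows <- list()
  if (all(c("sd", "range") %in% statistics)) {
    for (th in thresholds) {
      lab <- format(th)
      rows[[length(rows) + 1L]] <- validation_row(
        "SD vs range",
        sprintf("CSI-past SD th %s vs. CSI-past range th %s", lab, lab),
        compare_maps(past[["sd"]][[lab]], past[["range"]][[lab]]))
    }
  }
  if (all(c("mean", "median") %in% reducers)) {
    for (ssp in ssps) for (th in thresholds) {
      lab <- format(th)
      rows[[length(rows) + 1L]] <- validation_row(
        "mean vs median",
        sprintf("CSI-future mean %s th %s vs. CSI-future median %s th %s",
                ssp, lab, ssp, lab),
        compare_maps(future[[ssp]][["mean"]][[lab]],
                     future[[ssp]][["median"]][[lab]]))
    }
  }
  th_pairs <- if (length(thresholds) >= 2L)
    utils::combn(sort(thresholds), 2L, simplify = FALSE) else list()
  for (st in statistics) {
    for (p in th_pairs) {
      l1 <- format(p[1]); l2 <- format(p[2])
      rows[[length(rows) + 1L]] <- validation_row(
        "threshold (r)",
        sprintf("CSI-past %s th %s vs. CSI-past %s th %s",
                toupper(st), l1, toupper(st), l2),
        compare_maps(past[[st]][[l1]], past[[st]][[l2]]))
    }
  }
  for (ssp in ssps) for (red in reducers) {
    for (p in th_pairs) {
      l1 <- format(p[1]); l2 <- format(p[2])
      rows[[length(rows) + 1L]] <- validation_row(
        "threshold (r)",
        sprintf("CSI-future %s %s th %s vs. CSI-future %s %s th %s",
                red, ssp, l1, red, ssp, l2),
        compare_maps(future[[ssp]][[red]][[l1]], future[[ssp]][[red]][[l2]]))
    }
  }
  if (!length(rows)) {
    # degenerate single-cell sweep: report self-comparisons (exactly 1)
    for (st in statistics) for (lab in names(past[[st]]))
      rows[[length(rows) + 1L]] <- validation_row(
        "self", sprintf("CSI-past %s th %s vs. itself", toupper(st), lab),
        compare_maps(past[[st]][[lab]], past[[st]][[lab]]))
    for (ssp in ssps) for (red in reducers)
      for (lab in names(future[[ssp]][[red]]))
        rows[[length(rows) + 1L]] <- validation_row(
          "self",
          sprintf("CSI-future %s %s th %s vs. itself", red, ssp, lab),
          compare_maps(future[[ssp]][[red]][[lab]],
                       future[[ssp]][[red]][[lab]]))
  }
  out <- do.call(rbind, rows)
  attr(out, "metadata") <- list(statistics = statistics, reducers = reducers,
                                thresholds = thresholds, ssps = ssps,
                                n_points = n_points,
                                sampling_seed = sampling_seed,
                                selection_seed = selection_seed)
  class(out) <- c("validation_matrix", class(out))
  out
}

#' Write a validation matrix as CSV and JSON
#'
#' @param vm a `validation_matrix` from [run_validation()].
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, `vm`.
#' @export
write_validation <- function(vm, csv_path = NULL, json_path = NULL) {
  df <- as.data.frame(vm)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(metadata = attr(vm, "metadata"), rows = df),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(vm)
}
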