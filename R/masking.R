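# Land/sea masking rules for sea-level change across glacial cycles.
#
# Two distinct concerns, kept separate on purpose:
#  * the current-land mask REMOVES pixels that are sea today but were emerged
#    at low sea stands (they have too few periods for an honest dispersion
#    estimate and would otherwise look spuriously stable);
#  * the interglacial-affected flag only ANNOTATES current-land pixels that
#    were submerged during warm periods; those pixels stay in the index.

#' Build a keep-mask of current land from a template layer
#'
#' The template is the most recent period's layer (the Anthropocene slice in
#' a paleoclimate stack): 1 where it is valid (current land), 0 where NoData
#' (current sea).
#'
#' @param template a [raster_layer()].
#' @return a [raster_layer()] with `variable_id = "mask"`, values in {0, 1},
#'   semantics keep-mask.
#' @export
build_land_mask <- function(template) {
  stopifnot(inherits(template, "raster_layer"))
  m <- ifelse(is.na(template$values), 0, 1)
  out <- raster_layer(m, template$grid, variable_id = "mask",
                      period_id = template$period_id,
                      units = "dimensionless")
  out$semantics <- "keep-mask"
  out
}

#' Apply a keep-mask to a layer
#'
#' Output equals the input where the mask is 1 and NoData where it is 0 or
#' NoData. Idempotent: masking twice equals masking once.
#'
#' @param layer a [raster_layer()].
#' @param mask a keep-mask from [build_land_mask()] (values in {0, 1, NA}).
#' @return the masked [raster_layer()].
#' @export
apply_land_mask <- function(layer, mask) {
  assert_aligned(list(layer, mask))
  v <- layer$values
  v[is.na(mask$values) | mask$values == 0] <- NA_real_
  out <- layer
  out$values <- v
  out
}

#' Flag current-land pixels submerged during warm periods
#'
#' A pixel is flagged 1 if it is current land (mask = 1) and NoData in at
#' least one warm-period layer of any stack; 0 on other land; NoData off
#' land. The flag annotates pixels, it never removes them: dispersion there
#' is computed over fewer periods, and users can decide whether that matters
#' for their application.
#'
#' @param stacks list of [raster_stack()] objects.
#' @param warm_period_ids period ids with sea level above present
#'   (default `c("T2", "T4", "T10")`, the interglacial slices of a
#'   Pliocene-to-present map set).
#' @param mask current-land keep-mask from [build_land_mask()].
#' @return a [raster_layer()] flag with values in {0, 1, NA},
#'   semantics affected-flag.
#' @export
flag_interglacial_affected <- function(stacks,
                                       warm_period_ids = c("T2", "T4", "T10"),
                                       mask) {
  stopifnot(is.list(stacks), length(stacks) >= 1L,
            inherits(mask, "raster_layer"))
  affected <- matrix(FALSE, mask$grid$n_rows, mask$grid$n_cols)
  seen <- character(0)
  for (st in stacks) {
    stopifnot(inherits(st, "raster_stack"))
    assert_aligned(c(list(mask), st$layers))
    for (pid in intersect(warm_period_ids, st$period_ids)) {
      lay <- st$layers[[match(pid, st$period_ids)]]
      affected <- affected | is.na(lay$values)
      seen <- union(seen, pid)
    }
  }
  unknown <- setdiff(warm_period_ids, seen)
  if (length(unknown))
    stop("warm period id(s) not present in any stack: ",
         paste(unknown, collapse = ", "))
  land <- !is.na(mask$values) & mask$values == 1
  v <- matrix(NA_real_, mask$grid$n_rows, mask$grid$n_cols)
  v[land] <- 0
  v[land & affected] <- 1
  out <- raster_layer(v, mask$grid, variable_id = "mask",
                      period_id = paste(warm_period_ids, collapse = "+"),
                      units = "dimensionless")
  out$semantics <- "affected-flag"
  out
}

#' Deletion mask of once-emerged, currently submerged pixels
#'
#' Records which pixels the current-land mask removed: 1 where a pixel has a
#' valid value in at least one period of any stack but is current sea
#' (mask = 0), 0 elsewhere. This is the record of the glacial-shelf removal,
#' written alongside the index outputs (polarity: 1 = removed).
#'
#' @inheritParams flag_interglacial_affected
#' @return a [raster_layer()] with values in {0, 1}.
#' @export
build_deletion_mask <- function(stacks, mask) {
  stopifnot(is.list(stacks), length(stacks) >= 1L)
  ever_valid <- matrix(FALSE, mask$grid$n_rows, mask$grid$n_cols)
  for (st in stacks) {
    assert_aligned(c(list(mask), st$layers))
    for (lay in st$layers) ever_valid <- ever_valid | !is.na(lay$values)
  }
  sea <- is.na(mask$values) | mask$values == 0
  out <- raster_layer(ifelse(ever_valid & sea, 1, 0), mask$grid,
                      variable_id = "mask", period_id = "",
                      units = "dimensionless")
  out$semantics <- "deletion-mask"
  out
}
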