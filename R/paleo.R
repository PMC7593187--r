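# row-major (north-west first) cell vector of a raster, matching coarse cell ids
raster_to_cells <- function(r) as.vector(t(r$data))

#' Assemble a paleoclimate time-slice set
#'
#' @param slices List of slices ordered oldest to youngest, each a list with
#'   `age_ka` (integer), `anomalies` (named list of coarse [grid_raster()]s
#'   for the four base variables, expressed as paleo minus modern in the
#'   variable's units) and `ice` (coarse-geometry 0/1 [grid_raster()] aligned
#'   with the occupancy grid).
#' @param baseline Named list of the four fine current-climate rasters.
#' @return Object of class `timeslice_set`.
#' @export
timeslice_set <- function(slices, baseline) {
  ages <- vapply(slices, `[[`, numeric(1), "age_ka")
  if (length(ages) > 1 && any(diff(ages) >= 0)) {
    stop("slice ages must strictly decrease toward the present")
  }
  stopifnot(all(BASE_VARS %in% names(baseline)))
  for (s in slices) {
    if (!all(BASE_VARS %in% names(s$anomalies))) {
      stop("slice ", s$age_ka, " ka is missing anomaly variables")
    }
  }
  structure(list(slices = slices, baseline = baseline),
            class = "timeslice_set")
}

#' Delta (change-factor) downscaling of a coarse anomaly
#'
#' Bilinearly interpolates a coarse anomaly field to the fine raster's cell
#' centers and adds it to the fine baseline: temperature anomalies are purely
#' additive, precipitation anomalies additive with a floor at zero. Fine
#' cells outside the coarse centers' span are clamped to the nearest edge
#' (nearest-edge extrapolation) with a warning.
#'
#' @param anomaly Coarse [grid_raster()] of (paleo - modern) values.
#' @param baseline Fine [grid_raster()] of the current field.
#' @param floor_zero Clamp the result at 0 (use for precipitation).
#' @return Fine [grid_raster()] of the reconstructed paleo field.
#' @export
downscale_delta <- function(anomaly, baseline, floor_zero = FALSE) {
  stopifnot(inherits(anomaly, "grid_raster"), inherits(baseline, "grid_raster"))
  cc <- raster_centers(anomaly)
  fc <- raster_centers(baseline)
  # interp2 wants ascending axes; raster rows run north to south
  x <- cc$x
  y <- rev(cc$y)
  Z <- anomaly$data[rev(seq_len(nrow(anomaly$data))), , drop = FALSE]
  xp <- rep(fc$x, each = length(fc$y))
  yp <- rep(fc$y, times = length(fc$x))
  half <- anomaly$cellsize / 2
  outside <- xp < min(x) - half | xp > max(x) + half |
    yp < min(y) - half | yp > max(y) + half
  if (any(outside)) {
    warning(sum(outside),
            " fine cell(s) outside coarse coverage; nearest-edge extrapolated")
  }
  xpc <- pmin(pmax(xp, min(x)), max(x))
  ypc <- pmin(pmax(yp, min(y)), max(y))
  interp <- if (length(x) == 1 && length(y) == 1) {
    rep(Z[1, 1], length(xpc))
  } else if (length(y) == 1) {
    stats::approx(x, Z[1, ], xout = xpc)$y
  } else if (length(x) == 1) {
    stats::approx(y, Z[, 1], xout = ypc)$y
  } else {
    pracma::interp2(x, y, Z, xpc, ypc, method = "linear")
  }
  # element order: all fine rows (north to south) for fine column 1, then
  # column 2, ... -> column-major fill reproduces the raster layout
  anom_fine <- matrix(interp, nrow = length(fc$y), ncol = length(fc$x))
  res <- baseline$data + anom_fine
  if (floor_zero) res <- pmax(res, 0)
  grid_raster(res, baseline$cellsize, baseline$xll, baseline$yll)
}

#' Hindcast suitability across paleoclimate time slices
#'
#' For each slice: downscale the four anomaly fields onto the fine baseline
#' (precipitation floored at zero), extract the eight extreme-cell features
#' on the coarse grid, predict ensemble suitability, and zero out ice-covered
#' cells (probability 0 with an ice flag). Returns the slice maps ordered
#' oldest to youngest with the present-day map appended as the last layer.
#'
#' @param model A fitted `ensemble_model`.
#' @param slices A [timeslice_set()].
#' @param grid The coarse occupancy [coarse_grid()].
#' @param weight_by_auc Passed to [predict_ensemble()].
#' @return List of [suitability_map()]s (length `n_slices + 1`).
#' @export
project_timeslices <- function(model, slices, grid, weight_by_auc = FALSE) {
  stopifnot(inherits(slices, "timeslice_set"))
  maps <- lapply(slices$slices, function(s) {
    fine <- lapply(BASE_VARS, function(v) {
      downscale_delta(s$anomalies[[v]], slices$baseline[[v]],
                      floor_zero = startsWith(v, "P_"))
    })
    names(fine) <- BASE_VARS
    feats <- extract_features(fine, grid)
    m <- predict_ensemble(model, feats, tag = paste0(s$age_ka, "ka"),
                          weight_by_auc = weight_by_auc)
    ice <- raster_to_cells(s$ice) > 0
    m$prob[ice & !is.na(m$prob)] <- 0
    m$ice <- ice & !is.na(m$prob)
    m
  })
  present_feats <- extract_features(slices$baseline, grid)
  present <- predict_ensemble(model, present_feats, tag = "present",
                              weight_by_auc = weight_by_auc)
  c(maps, list(present))
}

#' Long-term climate-stability surface with refugium flags
#'
#' Sums per-cell suitability over the supplied maps (ice-masked cells
#' contribute 0), ranks cells by the sum, and flags the top
#' `ceil(top_frac * N_unmasked)` cells as areas of highest long-term climate
#' stability -- candidate glacial refugia. Ties at the cut are broken by cell
#' index ascending (deterministic); `include_ties = TRUE` instead keeps every
#' cell tied with the cut value.
#'
#' @param maps List of [suitability_map()]s sharing geometry.
#' @param top_frac Flagged fraction of unmasked cells (default 0.30).
#' @param include_ties Keep all cells tied at the cut instead of truncating.
#' @return data.frame of class `stability_map`:
#'   `cell_id, sum, rank, flag` (`NA` rank for masked cells).
#' @export
stability_surface <- function(maps, top_frac = 0.30, include_ties = FALSE) {
  if (length(maps) == 0) stop("empty map list")
  n <- length(maps[[1]]$prob)
  probs <- vapply(maps, function(m) {
    if (length(m$prob) != n) stop("maps do not share geometry")
    m$prob
  }, numeric(n))
  probs <- matrix(probs, nrow = n)
  sums <- rowSums(probs)  # NA if masked in any layer
  unmasked <- !is.na(sums)
  n_flag <- ceiling(top_frac * sum(unmasked))
  ord <- order(-sums, seq_len(n), na.last = TRUE)
  rnk <- rep(NA_integer_, n)
  rnk[ord[seq_len(sum(unmasked))]] <- seq_len(sum(unmasked))
  flag <- !is.na(rnk) & rnk <= n_flag
  if (include_ties && n_flag > 0 && n_flag < sum(unmasked)) {
    cut_val <- sums[ord[n_flag]]
    flag <- flag | (unmasked & sums >= cut_val)
  }
  out <- data.frame(cell_id = seq_len(n), sum = sums, rank = rnk, flag = flag)
  class(out) <- c("stability_map", "data.frame")
  out
}

#' Write a suitability map / stability surface over a coarse grid as .asc
#'
#' @param values Per-cell vector (row-major from the north-west).
#' @param grid A [coarse_grid()]; `file` output path.
#' @export
write_cells_asc <- function(values, grid, file) {
  m <- matrix(values, nrow = grid$nrow, ncol = grid$ncol, byrow = TRUE)
  write_asc(grid_raster(m, grid$cellsize_km), file)
}
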