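#' Names of the four base climate variables
#'
#' Seasonal climate of the coldest and warmest quarter: mean temperature
#' (degrees C) and mean precipitation (mm) of each. Min/max over the fine
#' cells inside each coarse cell yields the eight model features.
#' @export
BASE_VARS <- c("T_coldQ", "T_warmQ", "P_coldQ", "P_warmQ")

#' Coarse occupancy lattice over a block of fine climate cells
#'
#' Each coarse cell (emulating a 50 x 50-km occupancy square) owns a
#' `factor x factor` block of fine climate cells. Presence flags, region
#' membership and mean elevation are tracked per coarse cell.
#'
#' @param nrow,ncol Coarse grid dimensions.
#' @param factor Fine cells per coarse cell edge.
#' @param cellsize_km Coarse cell edge length in km (default 50).
#' @param presence Logical vector (length `nrow * ncol`, row-major from the
#'   north-west) flagging occupied cells.
#' @param region_id Character vector per coarse cell (`NA` = unassigned).
#' @param elevation_m Mean elevation per coarse cell in meters.
#' @return Object of class `coarse_grid` with a `cells` data.frame
#'   (`cell_id,row,col,presence,region_id,elevation_m,x_km,y_km`).
#' @export
coarse_grid <- function(nrow, ncol, factor, cellsize_km = 50,
                        presence = rep(FALSE, nrow * ncol),
                        region_id = rep(NA_character_, nrow * ncol),
                        elevation_m = rep(NA_real_, nrow * ncol)) {
  if (nrow < 1 || ncol < 1 || factor < 1) stop("non-positive grid dimensions")
  n <- nrow * ncol
  stopifnot(length(presence) == n, length(region_id) == n,
            length(elevation_m) == n)
  rows <- rep(seq_len(nrow), each = ncol)
  cols <- rep(seq_len(ncol), times = nrow)
  cells <- data.frame(
    cell_id = seq_len(n), row = rows, col = cols,
    presence = as.logical(presence), region_id = as.character(region_id),
    elevation_m = as.numeric(elevation_m),
    x_km = (cols - 0.5) * cellsize_km,
    y_km = (nrow - rows + 0.5) * cellsize_km
  )
  structure(list(cells = cells, nrow = nrow, ncol = ncol, factor = factor,
                 cellsize_km = cellsize_km),
            class = "coarse_grid")
}

#' @export
print.coarse_grid <- function(x, ...) {
  cat(sprintf("coarse_grid: %d x %d cells (%g km), %d presences, factor %d\n",
              x$nrow, x$ncol, x$cellsize_km, sum(x$cells$presence), x$factor))
  invisible(x)
}

#' Read/write the coarse grid cell table
#'
#' CSV columns: `cell_id,row,col,presence,region_id,elevation_m`.
#' @param grid A [coarse_grid()]; `file` path for the CSV.
#' @export
write_coarse_grid <- function(grid, file) {
  utils::write.csv(grid$cells[, c("cell_id", "row", "col", "presence",
                                  "region_id", "elevation_m")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_coarse_grid
#' @param nrow,ncol,factor,cellsize_km Geometry (not stored in the CSV).
#' @export
read_coarse_grid <- function(file, nrow, ncol, factor, cellsize_km = 50) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  df <- df[order(df$cell_id), ]
  coarse_grid(nrow, ncol, factor, cellsize_km,
              presence = df$presence, region_id = df$region_id,
              elevation_m = df$elevation_m)
}

# map every fine cell (row-major index) to its owning coarse cell id
fine_to_coarse_index <- function(grid, fine_nrow, fine_ncol) {
  f <- grid$factor
  stopifnot(fine_nrow == grid$nrow * f, fine_ncol == grid$ncol * f)
  coarse_row <- ceiling(rep(seq_len(fine_nrow), times = fine_ncol) / f)
  coarse_col <- ceiling(rep(seq_len(fine_ncol), each = fine_nrow) / f)
  (coarse_row - 1L) * grid$ncol + coarse_col  # column-major fine traversal
}

#' Extreme-cell climate features per coarse cell
#'
#' For each coarse cell and each of the four base variables, takes the
#' minimum and maximum over the valid fine cells the coarse cell owns --
#' i.e. the coldest/warmest and driest/wettest fine locations inside each
#' occupancy square -- yielding eight features. This captures the local
#' climate extremes a coarse presence square actually offers a montane
#' species, rather than the block average.
#'
#' @param fine_layers Named list of four [grid_raster()]s (names `BASE_VARS`),
#'   sharing geometry, each `factor` times finer than the coarse grid.
#' @param grid A [coarse_grid()].
#' @return data.frame of class `feature_table`: `cell_id` plus 8 columns
#'   `<var>_min`, `<var>_max`. Coarse cells with zero valid fine cells get
#'   all-`NA` rows with a warning.
#' @export
extract_features <- function(fine_layers, grid) {
  stopifnot(inherits(grid, "coarse_grid"))
  if (!all(BASE_VARS %in% names(fine_layers))) {
    stop("fine_layers must be named: ", paste(BASE_VARS, collapse = ", "))
  }
  dims <- dim(fine_layers[[BASE_VARS[1]]]$data)
  for (v in BASE_VARS) {
    if (!identical(dim(fine_layers[[v]]$data), dims)) {
      stop("fine layers do not share geometry")
    }
  }
  idx <- fine_to_coarse_index(grid, dims[1], dims[2])
  n <- grid$nrow * grid$ncol
  out <- data.frame(cell_id = seq_len(n))
  for (v in BASE_VARS) {
    vals <- as.vector(fine_layers[[v]]$data)  # column-major, matches idx
    mn <- tapply(vals, idx, function(z) if (all(is.na(z))) NA_real_ else
      min(z, na.rm = TRUE))
    mx <- tapply(vals, idx, function(z) if (all(is.na(z))) NA_real_ else
      max(z, na.rm = TRUE))
    out[[paste0(v, "_min")]] <- as.numeric(mn[as.character(seq_len(n))])
    out[[paste0(v, "_max")]] <- as.numeric(mx[as.character(seq_len(n))])
  }
  if (anyNA(out[, -1])) {
    warning(sum(!stats::complete.cases(out[, -1])),
            " coarse cell(s) have no valid fine cells; rows masked")
  }
  class(out) <- c("feature_table", "data.frame")
  out
}

#' The eight feature column names
#' @export
feature_names <- function() {
  as.vector(t(outer(BASE_VARS, c("_min", "_max"), paste0)))
}
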