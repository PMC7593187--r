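#' Minimal in-memory raster
#'
#' A rectangular grid of real values with a no-data sentinel, stored row-major
#' from the north-west corner (row 1 = northernmost). Coordinates refer to
#' cell centers; `xll`/`yll` give the lower-left corner of the grid extent.
#' All layers in one analysis are expected to share this geometry.
#'
#' @param data Numeric matrix (rows = north to south). `NA` marks no-data.
#' @param cellsize Cell edge length (same units as the coordinate system;
#'   kilometers for planar synthetic worlds).
#' @param xll,yll Coordinates of the lower-left corner of the extent.
#' @return Object of class `grid_raster`.
#' @export
grid_raster <- function(data, cellsize = 1, xll = 0, yll = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("raster data must be numeric")
  if (cellsize <= 0) stop("cellsize must be > 0")
  structure(list(data = data, cellsize = cellsize, xll = xll, yll = yll),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d cells, cellsize %g, origin (%g, %g)\n",
              nrow(x$data), ncol(x$data), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$data)

same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(c(a$cellsize, a$xll, a$yll), c(b$cellsize, b$xll, b$yll)))
}

# cell-center coordinates; row 1 is the northern edge
raster_centers <- function(r) {
  nr <- nrow(r$data); nc <- ncol(r$data)
  x <- r$xll + (seq_len(nc) - 0.5) * r$cellsize
  y <- r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize
  list(x = x, y = y)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param file Path to an ASCII grid. Supports `xllcorner`/`yllcorner` and
#'   `xllcenter`/`yllcenter` headers; `NODATA_value` cells become `NA`.
#' @return A [grid_raster()].
#' @export
read_asc <- function(file) {
  lines <- readLines(file, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[2]))) &&
        grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header in ", file)
  vals <- scan(file, skip = n_hdr, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("ASCII grid size mismatch in ", file)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  grid_raster(m, hdr$cellsize, xll, yll)
}

#' Write a raster as an ESRI ASCII grid (.asc)
#'
#' @param r A [grid_raster()].
#' @param file Output path.
#' @param nodata Sentinel written for `NA` cells (default -9999).
#' @export
write_asc <- function(r, file, nodata = -9999) {
  stopifnot(inherits(r, "grid_raster"))
  m <- r$data
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(m, 1, function(row) paste(format(row, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(c(hdr, body), file)
  invisible(file)
}
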