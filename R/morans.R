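#' Moran's I spatial autocorrelation for cell values
#'
#' Builds a spatial weight matrix from cell-center coordinates -- rook
#' contiguity (neighbors one cell step apart) or inverse distance -- then
#' evaluates Moran's I with row-standardized weights and a p-value from the
#' normal approximation under the randomization assumption (delegated to
#' \code{ape::Moran.I}, which row-standardizes internally).
#'
#' @param values Numeric vector (>= 3 non-constant values).
#' @param coords Two-column matrix/data.frame of cell-center x,y.
#' @param scheme `"rook"` or `"inverse-distance"`.
#' @param cellsize Cell edge for rook contiguity; inferred as the minimum
#'   positive center distance when `NULL`.
#' @return List `I, expected, sd, p`.
#' @export
morans_i <- function(values, coords, scheme = c("rook", "inverse-distance"),
                     cellsize = NULL) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("zero variance")
  if (nrow(coords) != n) stop("coords must match values")
  d <- as.matrix(stats::dist(coords))
  w <- if (scheme == "rook") {
    if (is.null(cellsize)) cellsize <- min(d[d > 0])
    (abs(d - cellsize) < 1e-9) * 1
  } else {
    iw <- 1 / d
    diag(iw) <- 0
    iw
  }
  if (all(w == 0)) stop("weight matrix is empty; no neighbors under scheme")
  res <- ape::Moran.I(values, weight = w, scaled = FALSE)
  list(I = res$observed, expected = res$expected, sd = res$sd,
       p = res$p.value)
}
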