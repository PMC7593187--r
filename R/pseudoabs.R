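#' Sample buffered pseudo-absences around presence cells
#'
#' Candidate absences are the non-presence coarse cells whose centers lie
#' within `buffer_km` of any presence center; restricting pseudo-absences to
#' this buffer avoids placing "absences" in distant mountain systems the
#' species never had a chance to occupy. A uniform random sample of
#' `min(ratio * n_presences, n_candidates)` candidates (without replacement,
#' seeded) is labeled 0 and returned together with the presences labeled 1.
#'
#' Distances are Euclidean on planar cell centers (synthetic worlds are
#' planar, in km); great-circle distance would replace this for geographic
#' coordinates.
#'
#' @param grid A [coarse_grid()] with at least one presence.
#' @param buffer_km Buffer radius in km (default 250).
#' @param ratio Pseudo-absences per presence (default 3).
#' @param seed Integer seed.
#' @return data.frame `cell_id,label` (label 1 = presence, 0 = pseudo-absence).
#' @export
sample_pseudo_absences <- function(grid, buffer_km = 250, ratio = 3, seed = 1L) {
  stopifnot(inherits(grid, "coarse_grid"))
  cells <- grid$cells
  pres <- cells[cells$presence, ]
  if (nrow(pres) == 0) stop("no presence cells")
  abs_cells <- cells[!cells$presence, ]
  if (nrow(abs_cells) > 0) {
    d2min <- vapply(seq_len(nrow(abs_cells)), function(i) {
      min((abs_cells$x_km[i] - pres$x_km)^2 + (abs_cells$y_km[i] - pres$y_km)^2)
    }, numeric(1))
    candidates <- abs_cells$cell_id[d2min <= buffer_km^2]
  } else {
    candidates <- integer(0)
  }
  if (length(candidates) == 0) stop("buffer excludes all absences")
  n_draw <- min(round(ratio * nrow(pres)), length(candidates))
  rng <- local_rng(seed)
  on.exit(rng())
  drawn <- sample(candidates, n_draw)
  rbind(
    data.frame(cell_id = pres$cell_id, label = 1L),
    data.frame(cell_id = sort(drawn), label = 0L)
  )
}
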