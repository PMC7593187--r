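#' Presence/absence threshold for suitability maps
#'
#' Fixed mode returns the supplied probability (the study convention is the
#' ensemble probability at the species' low-elevation climatic range edge);
#' range-edge mode derives it as the current ensemble probability of the
#' occupied coarse cell with the lowest mean elevation.
#'
#' @param current Current [suitability_map()].
#' @param grid A [coarse_grid()].
#' @param mode `"fixed"` or `"range-edge"`.
#' @param value Threshold in (0, 1) for fixed mode (default 0.49).
#' @return Threshold probability (scalar). Range-edge mode attaches the
#'   deriving `cell_id` as attribute `derived_from`.
#' @export
derive_threshold <- function(current, grid, mode = c("fixed", "range-edge"),
                             value = 0.49) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (!(value > 0 && value < 1)) stop("threshold must be in (0, 1)")
    return(value)
  }
  occ <- grid$cells[grid$cells$presence, ]
  if (nrow(occ) == 0) stop("no occupied cells")
  if (all(is.na(occ$elevation_m))) stop("occupied cells lack elevation data")
  lowest <- occ$cell_id[which.min(occ$elevation_m)]
  thr <- current$prob[lowest]
  if (is.na(thr)) stop("range-edge cell is masked in the current map")
  attr(thr, "derived_from") <- lowest
  thr
}

#' Classify coarse-cell fates under a future scenario
#'
#' Converts probabilities to presence/absence at `threshold` (suitable means
#' probability >= threshold) and classifies each cell: occupied and
#' future-suitable = `persistence`; occupied and future-unsuitable =
#' `extinction`; unoccupied and future-suitable = `colonization`; otherwise
#' `absent`.
#'
#' @param current,future [suitability_map()]s sharing geometry.
#' @param grid A [coarse_grid()].
#' @param threshold Suitability threshold probability.
#' @param scenario Scenario tag stored with the classification.
#' @return data.frame `cell_id, scenario, class` (class is a factor with
#'   levels persistence/extinction/colonization/absent).
#' @export
classify_cells <- function(current, future, grid, threshold,
                           scenario = future$tag) {
  if (length(current$prob) != length(future$prob) ||
      length(current$prob) != nrow(grid$cells)) {
    stop("geometry mismatch between maps and grid")
  }
  occ <- grid$cells$presence
  fut_suit <- !is.na(future$prob) & future$prob >= threshold
  cls <- ifelse(occ & fut_suit, "persistence",
         ifelse(occ & !fut_suit, "extinction",
         ifelse(fut_suit, "colonization", "absent")))
  data.frame(cell_id = grid$cells$cell_id, scenario = scenario,
             class = factor(cls, levels = c("persistence", "extinction",
                                            "colonization", "absent")))
}

#' Per-region range change from cell fates
#'
#' Range change is computed over currently occupied cells only:
#' `100 * (n_persisting - n_occupied) / n_occupied` (so it is <= 0; projected
#' colonization is reported separately, never netted against losses). A
#' region whose occupied cells all go extinct is marked `region_lost` with a
#' change of -100. Regions can be pooled for reporting via `aliases`
#' (e.g. several massif subranges reported as one mountain system).
#'
#' @param fates Output of [classify_cells()].
#' @param grid A [coarse_grid()] with `region_id` set on occupied cells.
#' @param aliases Optional named character vector mapping region_id to a
#'   pooled reporting label.
#' @return data.frame `region, n_occupied, n_persisting, n_colonizing,
#'   range_change_pct, region_lost`, one row per (pooled) region with at
#'   least one occupied cell; regions with zero occupied cells are dropped
#'   with a warning.
#' @export
range_change <- function(fates, grid, aliases = NULL) {
  cells <- grid$cells
  region <- cells$region_id
  if (!is.null(aliases)) {
    hit <- region %in% names(aliases)
    region[hit] <- aliases[region[hit]]
  }
  occ <- cells$presence
  if (any(occ & is.na(region))) {
    stop("occupied cell(s) without a region assignment: ",
         paste(utils::head(cells$cell_id[occ & is.na(region)], 5),
               collapse = ", "))
  }
  cls <- fates$class[match(cells$cell_id, fates$cell_id)]
  regs <- sort(unique(region[!is.na(region)]))
  rows <- lapply(regs, function(rg) {
    in_rg <- !is.na(region) & region == rg
    n_occ <- sum(in_rg & occ)
    if (n_occ == 0) {
      warning("region '", rg, "' has no occupied cells; excluded")
      return(NULL)
    }
    n_per <- sum(in_rg & occ & cls == "persistence")
    n_col <- sum(in_rg & !occ & cls == "colonization")
    data.frame(region = rg, n_occupied = n_occ, n_persisting = n_per,
               n_colonizing = n_col,
               range_change_pct = 100 * (n_per - n_occ) / n_occ,
               region_lost = n_per == 0L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Haplotype-risk statistic H_r
#'
#' Region-unique haplotypes are assumed at risk when every occupied coarse
#' cell of their region is projected to become climatically unsuitable
#' (the region is "lost"). `Hr` is the total count of unique haplotypes over
#' lost regions:
#' \deqn{H_r = \sum_{r : \mathrm{lost}(r)} H_u(r)}
#'
#' @param regions data.frame with columns `region` and `region_lost`
#'   (typically from [range_change()]), or with a `range_change_pct` column
#'   from which `region_lost` is derived as change == -100.
#' @param diversity data.frame with columns `region` and `Hu` (e.g. from
#'   [diversity_table()], excluding the "All" row). Every genetics region
#'   must appear in the spatial layer.
#' @param table Optional `haplotype_table` used to list the at-risk
#'   haplotype ids (region-unique haplotypes of lost regions).
#' @param aliases Optional named character vector mapping genetic region ids
#'   onto the spatial layer's (possibly pooled) region labels.
#' @return List: `Hr`, `lost_regions`, `at_risk_haplotypes` (integer ids,
#'   or `NULL` when no `table` given).
#' @export
haplotypes_at_risk <- function(regions, diversity, table = NULL,
                               aliases = NULL) {
  if (!"region_lost" %in% names(regions)) {
    if (!"range_change_pct" %in% names(regions)) {
      stop("regions needs a region_lost or range_change_pct column")
    }
    regions$region_lost <- regions$range_change_pct <= -100
  }
  map_region <- function(x) {
    x <- as.character(x)
    if (!is.null(aliases)) {
      hit <- x %in% names(aliases)
      x[hit] <- aliases[x[hit]]
    }
    x
  }
  gen_regions <- map_region(diversity$region)
  keep <- as.character(diversity$region) != "All"
  missing <- setdiff(gen_regions[keep], as.character(regions$region))
  if (length(missing) > 0) {
    stop("region(s) present in genetics but absent from spatial layer: ",
         paste(missing, collapse = ", "))
  }
  lost <- as.character(regions$region[regions$region_lost])
  Hr <- sum(diversity$Hu[keep & gen_regions %in% lost])
  at_risk <- NULL
  if (!is.null(table)) {
    uniq <- rowSums(table$counts > 0) == 1L
    home <- map_region(
      colnames(table$counts)[apply(table$counts > 0, 1, which.max)])
    at_risk <- table$hap_id[uniq & home %in% lost]
  }
  list(Hr = Hr, lost_regions = lost, at_risk_haplotypes = at_risk)
}

#' Linear trend of suitability change with elevation
#'
#' Ordinary least-squares regression of per-cell probability change on mean
#' cell elevation; used to show whether projected losses concentrate at low
#' elevations.
#'
#' @param delta_p Per-cell change in ensemble probability (future - current).
#' @param elevation_m Per-cell mean elevation (non-constant, >= 3 cells).
#' @return List `slope, intercept, r2, F, df, p`.
#' @export
elevation_trend <- function(delta_p, elevation_m) {
  ok <- !is.na(delta_p) & !is.na(elevation_m)
  delta_p <- delta_p[ok]; elevation_m <- elevation_m[ok]
  if (length(delta_p) < 3) stop("need at least 3 cells")
  if (stats::sd(elevation_m) == 0) stop("constant elevation")
  if (stats::sd(delta_p) == 0) {
    return(list(slope = 0, intercept = delta_p[1], r2 = 0, F = 0,
                df = c(1, length(delta_p) - 2), p = 1))
  }
  fit <- stats::lm(delta_p ~ elevation_m)
  sm <- summary(fit)
  Fst <- sm$fstatistic
  p <- if (is.null(Fst)) 1 else
    stats::pf(Fst[1], Fst[2], Fst[3], lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       F = if (is.null(Fst)) 0 else unname(Fst[1]),
       df = c(1, length(delta_p) - 2),
       p = unname(p))
}

#' Full per-scenario risk report
#'
#' Runs [classify_cells()], [range_change()] and [haplotypes_at_risk()] for
#' one future scenario and bundles the results.
#'
#' @inheritParams classify_cells
#' @param diversity Per-region diversity table (see [haplotypes_at_risk()]).
#' @param table Optional `haplotype_table` for at-risk haplotype ids.
#' @param aliases Optional region pooling map (see [range_change()]).
#' @return List of class `risk_report`: `scenario`, `fates`, `regions`,
#'   `Hr`, `lost_regions`, `at_risk_haplotypes`, `threshold`.
#' @export
risk_report <- function(current, future, grid, threshold, diversity,
                        table = NULL, aliases = NULL, scenario = future$tag) {
  fates <- classify_cells(current, future, grid, threshold, scenario)
  regions <- range_change(fates, grid, aliases)
  hr <- haplotypes_at_risk(regions, diversity, table, aliases)
  structure(list(scenario = scenario, fates = fates, regions = regions,
                 Hr = hr$Hr, lost_regions = hr$lost_regions,
                 at_risk_haplotypes = hr$at_risk_haplotypes,
                 threshold = threshold),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("risk_report [%s] threshold %.3g: Hr = %d, %d region(s) lost\n",
              x$scenario, x$threshold, x$Hr, length(x$lost_regions)))
  if (length(x$lost_regions)) {
    cat("  lost:", paste(x$lost_regions, collapse = ", "), "\n")
  }
  invisible(x)
}
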