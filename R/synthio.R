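#' Specification of a synthetic study world
#'
#' Defines a fully deterministic synthetic landscape, climate, occupancy and
#' regional sequence panel with known ground truth, emulating the data shape
#' of a continental phylogeography + SDM study: 13 mountain regions, 215 COI
#' sequences of 649 bp collapsing to 31 haplotypes (27 region-unique), a
#' coarse 50-km occupancy lattice over fine ~5-km climate cells, 21
#' millennial paleoclimate slices back to a glacial maximum, and two future
#' warming scenarios.
#'
#' Temperature follows elevation at a fixed lapse rate plus smooth seeded
#' noise; precipitation has an orographic gain. True suitability is a
#' logistic in the eight extreme-cell features (by default driven by the
#' minimum warmest-quarter temperature, the key variable for a cold-adapted
#' species). The warming trajectory ramps linearly from the glacial offset to
#' the present; ice covers cells whose coldest-quarter temperature falls
#' below `ice_cutoff_C`.
#'
#' @param coarse_nrow,coarse_ncol Coarse grid dimensions (default 20 x 20).
#' @param factor Fine cells per coarse edge (default 10).
#' @param cellsize_km Coarse cell edge (default 50 km).
#' @param lapse_rate Temperature lapse rate in degrees C per km (default -6.5).
#' @param t_warm_base,t_cold_base Sea-level quarter temperatures (degrees C).
#' @param p_warm_base,p_cold_base Base quarterly precipitation (mm).
#' @param orography_gain Precipitation gain per km elevation (mm).
#' @param noise_sd_t,noise_sd_p Smooth-noise standard deviations.
#' @param regions data.frame `region,row,col,peak_m,sd_km` of ridge centers
#'   (coarse row/col), summit elevations and ridge widths; default 13 ridges.
#' @param true_coef Named logistic coefficients: `intercept` plus any of the
#'   eight feature names.
#' @param occupancy_threshold True-probability cutoff for presence.
#' @param lgm_offset_C Temperature anomaly at the glacial maximum (default -4).
#' @param ice_cutoff_C Coldest-quarter temperature below which a coarse cell
#'   is ice-covered (default -12).
#' @param scenario_offsets Named warming offsets (degrees C) for future
#'   scenarios (default `c(low = 1, high = 2.5)`).
#' @param seq_length Alignment length (default 649).
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class `world_spec`.
#' @export
world_spec <- function(coarse_nrow = 20, coarse_ncol = 20, factor = 10,
                       cellsize_km = 50,
                       lapse_rate = -6.5,
                       t_warm_base = 16, t_cold_base = 2,
                       p_warm_base = 200, p_cold_base = 120,
                       orography_gain = 150,
                       noise_sd_t = 0.4, noise_sd_p = 15,
                       regions = default_regions(),
                       true_coef = c(intercept = 8.1, T_warmQ_min = -0.9),
                       occupancy_threshold = 0.5,
                       lgm_offset_C = -4,
                       ice_cutoff_C = -12,
                       scenario_offsets = c(low = 1, high = 2.5),
                       seq_length = 649,
                       seed = 20200930) {
  if (coarse_nrow < 1 || coarse_ncol < 1 || factor < 1) {
    stop("non-positive grid dimensions")
  }
  structure(list(
    coarse_nrow = coarse_nrow, coarse_ncol = coarse_ncol, factor = factor,
    cellsize_km = cellsize_km, lapse_rate = lapse_rate,
    t_warm_base = t_warm_base, t_cold_base = t_cold_base,
    p_warm_base = p_warm_base, p_cold_base = p_cold_base,
    orography_gain = orography_gain,
    noise_sd_t = noise_sd_t, noise_sd_p = noise_sd_p,
    regions = regions, true_coef = true_coef,
    occupancy_threshold = occupancy_threshold,
    lgm_offset_C = lgm_offset_C, ice_cutoff_C = ice_cutoff_C,
    scenario_offsets = scenario_offsets,
    seq_length = seq_length, seed = as.integer(seed)
  ), class = "world_spec")
}

#' Default 13-region ridge layout
#'
#' Thirteen mountain ridges scattered over the default 20 x 20 coarse grid,
#' with varying summit heights so that regions differ in how close their
#' occupied cells sit to the species' warm range edge.
#' @return data.frame `region,row,col,peak_m,sd_km`.
#' @export
default_regions <- function() {
  data.frame(
    region = sprintf("R%02d", 1:13),
    row  = c(3,  3,  8, 17,  6, 12, 17, 12,  3, 17,  8, 12,  8),
    col  = c(3, 10,  6,  3, 17, 10,  9, 17, 17, 17,  13, 3,  2),
    peak_m = c(1250, 1400, 2100, 1500, 1350, 2600, 1800, 2200,
               1700, 1450, 2500, 2300, 1900),
    sd_km  = c(60, 70, 90, 70, 60, 110, 80, 90, 75, 65, 100, 95, 80)
  )
}

# deterministic sub-seeds per generator stage (kept < 2^31)
stage_seed <- function(spec, stage) {
  offs <- c(landscape = 11L, sequences = 23L, timeseries = 37L)
  (spec$seed + offs[[stage]]) %% .Machine$integer.max
}

# smooth seeded noise: coarse random field bilinearly upsampled to fine dims
smooth_noise <- function(nr, nc, sd, knots = 8) {
  if (sd == 0) return(matrix(0, nr, nc))
  kr <- max(2, min(knots, nr)); kc <- max(2, min(knots, nc))
  field <- matrix(stats::rnorm(kr * kc, sd = sd), kr, kc)
  xs <- seq(1, nc, length.out = kc)
  ys <- seq(1, nr, length.out = kr)
  xp <- rep(seq_len(nc), each = nr)
  yp <- rep(seq_len(nr), times = nc)
  matrix(pracma::interp2(xs, ys, field, as.numeric(xp), as.numeric(yp),
                         method = "linear"), nrow = nr, ncol = nc)
}

#' Generate the synthetic landscape and current climate
#'
#' Elevation is a sum of Gaussian ridges over a 100-m plain. Temperature
#' layers are sea-level bases plus `lapse_rate * elevation` plus smooth
#' seeded noise; precipitation layers are bases plus an orographic term plus
#' noise (floored at 0). Every coarse cell is assigned to the region of its
#' nearest ridge center and carries its block-mean elevation.
#'
#' @param spec A [world_spec()].
#' @return List: `elevation` (fine [grid_raster()]), `climate` (named list of
#'   four fine rasters), `grid` (a [coarse_grid()] without presences).
#' @export
make_landscape <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  f <- spec$factor
  nr <- spec$coarse_nrow * f
  nc <- spec$coarse_ncol * f
  fine_size <- spec$cellsize_km / f
  x <- (seq_len(nc) - 0.5) * fine_size
  y <- (nr - seq_len(nr) + 0.5) * fine_size
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  elev <- matrix(100, nr, nc)
  for (i in seq_len(nrow(spec$regions))) {
    rg <- spec$regions[i, ]
    cx <- (rg$col - 0.5) * spec$cellsize_km
    cy <- (spec$coarse_nrow - rg$row + 0.5) * spec$cellsize_km
    d2 <- (X - cx)^2 + (Y - cy)^2
    elev <- elev + (rg$peak_m - 100) * exp(-d2 / (2 * rg$sd_km^2))
  }
  rng <- local_rng(stage_seed(spec, "landscape"))
  on.exit(rng())
  ek <- elev / 1000
  climate <- list(
    T_warmQ = spec$t_warm_base + spec$lapse_rate * ek +
      smooth_noise(nr, nc, spec$noise_sd_t),
    T_coldQ = spec$t_cold_base + spec$lapse_rate * ek +
      smooth_noise(nr, nc, spec$noise_sd_t),
    P_warmQ = pmax(spec$p_warm_base + spec$orography_gain * ek +
                     smooth_noise(nr, nc, spec$noise_sd_p), 0),
    P_coldQ = pmax(spec$p_cold_base + spec$orography_gain * ek +
                     smooth_noise(nr, nc, spec$noise_sd_p), 0)
  )
  climate <- lapply(climate[BASE_VARS], grid_raster, cellsize = fine_size)
  elev_r <- grid_raster(elev, fine_size)

  grid0 <- coarse_grid(spec$coarse_nrow, spec$coarse_ncol, f, spec$cellsize_km)
  idx <- fine_to_coarse_index(grid0, nr, nc)
  mean_elev <- as.numeric(tapply(as.vector(elev), idx, mean))
  cx_r <- (spec$regions$col - 0.5) * spec$cellsize_km
  cy_r <- (spec$coarse_nrow - spec$regions$row + 0.5) * spec$cellsize_km
  nearest <- vapply(seq_len(nrow(grid0$cells)), function(i) {
    which.min((grid0$cells$x_km[i] - cx_r)^2 + (grid0$cells$y_km[i] - cy_r)^2)
  }, integer(1))
  grid <- coarse_grid(spec$coarse_nrow, spec$coarse_ncol, f, spec$cellsize_km,
                      region_id = spec$regions$region[nearest],
                      elevation_m = mean_elev)
  list(elevation = elev_r, climate = climate, grid = grid)
}

# linear predictor of the true logistic on a feature table
true_linear_predictor <- function(spec, features) {
  eta <- rep(spec$true_coef[["intercept"]], nrow(features))
  for (nm in setdiff(names(spec$true_coef), "intercept")) {
    eta <- eta + spec$true_coef[[nm]] * features[[nm]]
  }
  eta
}

#' Evaluate the generator's true suitability model
#'
#' @param spec A [world_spec()].
#' @param fine_layers Named list of the four fine climate rasters.
#' @param grid The coarse grid.
#' @param tag Provenance tag.
#' @return A [suitability_map()] of true probabilities.
#' @export
true_suitability <- function(spec, fine_layers, grid, tag = "truth") {
  feats <- extract_features(fine_layers, grid)
  suitability_map(stats::plogis(true_linear_predictor(spec, feats)), tag = tag)
}

#' Derive occupancy from the true suitability model
#'
#' Presence wherever the true probability reaches the occupancy threshold.
#'
#' @param landscape Output of [make_landscape()].
#' @param spec A [world_spec()].
#' @return The landscape's [coarse_grid()] with presences set; the true
#'   probability vector is attached as attribute `truth`.
#' @export
make_occupancy <- function(landscape, spec) {
  truth <- true_suitability(spec, landscape$climate, landscape$grid)
  pres <- !is.na(truth$prob) & truth$prob >= spec$occupancy_threshold
  if (!any(pres)) stop("world uninhabitable, adjust spec")
  grid <- landscape$grid
  grid$cells$presence <- pres
  attr(grid, "truth") <- truth$prob
  grid
}

#' Generate the 21-slice paleoclimate anomaly series with ice masks
#'
#' Temperature anomalies ramp linearly from `lgm_offset_C` at 21 ka to near
#' zero at 1 ka, applied uniformly (precipitation anomalies are zero).
#' Anomaly rasters are emitted on a deliberately coarse lattice (emulating a
#' low-resolution paleoclimate product) spanning the same extent; the ice
#' mask covers coarse cells whose slice coldest-quarter temperature falls
#' below the cutoff.
#'
#' @param spec A [world_spec()].
#' @param landscape Output of [make_landscape()].
#' @param anomaly_dims Rows/cols of the coarse anomaly lattice (default 5x5).
#' @return A [timeslice_set()] with 21 slices (21 ka ... 1 ka).
#' @export
make_timeseries <- function(spec, landscape, anomaly_dims = c(5, 5)) {
  ages <- 21:1
  offsets <- spec$lgm_offset_C * ages / max(ages)
  grid <- landscape$grid
  fine_t_cold <- landscape$climate$T_coldQ
  idx <- fine_to_coarse_index(grid, nrow(fine_t_cold$data),
                              ncol(fine_t_cold$data))
  coarse_t_cold <- as.numeric(tapply(as.vector(fine_t_cold$data), idx, mean))
  extent_km <- c(spec$coarse_ncol, spec$coarse_nrow) * spec$cellsize_km
  anom_size <- extent_km[1] / anomaly_dims[2]
  slices <- lapply(seq_along(ages), function(k) {
    dT <- offsets[k]
    anomalies <- list(
      T_warmQ = grid_raster(matrix(dT, anomaly_dims[1], anomaly_dims[2]),
                            anom_size),
      T_coldQ = grid_raster(matrix(dT, anomaly_dims[1], anomaly_dims[2]),
                            anom_size),
      P_warmQ = grid_raster(matrix(0, anomaly_dims[1], anomaly_dims[2]),
                            anom_size),
      P_coldQ = grid_raster(matrix(0, anomaly_dims[1], anomaly_dims[2]),
                            anom_size)
    )
    iced <- (coarse_t_cold + dT) < spec$ice_cutoff_C
    ice <- grid_raster(matrix(as.numeric(iced), grid$nrow, grid$ncol,
                              byrow = TRUE), spec$cellsize_km)
    list(age_ka = ages[k], anomalies = anomalies, ice = ice)
  })
  timeslice_set(slices, landscape$climate)
}

#' Future climate layers for a named warming scenario
#'
#' Applies the scenario's uniform warming offset to both temperature layers
#' (precipitation unchanged).
#'
#' @param spec A [world_spec()]; `landscape` from [make_landscape()].
#' @param scenario Name in `spec$scenario_offsets` (e.g. "low", "high"), or a
#'   numeric offset in degrees C.
#' @return Named list of four fine rasters.
#' @export
make_future <- function(spec, landscape, scenario = "high") {
  dT <- if (is.numeric(scenario)) scenario else {
    if (!scenario %in% names(spec$scenario_offsets)) {
      stop("unknown scenario: ", scenario)
    }
    spec$scenario_offsets[[scenario]]
  }
  out <- landscape$climate
  for (v in c("T_warmQ", "T_coldQ")) {
    out[[v]] <- grid_raster(out[[v]]$data + dT, out[[v]]$cellsize,
                            out[[v]]$xll, out[[v]]$yll)
  }
  out
}

#' Warming offset that extinguishes exactly one region
#'
#' From the generator's truth, computes for every occupied cell the uniform
#' warming at which its true suitability drops below the occupancy
#' threshold; the region whose most resistant occupied cell crosses first is
#' the designated target, and the returned offset is the midpoint between
#' its crossing point and the next region's. Under that offset the target
#' region loses all occupied cells while every other region keeps at least
#' one.
#'
#' @param spec A [world_spec()].
#' @param landscape Output of [make_landscape()].
#' @param grid Occupied [coarse_grid()] from [make_occupancy()].
#' @return List `offset_C`, `target_region`.
#' @export
plant_extinction_offset <- function(spec, landscape, grid) {
  b_T <- sum(spec$true_coef[grepl("^T_", names(spec$true_coef))])
  if (!(b_T < 0)) stop("true model must cool-limit (negative T coefficients)")
  feats <- extract_features(landscape$climate, grid)
  eta <- true_linear_predictor(spec, feats)
  # survives warming dT iff eta + b_T * dT >= logit(threshold)
  crossing <- (stats::qlogis(spec$occupancy_threshold) - eta) / b_T
  occ <- grid$cells$presence
  reg_max <- tapply(crossing[occ], grid$cells$region_id[occ], max)
  ord <- sort(unlist(reg_max))
  if (length(ord) < 2) stop("need at least two occupied regions")
  if (ord[2] - ord[1] < 1e-6) stop("no clean gap between regions; adjust spec")
  list(offset_C = unname((ord[1] + ord[2]) / 2),
       target_region = names(ord)[1])
}

#' Generate the regional COI sequence panel
#'
#' Draws a random root sequence and derives each planted haplotype by
#' substituting a specified number of globally distinct positions (sampled
#' without replacement), so every haplotype is distinct and pairwise planted
#' Hamming distances are exact. Haplotypes are emitted with their planted
#' per-region copy numbers; shared haplotypes appear identically in all
#' their regions. The default panel plants 31 haplotypes (27 region-unique,
#' 4 shared) across 13 regions in 215 sequences, mirroring a star-like
#' continental phylogeography.
#'
#' @param spec A [world_spec()].
#' @param panel data.frame `hap,regions,copies,n_mut` where `regions` and
#'   `copies` are comma-separated parallel lists; default [default_panel()].
#' @return List: `aln` (a [hap_alignment()]), `truth` (list with
#'   `n_haplotypes`, `n_unique`, `region_n`, `region_unique`).
#' @export
make_sequences <- function(spec, panel = default_panel()) {
  L <- spec$seq_length
  total_mut <- sum(panel$n_mut)
  if (any(panel$n_mut > L) || total_mut > L) {
    stop("mutations exceed sequence length")
  }
  rng <- local_rng(stage_seed(spec, "sequences"))
  on.exit(rng())
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)
  pos_pool <- sample.int(L, total_mut)
  hap_seqs <- character(nrow(panel))
  used <- 0L
  for (i in seq_len(nrow(panel))) {
    s <- root
    k <- panel$n_mut[i]
    if (k > 0) {
      pos <- pos_pool[(used + 1L):(used + k)]
      used <- used + k
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    }
    hap_seqs[i] <- paste(s, collapse = "")
  }
  seqs <- character(0); regs <- character(0)
  for (i in seq_len(nrow(panel))) {
    rr <- strsplit(panel$regions[i], ",", fixed = TRUE)[[1]]
    cc <- as.integer(strsplit(panel$copies[i], ",", fixed = TRUE)[[1]])
    stopifnot(length(rr) == length(cc))
    for (j in seq_along(rr)) {
      seqs <- c(seqs, rep(hap_seqs[i], cc[j]))
      regs <- c(regs, rep(rr[j], cc[j]))
    }
  }
  ord <- order(regs, seq_along(regs))  # emit region by region
  seqs <- seqs[ord]; regs <- regs[ord]
  aln <- hap_alignment(seqs, sprintf("s%03d", seq_along(seqs)), regs)
  n_unique <- sum(!grepl(",", panel$regions))
  region_list <- strsplit(panel$regions, ",", fixed = TRUE)
  all_regions <- sort(unique(unlist(region_list)))
  region_unique <- vapply(all_regions, function(r) {
    sum(vapply(region_list, function(x) identical(x, r), logical(1)))
  }, integer(1))
  copies <- lapply(strsplit(panel$copies, ",", fixed = TRUE), as.integer)
  region_n <- vapply(all_regions, function(r) {
    sum(unlist(Map(function(rl, cp) sum(cp[rl == r]), region_list, copies)))
  }, integer(1))
  truth <- list(n_haplotypes = nrow(panel), n_unique = n_unique,
                region_n = region_n, region_unique = region_unique)
  list(aln = aln, truth = truth)
}

#' Default planted haplotype panel
#'
#' 31 haplotypes over 13 regions: 4 shared across region sets and 27
#' region-unique, 215 sequences in total, substitution counts of 1-5 from
#' the root haplotype.
#' @return data.frame `hap,regions,copies,n_mut`.
#' @export
default_panel <- function() {
  df <- rbind(
    data.frame(hap = "s1", regions = "R01,R02,R05,R11",
               copies = "12,22,22,6", n_mut = 0),
    data.frame(hap = "s2", regions = "R02,R10", copies = "3,8", n_mut = 2),
    data.frame(hap = "s3", regions = "R03,R04,R08", copies = "8,8,10",
               n_mut = 3),
    data.frame(hap = "s4", regions = "R11,R09", copies = "3,6", n_mut = 1),
    data.frame(hap = "u_R02_1", regions = "R02", copies = "2", n_mut = 1),
    data.frame(hap = c("u_R03_1", "u_R03_2", "u_R03_3"), regions = "R03",
               copies = c("5", "3", "2"), n_mut = c(4, 1, 2)),
    data.frame(hap = "u_R04_1", regions = "R04", copies = "3", n_mut = 4),
    data.frame(hap = sprintf("u_R05_%d", 1:6), regions = "R05",
               copies = c("6", "7", "5", "3", "2", "2"),
               n_mut = c(1, 2, 1, 3, 2, 1)),
    data.frame(hap = c("u_R06_1", "u_R06_2"), regions = "R06",
               copies = c("8", "5"), n_mut = c(5, 4)),
    data.frame(hap = c("u_R07_1", "u_R07_2"), regions = "R07",
               copies = c("6", "5"), n_mut = c(2, 3)),
    data.frame(hap = sprintf("u_R09_%d", 1:3), regions = "R09",
               copies = c("4", "3", "2"), n_mut = c(1, 2, 1)),
    data.frame(hap = "u_R10_1", regions = "R10", copies = "4", n_mut = 2),
    data.frame(hap = sprintf("u_R11_%d", 1:5), regions = "R11",
               copies = c("6", "4", "3", "2", "2"), n_mut = c(1, 1, 2, 3, 2)),
    data.frame(hap = c("u_R12_1", "u_R12_2"), regions = "R12",
               copies = c("5", "3"), n_mut = c(4, 5)),
    data.frame(hap = "u_R13_1", regions = "R13", copies = "5", n_mut = 3)
  )
  rownames(df) <- NULL
  df
}

#' Planted-loss ridge layout
#'
#' Variant of [default_regions()] in which region R05 -- the region planted
#' with six unique haplotypes in the default sequence panel -- swaps ridges
#' with R01, taking over the isolated low-summit ridge whose occupied cells
#' cross the suitability threshold first under uniform warming. The offset
#' from [plant_extinction_offset()] then designates R05 as the single region
#' to lose all occupied cells, so planted-extinction recovery checks operate
#' on a nonzero planted haplotype count.
#' @return data.frame `region,row,col,peak_m,sd_km`.
#' @export
planted_loss_regions <- function() {
  rg <- default_regions()
  i1 <- rg$region == "R01"; i5 <- rg$region == "R05"
  swap <- c("row", "col", "peak_m", "sd_km")
  tmp <- rg[i1, swap]
  rg[i1, swap] <- rg[i5, swap]
  rg[i5, swap] <- tmp
  rg
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: landscape, occupancy (with truth), time slices,
#' future scenarios and the sequence panel, all from one spec.
#'
#' @param spec A [world_spec()].
#' @return List `spec, elevation, climate, grid, truth, slices, sequences`.
#' @export
make_world <- function(spec = world_spec()) {
  landscape <- make_landscape(spec)
  grid <- make_occupancy(landscape, spec)
  slices <- make_timeseries(spec, landscape)
  seqs <- make_sequences(spec)
  list(spec = spec, elevation = landscape$elevation,
       climate = landscape$climate, grid = grid,
       truth = attr(grid, "truth"), slices = slices,
       sequences = seqs)
}

#' Write a synthetic world to disk
#'
#' FASTA + region CSV, elevation and climate `.asc` rasters, coarse-grid
#' CSV, a slice manifest with per-slice anomaly/ice rasters, and a truth
#' JSON.
#'
#' @param world Output of [make_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aln <- world$sequences$aln
  dna <- ape::as.DNAbin(strsplit(aln$seq, ""))
  names(dna) <- aln$sample_id
  ape::write.FASTA(dna, file.path(dir, "sequences.fasta"))
  utils::write.csv(data.frame(sample_id = aln$sample_id,
                              region_id = aln$region_id),
                   file.path(dir, "regions.csv"), row.names = FALSE,
                   quote = FALSE)
  write_asc(world$elevation, file.path(dir, "elevation.asc"))
  for (v in BASE_VARS) {
    write_asc(world$climate[[v]], file.path(dir, paste0(v, ".asc")))
  }
  write_coarse_grid(world$grid, file.path(dir, "grid.csv"))
  manifest <- do.call(rbind, lapply(world$slices$slices, function(s) {
    rows <- lapply(BASE_VARS, function(v) {
      ap <- sprintf("slice_%02d_%s.asc", s$age_ka, v)
      write_asc(s$anomalies[[v]], file.path(dir, ap))
      data.frame(age_ka = s$age_ka, var = v, anomaly_path = ap,
                 ice_path = sprintf("slice_%02d_ice.asc", s$age_ka))
    })
    write_asc(s$ice, file.path(dir, sprintf("slice_%02d_ice.asc", s$age_ka)))
    do.call(rbind, rows)
  }))
  utils::write.csv(manifest, file.path(dir, "slices.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(true_prob = world$truth,
         n_haplotypes = world$sequences$truth$n_haplotypes,
         n_unique = world$sequences$truth$n_unique,
         region_unique = as.list(world$sequences$truth$region_unique),
         seed = world$spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
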