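test_that("temperature follows the lapse-rate formula exactly without noise", {
  spec <- small_world_spec(noise_sd_t = 0, noise_sd_p = 0)
  ls <- make_landscape(spec)
  expect_equal(ls$climate$T_warmQ$data,
               spec$t_warm_base + spec$lapse_rate * ls$elevation$data / 1000)
  # 1000 m of relief is worth exactly one lapse rate
  e <- ls$elevation$data
  t <- ls$climate$T_warmQ$data
  i_hi <- which.max(e); i_lo <- which.min(e)
  expect_equal(t[i_lo] - t[i_hi],
               -spec$lapse_rate * (e[i_hi] - e[i_lo]) / 1000)
  # flat lapse rate means uniform temperature
  flat <- make_landscape(small_world_spec(lapse_rate = 0, noise_sd_t = 0))
  expect_equal(max(flat$climate$T_coldQ$data), min(flat$climate$T_coldQ$data))
})

test_that("the generator is bit-reproducible from its spec", {
  spec <- small_world_spec()
  w1 <- make_landscape(spec)
  w2 <- make_landscape(spec)
  expect_identical(w1$climate$T_warmQ$data, w2$climate$T_warmQ$data)
  expect_identical(w1$climate$P_coldQ$data, w2$climate$P_coldQ$data)
  s1 <- make_sequences(spec)
  s2 <- make_sequences(spec)
  expect_identical(s1$aln$seq, s2$aln$seq)
  # a different master seed moves the noise
  w3 <- make_landscape(small_world_spec(seed = 999))
  expect_false(identical(w1$climate$T_warmQ$data, w3$climate$T_warmQ$data))
})

test_that("occupancy is the superlevel set of true suitability", {
  spec <- small_world_spec()
  ls <- make_landscape(spec)
  grid <- make_occupancy(ls, spec)
  truth <- attr(grid, "truth")
  expect_identical(grid$cells$presence, truth >= spec$occupancy_threshold)
  expect_gt(sum(grid$cells$presence), 0)
  # an impossible threshold leaves the world uninhabitable
  spec_hot <- small_world_spec(occupancy_threshold = 1)
  expect_error(make_occupancy(make_landscape(spec_hot), spec_hot),
               "uninhabitable")
  # presences sit on the high ground: occupied cells are colder in summer
  feats <- extract_features(ls$climate, grid)
  occ <- grid$cells$presence
  expect_lt(max(feats$T_warmQ_min[occ]), max(feats$T_warmQ_min[!occ]))
})

test_that("hand-computable 3x3 world matches the logistic formula", {
  rg <- data.frame(region = "R1", row = 2, col = 2, peak_m = 2000,
                   sd_km = 40)
  spec <- world_spec(coarse_nrow = 3, coarse_ncol = 3, factor = 2,
                     regions = rg, noise_sd_t = 0, noise_sd_p = 0)
  ls <- make_landscape(spec)
  grid <- make_occupancy(ls, spec)
  feats <- extract_features(ls$climate, grid)
  expected <- plogis(spec$true_coef[["intercept"]] +
                       spec$true_coef[["T_warmQ_min"]] * feats$T_warmQ_min)
  expect_equal(attr(grid, "truth"), expected, tolerance = 1e-12)
})

test_that("the slice series ramps to the glacial offset and ices summits", {
  spec <- small_world_spec()
  ls <- make_landscape(spec)
  ts <- make_timeseries(spec, ls)
  expect_length(ts$slices, 21)
  ages <- vapply(ts$slices, `[[`, numeric(1), "age_ka")
  expect_equal(ages, 21:1)
  expect_equal(ts$slices[[1]]$anomalies$T_warmQ$data[1, 1], spec$lgm_offset_C)
  expect_equal(ts$slices[[21]]$anomalies$T_warmQ$data[1, 1],
               spec$lgm_offset_C / 21)
  expect_true(all(ts$slices[[5]]$anomalies$P_warmQ$data == 0))

  # with no glacial cooling (and a cutoff below every summit) nothing ices
  # and slices match the baseline
  spec0 <- small_world_spec(lgm_offset_C = 0, ice_cutoff_C = -100)
  ts0 <- make_timeseries(spec0, make_landscape(spec0))
  expect_true(all(vapply(ts0$slices,
                         function(s) all(s$ice$data == 0), logical(1))))
  expect_true(all(ts0$slices[[1]]$anomalies$T_coldQ$data == 0))

  # a cutoff between glacial and present summit temperature ices the summit
  # only in cold slices
  fine_t <- ls$climate$T_coldQ
  idx <- refugia:::fine_to_coarse_index(ls$grid, nrow(fine_t$data),
                                        ncol(fine_t$data))
  coarse_t <- as.numeric(tapply(as.vector(fine_t$data), idx, mean))
  summit <- which.min(coarse_t)
  cutoff <- coarse_t[summit] + spec$lgm_offset_C / 2
  ts2 <- make_timeseries(small_world_spec(ice_cutoff_C = cutoff), ls)
  iced <- vapply(ts2$slices,
                 function(s) refugia:::raster_to_cells(s$ice)[summit] > 0,
                 logical(1))
  expect_true(iced[1])       # glacial maximum
  expect_false(iced[21])     # near-present
  expect_true(all(diff(iced) <= 0))  # ice only retreats along the ramp
})

test_that("planted haplotypes carry their exact substitution counts", {
  spec <- small_world_spec()
  panel <- data.frame(hap = c("root", "h1", "h2"),
                      regions = c("R01", "R01", "R02"),
                      copies = c("2", "1", "3"), n_mut = c(0, 3, 5))
  out <- make_sequences(spec, panel)
  expect_equal(length(out$aln$seq), 6)
  haps <- collapse_haplotypes(out$aln)
  expect_equal(length(haps$hap_id), 3)
  d <- hamming_matrix(haps$sequence)
  root_seq <- unique(out$aln$seq[1:2])
  root_id <- which(haps$sequence == root_seq)
  others <- setdiff(1:3, root_id)
  expect_setequal(d[root_id, others], c(3, 5))
  expect_equal(d[others[1], others[2]], 8)  # disjoint substitution sites

  # a single zero-mutation haplotype collapses to monomorphism
  mono <- make_sequences(spec, data.frame(hap = "r", regions = "R01",
                                          copies = "4", n_mut = 0))
  h <- collapse_haplotypes(mono$aln)
  expect_equal(length(h$hap_id), 1)
  expect_error(make_sequences(spec, data.frame(hap = "x", regions = "R01",
                                               copies = "1", n_mut = 1e5)),
               "exceed")
})

test_that("the default panel reproduces the planted regional diversity", {
  spec <- world_spec()
  out <- make_sequences(spec)
  aln <- crop_and_filter(out$aln)
  expect_equal(aln$length, 649)
  expect_equal(length(aln$seq), 215)
  haps <- collapse_haplotypes(aln)
  div <- diversity_table(haps, aln)
  all_row <- div[div$region == "All", ]
  expect_equal(all_row$Hn, out$truth$n_haplotypes)  # 31 planted
  expect_equal(all_row$Hu, out$truth$n_unique)      # 27 region-unique
  expect_equal(all_row$Hn, 31)
  expect_equal(all_row$Hu, 27)
  reg <- div[div$region != "All", ]
  expect_equal(stats::setNames(reg$n, reg$region), out$truth$region_n)
  expect_equal(stats::setNames(reg$Hu, reg$region), out$truth$region_unique)
})

test_that("a world bundle writes and re-reads through the text formats", {
  spec <- small_world_spec()
  w <- make_world(spec)
  dir <- file.path(tempdir(), "world_io")
  write_world(w, dir)
  r <- read_asc(file.path(dir, "T_warmQ.asc"))
  expect_equal(r$data, w$climate$T_warmQ$data, tolerance = 1e-6)
  aln <- read_alignment(file.path(dir, "sequences.fasta"),
                        file.path(dir, "regions.csv"))
  expect_equal(aln$seq, w$sequences$aln$seq)
  grid2 <- read_coarse_grid(file.path(dir, "grid.csv"), spec$coarse_nrow,
                            spec$coarse_ncol, spec$factor)
  expect_equal(grid2$cells$presence, w$grid$cells$presence)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$n_haplotypes, 31)
  manifest <- read.csv(file.path(dir, "slices.csv"))
  expect_equal(sort(unique(manifest$age_ka)), 1:21)
  unlink(dir, recursive = TRUE)
})
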