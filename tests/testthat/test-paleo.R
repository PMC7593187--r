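test_that("delta downscaling adds the interpolated anomaly to the baseline", {
  base <- grid_raster(matrix(10, 4, 4), cellsize = 1)
  anom0 <- grid_raster(matrix(0, 2, 2), cellsize = 2)
  expect_equal(downscale_delta(anom0, base)$data, base$data)

  anom2 <- grid_raster(matrix(2, 2, 2), cellsize = 2)
  expect_equal(downscale_delta(anom2, base)$data, base$data + 2)

  # midway between coarse centers with anomalies 0 and 2 -> +1
  anom_grad <- grid_raster(matrix(c(0, 2), 1, 2), cellsize = 2)
  base_line <- grid_raster(matrix(0, 1, 3), cellsize = 1, xll = 0.5)
  out <- downscale_delta(anom_grad, base_line)
  expect_equal(as.numeric(out$data), c(0, 1, 2))

  # precipitation floor
  anom_neg <- grid_raster(matrix(-5, 2, 2), cellsize = 2)
  base_low <- grid_raster(matrix(1, 4, 4), cellsize = 1)
  expect_equal(downscale_delta(anom_neg, base_low, floor_zero = TRUE)$data,
               matrix(0, 4, 4))
  expect_equal(downscale_delta(anom_neg, base_low)$data, matrix(-4, 4, 4))
})

test_that("cells beyond the coarse extent extrapolate from the nearest edge", {
  anom <- grid_raster(matrix(c(0, 2), 1, 2), cellsize = 2)  # extent x [0,4]
  base <- grid_raster(matrix(0, 1, 6), cellsize = 1)        # centers 0.5..5.5
  expect_warning(out <- downscale_delta(anom, base), "nearest-edge")
  expect_equal(as.numeric(out$data)[5:6], c(2, 2))  # clamped to right edge
})

tiny_slices <- function() {
  baseline <- lapply(stats::setNames(BASE_VARS, BASE_VARS), function(v) {
    grid_raster(matrix(c(0, 5), 4, 4), cellsize = 25)
  })
  anom0 <- lapply(stats::setNames(BASE_VARS, BASE_VARS), function(v) {
    grid_raster(matrix(0, 2, 2), cellsize = 50)
  })
  no_ice <- grid_raster(matrix(0, 2, 2), cellsize = 50)
  all_ice <- grid_raster(matrix(1, 2, 2), cellsize = 50)
  timeslice_set(
    list(list(age_ka = 2, anomalies = anom0, ice = no_ice),
         list(age_ka = 1, anomalies = anom0, ice = all_ice)),
    baseline)
}

test_that("slice projection is a pipeline identity without anomalies or ice", {
  grid <- coarse_grid(2, 2, 2, cellsize_km = 50)
  model <- stub_envelope_model(rep(-100, 8), rep(100, 8))
  maps <- project_timeslices(model, tiny_slices(), grid)
  expect_length(maps, 3)  # 2 slices + present
  present <- maps[[3]]
  expect_equal(maps[[1]]$prob, present$prob)
  expect_false(any(maps[[1]]$ice))
  # fully iced slice drops to zero everywhere
  expect_equal(maps[[2]]$prob, rep(0, 4))
  expect_true(all(maps[[2]]$ice))
  expect_equal(present$prob, rep(1, 4))
})

test_that("slice ages must decrease toward the present", {
  s <- tiny_slices()
  expect_error(timeslice_set(rev(s$slices), s$baseline), "strictly decrease")
})

test_that("stability surface ranks sums and flags the top fraction", {
  # 22 identical maps, suitable on half the cells
  half <- rep(c(1, 0), each = 5)
  maps <- replicate(22, suitability_map(half), simplify = FALSE)
  st <- stability_surface(maps)
  expect_equal(sort(unique(st$sum)), c(0, 22))
  expect_equal(sum(st$flag), 3)  # ceil(0.3 * 10)
  expect_true(all(st$sum[st$flag] == 22))

  # hand-set descending sums: flags are exactly the top three
  st2 <- stability_surface(list(suitability_map(seq(0.9, 0, by = -0.1))))
  expect_equal(which(st2$flag), 1:3)
  expect_equal(st2$rank, 1:10)

  expect_error(stability_surface(list()), "empty map list")
})

test_that("exactly 30 of 100 unmasked cells are flagged", {
  set.seed(17)
  maps <- replicate(5, suitability_map(runif(100)), simplify = FALSE)
  st <- stability_surface(maps)
  expect_equal(sum(st$flag), 30)
  # slice order is irrelevant
  st_rev <- stability_surface(rev(maps))
  expect_equal(st_rev$sum, st$sum)
  expect_identical(st_rev$flag, st$flag)
  # an all-zero map changes sums by nothing and flags by nothing
  st_aug <- stability_surface(c(maps, list(suitability_map(rep(0, 100)))))
  expect_identical(st_aug$flag, st$flag)
})

test_that("ties at the cut break by cell index unless retained explicitly", {
  vals <- c(0.9, 0.5, 0.5, 0.5, 0.1, 0.1, 0, 0, 0, 0)
  st <- stability_surface(list(suitability_map(vals)))
  expect_equal(which(st$flag), c(1, 2, 3))  # third 0.5 loses the tie
  st_ties <- stability_surface(list(suitability_map(vals)),
                               include_ties = TRUE)
  expect_equal(which(st_ties$flag), 1:4)
})

test_that("raising a cell's probability never lowers its stability rank", {
  set.seed(23)
  base_prob <- runif(30)
  maps <- list(suitability_map(base_prob), suitability_map(runif(30)))
  st <- stability_surface(maps)
  for (cell in c(1, 15, 30)) {
    bumped <- base_prob
    bumped[cell] <- min(1, bumped[cell] + 0.5)
    st2 <- stability_surface(list(suitability_map(bumped), maps[[2]]))
    expect_lte(st2$rank[cell], st$rank[cell])
  }
})

test_that("masked cells are excluded from the ranked pool", {
  vals <- c(NA, 0.9, 0.8, 0.2, 0.1)
  st <- stability_surface(list(suitability_map(vals)), top_frac = 0.5)
  expect_true(is.na(st$rank[1]))
  expect_false(st$flag[1])
  expect_equal(sum(st$flag), 2)  # ceil(0.5 * 4 unmasked)
})
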