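risk_grid <- function(presence, region, elevation = NULL) {
  n <- length(presence)
  coarse_grid(1, n, 1, cellsize_km = 50, presence = presence,
              region_id = region,
              elevation_m = elevation %||% rep(500, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("threshold derivation follows the fixed and range-edge rules", {
  grid <- risk_grid(c(TRUE, TRUE, FALSE), rep("A", 3),
                    elevation = c(900, 400, 100))
  cur <- suitability_map(c(0.88, 0.51, 0.2))
  expect_equal(derive_threshold(cur, grid, mode = "fixed"), 0.49)
  expect_equal(derive_threshold(cur, grid, mode = "fixed", value = 0.3), 0.3)
  expect_error(derive_threshold(cur, grid, mode = "fixed", value = 1.2),
               "in \\(0, 1\\)")
  # lowest-elevation occupied cell is cell 2 at 400 m
  thr <- derive_threshold(cur, grid, mode = "range-edge")
  expect_equal(as.numeric(thr), 0.51)
  expect_equal(attr(thr, "derived_from"), 2L)
  # single occupied cell returns its own probability
  g1 <- risk_grid(c(FALSE, TRUE, FALSE), rep("A", 3))
  expect_equal(as.numeric(derive_threshold(cur, g1, mode = "range-edge")),
               0.51)
  g0 <- risk_grid(rep(FALSE, 3), rep("A", 3))
  expect_error(derive_threshold(cur, g0, mode = "range-edge"), "no occupied")
})

test_that("cell fates follow occupancy and future suitability", {
  grid <- risk_grid(c(TRUE, TRUE, FALSE, FALSE), rep("A", 4))
  cur <- suitability_map(c(0.8, 0.8, 0.3, 0.3))
  fut <- suitability_map(c(0.8, 0.30, 0.60, 0.1))
  fates <- classify_cells(cur, fut, grid, 0.49)
  expect_equal(as.character(fates$class),
               c("persistence", "extinction", "colonization", "absent"))
  # boundary: probability exactly at the threshold counts as suitable
  fut_edge <- suitability_map(c(0.49, 0.49, 0.49, 0.1))
  fe <- classify_cells(cur, fut_edge, grid, 0.49)
  expect_equal(as.character(fe$class[1]), "persistence")
  expect_error(classify_cells(cur, suitability_map(0.5), grid, 0.49),
               "geometry mismatch")
  # purity: identical inputs give identical fates
  expect_identical(fates, classify_cells(cur, fut, grid, 0.49))
})

test_that("range change counts only losses over occupied cells", {
  grid <- risk_grid(c(rep(TRUE, 4), FALSE), rep("A", 5))
  cur <- suitability_map(rep(0.9, 5))
  fut <- suitability_map(c(0.9, 0.1, 0.1, 0.1, 0.9))
  rc <- range_change(classify_cells(cur, fut, grid, 0.49), grid)
  expect_equal(rc$range_change_pct, -75)
  expect_equal(rc$n_colonizing, 1)
  expect_false(rc$region_lost)

  rc_all <- range_change(
    classify_cells(cur, suitability_map(rep(0.9, 5)), grid, 0.49), grid)
  expect_equal(rc_all$range_change_pct, 0)

  rc_none <- range_change(
    classify_cells(cur, suitability_map(rep(0.1, 5)), grid, 0.49), grid)
  expect_equal(rc_none$range_change_pct, -100)
  expect_true(rc_none$region_lost)
})

test_that("persistence and extinction partition the occupied cells", {
  set.seed(41)
  n <- 40
  grid <- risk_grid(sample(c(TRUE, FALSE), n, replace = TRUE),
                    sample(c("A", "B", "C"), n, replace = TRUE))
  cur <- suitability_map(runif(n))
  fut <- suitability_map(runif(n))
  fates <- classify_cells(cur, fut, grid, 0.5)
  rc <- range_change(fates, grid)
  n_ext <- sum(fates$class == "extinction")
  expect_equal(sum(rc$n_persisting) + n_ext, sum(rc$n_occupied))
})

test_that("region pooling via aliases merges subregions", {
  grid <- risk_grid(rep(TRUE, 4), c("W", "E", "E", "C"))
  cur <- suitability_map(rep(0.9, 4))
  fut <- suitability_map(c(0.9, 0.1, 0.9, 0.9))
  al <- c(W = "Pooled", E = "Pooled", C = "Pooled")
  rc <- range_change(classify_cells(cur, fut, grid, 0.49), grid, aliases = al)
  expect_equal(nrow(rc), 1)
  expect_equal(rc$range_change_pct, -25)
})

test_that("haplotype risk sums unique haplotypes over lost regions", {
  regions <- data.frame(region = c("A", "B", "C"),
                        region_lost = c(TRUE, FALSE, TRUE))
  div <- data.frame(region = c("A", "B", "C"), Hu = c(2, 5, 1))
  hr <- haplotypes_at_risk(regions, div)
  expect_equal(hr$Hr, 3)
  expect_setequal(hr$lost_regions, c("A", "C"))

  none <- haplotypes_at_risk(
    data.frame(region = c("A", "B", "C"), region_lost = FALSE), div)
  expect_equal(none$Hr, 0)

  expect_error(
    haplotypes_at_risk(regions,
                       data.frame(region = c("A", "Englund"), Hu = c(1, 1))),
    "Englund")
})

test_that("at-risk haplotypes are the region-unique ids of lost regions", {
  a <- tiny_aln(c("AAAA", "AAAT", "AATT", "AAAA", "ATTT"),
                c("A", "A", "B", "B", "C"))
  haps <- collapse_haplotypes(a)
  div <- suppressWarnings(diversity_table(haps, a))
  regions <- data.frame(region = c("A", "B", "C"),
                        region_lost = c(TRUE, TRUE, FALSE))
  hr <- haplotypes_at_risk(regions, div[div$region != "All", ], haps)
  # hap 1 (AAAA) is shared A/B; haps 2 (A) and 3 (B) are unique and at risk
  expect_equal(hr$Hr, 2)
  expect_setequal(hr$at_risk_haplotypes, c(2L, 3L))
})

test_that("haplotype risk is monotone in the suitability threshold", {
  grid <- risk_grid(rep(TRUE, 6), c("A", "A", "B", "B", "C", "C"))
  cur <- suitability_map(rep(0.9, 6))
  fut <- suitability_map(c(0.2, 0.3, 0.45, 0.5, 0.7, 0.9))
  div <- data.frame(region = c("A", "B", "C"), Hu = c(1, 2, 4))
  hr_prev <- -1
  for (thr in c(0.1, 0.35, 0.55, 0.8, 0.95)) {
    fates <- classify_cells(cur, fut, grid, thr)
    hr <- haplotypes_at_risk(range_change(fates, grid), div)$Hr
    expect_gte(hr, hr_prev)
    hr_prev <- hr
  }
})

test_that("elevation trend recovers exact and degenerate regressions", {
  elev <- seq(200, 2000, length.out = 10)
  flat <- elevation_trend(rep(-0.2, 10), elev)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)

  # noiseless line: lm warns about the perfect fit, which is the point here
  exact <- suppressWarnings(elevation_trend(0.001 * elev - 0.5, elev))
  expect_equal(exact$r2, 1)
  expect_equal(exact$slope, 0.001)

  set.seed(9)
  dp <- -0.5 + 0.0003 * elev + rnorm(10, sd = 0.05)
  fit <- elevation_trend(dp, elev)
  # closed-form normal equations
  b <- cov(elev, dp) / var(elev)
  expect_equal(fit$slope, b, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(dp) - b * mean(elev), tolerance = 1e-12)
  expect_equal(fit$df, c(1, 8))
  expect_error(elevation_trend(dp, rep(1000, 10)), "constant elevation")
})
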