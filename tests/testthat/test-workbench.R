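small_config <- function(out_dir, ...) {
  rg <- default_regions()
  rg$row <- pmax(1, pmin(10, ceiling(rg$row / 2)))
  rg$col <- pmax(1, pmin(10, ceiling(rg$col / 2)))
  rg$sd_km <- rg$sd_km * 0.7
  base <- list(out_dir = out_dir, seed = 11,
               world = list(coarse_nrow = 10, coarse_ncol = 10, factor = 5,
                            regions = rg),
               scenarios = "high", n_permutations = 49)
  utils::modifyList(base, list(...))
}

test_that("config validation fills defaults and flags bad fields", {
  cfg <- validate_config(small_config(tempfile()))
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$threshold$value, 0.49)
  expect_equal(cfg$auc_gate, 0.85)
  expect_equal(cfg$buffer_km, 250)
  expect_s3_class(cfg$spec, "world_spec")

  expect_error(validate_config(list(seed = 1)), "out_dir")
  expect_error(validate_config(small_config(tempfile(), scenarios = "rcp9")),
               "unknown scenario")
  expect_error(
    validate_config(small_config(tempfile(),
                                 inputs = list(fasta = "/no/such.fasta"))),
    "missing path")
  expect_error(
    validate_config(small_config(tempfile(),
                                 aliases = list(R01 = "Englund"))),
    "Englund")
})

test_that("a YAML config round-trips through serialization", {
  cfg <- list(out_dir = "out", seed = 3,
              threshold = list(mode = "fixed", value = 0.4),
              scenarios = c("low", "high"), pa_ratio = 2)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  back <- yaml::read_yaml(f)
  expect_equal(back, cfg)
  v <- validate_config(f)
  expect_equal(v$threshold$value, 0.4)
  expect_equal(v$pa_ratio, 2)
})

test_that("genetics regions missing from the spatial layer abort the run", {
  dir <- file.path(tempdir(), "wb_bad_region")
  a <- tiny_aln(c("ACGT", "ACGA"), c("Englund", "Englund"))
  fa <- tempfile(fileext = ".fasta"); csv <- tempfile(fileext = ".csv")
  dna <- ape::as.DNAbin(strsplit(a$seq, ""))
  names(dna) <- a$sample_id
  ape::write.FASTA(dna, fa)
  write.csv(data.frame(sample_id = a$sample_id, region_id = a$region_id),
            csv, row.names = FALSE)
  cfg <- small_config(dir, inputs = list(fasta = fa, regions = csv))
  expect_error(suppressWarnings(run_pipeline(cfg)), "Englund")
  unlink(dir, recursive = TRUE)
})

test_that("the full pipeline produces a complete, deterministic bundle", {
  dir1 <- file.path(tempdir(), "wb_run1")
  dir2 <- file.path(tempdir(), "wb_run2")
  b1 <- suppressWarnings(run_pipeline(small_config(dir1)))
  expect_s3_class(b1, "pipeline_bundle")
  expect_equal(b1$diversity$Hn[b1$diversity$region == "All"], 31)
  expect_true(all(file.exists(file.path(dir1,
    c("diversity.csv", "haplotypes.csv", "network.csv", "network.gml",
      "ensemble.json", "current.asc", "stability.asc", "refugia.csv",
      "risk_report_high.csv", "fates.csv", "summary.json",
      "manifest.json")))))
  expect_equal(length(list.files(dir1, pattern = "^suitability_.*asc$")), 22)
  expect_gte(sum(b1$stability$flag), 1)
  tr <- b1$elevation_trend$high
  expect_true(is.finite(tr$slope) && is.finite(tr$r2) && is.finite(tr$p))
  # warming hits low ground hardest: suitability change rises with elevation
  expect_gt(tr$slope, 0)

  b2 <- suppressWarnings(run_pipeline(small_config(dir2)))
  expect_identical(b2$risk$high$Hr, b1$risk$high$Hr)
  expect_identical(b2$risk$high$lost_regions, b1$risk$high$lost_regions)
  s1 <- jsonlite::read_json(file.path(dir1, "summary.json"))
  s2 <- jsonlite::read_json(file.path(dir2, "summary.json"))
  expect_identical(s1, s2)
  unlink(c(dir1, dir2), recursive = TRUE)
})
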