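#' Build or load a pipeline configuration
#'
#' A configuration is a named list (optionally read from a YAML file)
#' driving [run_pipeline()]. Recognized fields:
#'
#' * `out_dir` -- output directory (required).
#' * `seed` -- master seed (default 1).
#' * `world` -- named list of [world_spec()] overrides for the synthetic
#'   world that supplies climate/occupancy (and sequences unless overridden).
#' * `inputs` -- optional named list of file paths (`fasta`, `regions`)
#'   replacing the synthetic sequence panel.
#' * `threshold` -- list `mode` ("fixed" or "range-edge") and `value`
#'   (default fixed 0.49).
#' * `scenarios` -- character vector of scenario names to project
#'   (default all of the spec's `scenario_offsets`).
#' * `auc_gate`, `split_fraction`, `buffer_km`, `pa_ratio` -- SDM knobs.
#' * `aliases` -- named list pooling genetic regions into spatial reporting
#'   regions.
#' * `n_permutations` -- AMOVA permutations (default 999).
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config (class `pipeline_config`) with defaults filled
#'   and the constructed [world_spec()] attached as `$spec`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$out_dir)) stop("config field missing: out_dir")
  config$seed <- as.integer(config$seed %||% 1L)
  defaults <- list(threshold = list(mode = "fixed", value = 0.49),
                   auc_gate = 0.85, split_fraction = 0.70,
                   buffer_km = 250, pa_ratio = 3, n_permutations = 999)
  for (nm in names(defaults)) config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  if (!config$threshold$mode %in% c("fixed", "range-edge")) {
    stop("config field threshold$mode must be fixed or range-edge")
  }
  spec_args <- config$world %||% list()
  if (!"seed" %in% names(spec_args)) spec_args$seed <- config$seed
  config$spec <- do.call(world_spec, spec_args)
  config$scenarios <- config$scenarios %||% names(config$spec$scenario_offsets)
  bad_sc <- setdiff(config$scenarios, names(config$spec$scenario_offsets))
  if (length(bad_sc)) stop("unknown scenario(s): ", paste(bad_sc, collapse = ", "))
  if (!is.null(config$inputs)) {
    for (nm in names(config$inputs)) {
      if (!file.exists(config$inputs[[nm]])) {
        stop("config field inputs$", nm, " points to a missing path: ",
             config$inputs[[nm]])
      }
    }
  }
  registry <- config$spec$regions$region
  for (a in names(config$aliases %||% list())) {
    target <- config$aliases[[a]]
    if (!target %in% registry) {
      stop("config aliases map to region '", target,
           "' absent from spatial layer")
    }
  }
  class(config) <- c("pipeline_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full phylogeography + SDM + risk pipeline
#'
#' Stage order: sequence panel to haplotypes/diversity/AMOVA/network;
#' current-climate ensemble fit and prediction; paleoclimate hindcast with
#' the climate-stability refugium surface; per-scenario future projection,
#' cell-fate classification, range change and haplotype risk. Every stage
#' writes its outputs under `out_dir` and a run manifest records seeds and
#' the config, so a bundle can be reproduced exactly.
#'
#' @param config A list or YAML path accepted by [validate_config()].
#' @return Invisible list of class `pipeline_bundle`: `diversity`, `amova`,
#'   `network`, `model`, `current`, `stability`, `risk` and
#'   `elevation_trend` (per scenario), `threshold`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config$spec

  # genetics
  if (!is.null(config$inputs$fasta)) {
    aln <- read_alignment(config$inputs$fasta, config$inputs$regions)
  } else {
    aln <- make_sequences(spec)$aln
  }
  # genetics regions must exist in the spatial registry (possibly via alias)
  aliases <- unlist(config$aliases %||% list())
  gen_regions <- unique(aln$region_id)
  known <- c(spec$regions$region, names(aliases))
  dangling <- setdiff(gen_regions, known)
  if (length(dangling)) {
    stop("region(s) present in genetics but absent from spatial layer: ",
         paste(dangling, collapse = ", "))
  }

  aln <- crop_and_filter(aln)
  haps <- collapse_haplotypes(aln)
  div <- diversity_table(haps, aln, file.path(config$out_dir, "diversity.csv"))
  amova <- amova_phi(aln, n_permutations = config$n_permutations,
                     seed = config$seed)
  net <- build_network(haps)
  write_haplotype_table(haps, file.path(config$out_dir, "haplotypes.csv"))
  write_network(net, file.path(config$out_dir, "network.csv"),
                file.path(config$out_dir, "network.gml"))

  # current-climate ensemble
  landscape <- make_landscape(spec)
  grid <- make_occupancy(landscape, spec)
  feats <- extract_features(landscape$climate, grid)
  labels <- sample_pseudo_absences(grid, buffer_km = config$buffer_km,
                                   ratio = config$pa_ratio, seed = config$seed)
  model <- fit_committee(feats, labels,
                         inclusion_threshold = config$auc_gate,
                         split_fraction = config$split_fraction,
                         seed = config$seed)
  current <- predict_ensemble(model, feats, tag = "current")
  write_ensemble_json(model, file.path(config$out_dir, "ensemble.json"))
  write_cells_asc(current$prob, grid, file.path(config$out_dir, "current.asc"))

  # hindcast + stability
  slices <- make_timeseries(spec, landscape)
  paleo_maps <- project_timeslices(model, slices, grid)
  for (m in paleo_maps) {
    write_cells_asc(m$prob, grid,
                    file.path(config$out_dir, paste0("suitability_", m$tag,
                                                     ".asc")))
  }
  stab <- stability_surface(paleo_maps)
  write_cells_asc(stab$sum, grid, file.path(config$out_dir, "stability.asc"))
  utils::write.csv(stab, file.path(config$out_dir, "refugia.csv"),
                   row.names = FALSE, quote = FALSE)

  # future scenarios + risk
  thr <- derive_threshold(current, grid, mode = config$threshold$mode,
                          value = config$threshold$value %||% 0.49)
  risks <- list()
  fates_all <- list()
  trends <- list()
  for (sc in config$scenarios) {
    fut_layers <- make_future(spec, landscape, sc)
    fut <- predict_ensemble(model, extract_features(fut_layers, grid),
                            tag = sc)
    rr <- risk_report(current, fut, grid, thr, div, haps,
                      aliases = aliases, scenario = sc)
    risks[[sc]] <- rr
    fates_all[[sc]] <- rr$fates
    trends[[sc]] <- elevation_trend(fut$prob - current$prob,
                                    grid$cells$elevation_m)
    utils::write.csv(
      merge(rr$regions,
            div[div$region != "All", c("region", "Hn", "Hu")],
            by = "region", all.x = TRUE),
      file.path(config$out_dir, paste0("risk_report_", sc, ".csv")),
      row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(do.call(rbind, fates_all),
                   file.path(config$out_dir, "fates.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(Hr = lapply(risks, `[[`, "Hr"),
         lost_regions = lapply(risks, `[[`, "lost_regions"),
         threshold = as.numeric(thr),
         phi = amova$phi, phi_p = amova$p_value,
         elevation_trend = lapply(trends, function(tr) {
           tr[c("slope", "r2", "F", "p")]
         })),
    file.path(config$out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("refugia")),
         r_version = R.version.string,
         seed = config$seed,
         config = config[setdiff(names(config), "spec")]),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE,
    digits = NA, force = TRUE)

  invisible(structure(
    list(diversity = div, amova = amova, network = net, model = model,
         current = current, stability = stab, risk = risks,
         elevation_trend = trends, threshold = thr,
         grid = grid, out_dir = config$out_dir),
    class = "pipeline_bundle"))
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("pipeline_bundle ->", x$out_dir, "\n")
  cat(sprintf("  %d haplotypes, phi = %.3f; threshold %.3g\n",
              nrow(x$network$nodes), x$amova$phi, x$threshold))
  for (sc in names(x$risk)) {
    cat(sprintf("  scenario %-6s Hr = %d (%d region(s) lost)\n", sc,
                x$risk[[sc]]$Hr, length(x$risk[[sc]]$lost_regions)))
  }
  invisible(x)
}
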