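#' Published per-region diversity and projected range change (worked example)
#'
#' The per-region genetic diversity (Hn, Hu, Hd, pi) and projected % range
#' change under the low (RCP 2.6) and high (RCP 8.5) 2070 scenarios for the
#' European mountain ringlet study system, as printed in the source study's
#' regional summary. The three Alps subregions carry the pooled Alps range
#' change. Used as the worked-example input for the haplotype-risk rule.
#'
#' @return data.frame with columns `region, n_region_label, Hn, Hu, Hd, pi,
#'   range_change_low_pct, range_change_high_pct`.
#' @export
published_region_table <- function() {
  utils::read.csv(system.file("extdata", "erebia_epiphron_regions.csv",
                              package = "refugia", mustWork = TRUE),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' Haplotype risk from the published regional table
#'
#' Applies the H_r rule to [published_region_table()]: a region is lost when
#' its printed range change is -100% (all occupied 50-km squares become
#' unsuitable), and H_r sums the unique-haplotype counts of lost regions.
#'
#' @param scenario `"low"` (RCP 2.6) or `"high"` (RCP 8.5).
#' @return List `Hr`, `lost_regions` (see [haplotypes_at_risk()]).
#' @export
published_haplotype_risk <- function(scenario = c("high", "low")) {
  scenario <- match.arg(scenario)
  tab <- published_region_table()
  col <- paste0("range_change_", scenario, "_pct")
  regions <- data.frame(region = tab$region,
                        range_change_pct = tab[[col]])
  haplotypes_at_risk(regions, tab[, c("region", "Hu")])
}
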