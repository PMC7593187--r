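#' Genetic diversity statistics for one region or the whole sample
#'
#' Computes, for the requested scope, the number of haplotypes `Hn`, the
#' number of region-unique haplotypes `Hu` (nonzero count in exactly one
#' region), the sample-size-corrected haplotype diversity
#' \deqn{H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' (the probability that two randomly sampled alleles differ), and the
#' nucleotide diversity \eqn{\pi}: the mean number of per-site nucleotide
#' differences over all unordered pairs of sequences, divided by the retained
#' alignment length.
#'
#' @param table A `haplotype_table` from [collapse_haplotypes()].
#' @param aln The filtered [hap_alignment()] the table was built from.
#' @param scope A region id present in the alignment, or `"All"`.
#' @return A one-row data.frame with columns
#'   `scope, n, Hn, Hu, Hd, pi`. For `n = 1` scopes `Hd` and `pi` are 0 and a
#'   warning is raised.
#' @export
diversity_stats <- function(table, aln, scope = "All") {
  stopifnot(inherits(table, "haplotype_table"), inherits(aln, "hap_alignment"))
  regions <- colnames(table$counts)
  if (scope != "All" && !scope %in% regions) {
    stop("unknown scope: ", scope)
  }
  in_scope <- if (scope == "All") rep(TRUE, length(aln$seq)) else
    aln$region_id == scope
  n <- sum(in_scope)
  # unique = present in exactly one region (for "All": count of such haplotypes)
  n_regions_present <- rowSums(table$counts > 0)
  if (scope == "All") {
    hap_counts <- rowSums(table$counts)
    Hu <- sum(n_regions_present == 1L)
  } else {
    hap_counts <- table$counts[, scope]
    Hu <- sum(n_regions_present == 1L & hap_counts > 0L)
  }
  hap_counts <- hap_counts[hap_counts > 0]
  Hn <- length(hap_counts)
  if (n == 1L) {
    warning("scope '", scope, "' has a single sample; Hd and pi reported as 0")
    return(data.frame(scope = scope, n = n, Hn = Hn, Hu = Hu, Hd = 0, pi = 0))
  }
  p <- hap_counts / n
  Hd <- n * (1 - sum(p^2)) / (n - 1)
  pi <- nucleotide_diversity(aln$seq[in_scope], aln$length)
  data.frame(scope = scope, n = n, Hn = Hn, Hu = Hu, Hd = Hd, pi = pi)
}

# mean pairwise per-site difference; column-wise identity counting so the
# cost is O(n * L) rather than O(n^2 * L)
nucleotide_diversity <- function(seqs, L) {
  n <- length(seqs)
  if (n < 2L) return(0)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  npairs <- n * (n - 1) / 2
  diff_pairs <- 0
  for (j in seq_len(ncol(m))) {
    tab <- tabulate(factor(m[, j], levels = c("A", "C", "G", "T")), 4L)
    diff_pairs <- diff_pairs + npairs - sum(tab * (tab - 1) / 2)
  }
  diff_pairs / (npairs * L)
}

#' Per-region and overall diversity table
#'
#' Convenience wrapper running [diversity_stats()] for every region and the
#' pooled sample, mirroring the layout of a per-region diversity table
#' (`region, n, Hn, Hu, Hd, pi`).
#'
#' @inheritParams diversity_stats
#' @param file Optional path; when given the table is also written as CSV.
#' @return data.frame with one row per region plus an `"All"` row first.
#' @export
diversity_table <- function(table, aln, file = NULL) {
  scopes <- c("All", colnames(table$counts))
  out <- do.call(rbind, lapply(scopes, function(s) diversity_stats(table, aln, s)))
  names(out)[1] <- "region"
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  out
}
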