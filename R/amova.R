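#' Pairwise Hamming distances between sequences
#'
#' Number of differing sites between every pair of equal-length sequences.
#'
#' @param seqs Character vector of equal-length sequences.
#' @return Symmetric integer matrix of distances.
#' @export
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  d <- matrix(0L, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
      }
    }
  }
  d
}

# variance components of a two-level AMOVA from a squared-distance matrix.
# SS_total = sum_{i<j} d2/N; SS_within = per-group sum_{i<j} d2/n_g;
# unbiased n-coefficient n0 = (N - sum n_g^2 / N) / (G - 1).
amova_components <- function(d2, grp) {
  N <- nrow(d2)
  glev <- unique(grp)
  G <- length(glev)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  sizes <- numeric(G)
  for (k in seq_len(G)) {
    idx <- which(grp == glev[k])
    sizes[k] <- length(idx)
    if (length(idx) >= 2) {
      dg <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(dg[upper.tri(dg)]) / length(idx)
    }
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1
  df_within <- N - G
  ms_among <- ss_among / df_among
  ms_within <- if (df_within > 0) ss_within / df_within else 0
  n0 <- (N - sum(sizes^2) / N) / df_among
  var_within <- ms_within
  var_among <- (ms_among - ms_within) / n0
  denom <- var_among + var_within
  phi <- if (denom > 0) var_among / denom else 0
  list(phi = phi, ss_among = ss_among, ss_within = ss_within,
       variance_among = var_among, variance_within = var_within)
}

#' AMOVA phi statistic with a permutation test
#'
#' Two-level analysis of molecular variance on pairwise Hamming distances.
#' phi is the proportion of molecular variance attributable to among-group
#' differences, \eqn{\phi = \sigma^2_a / (\sigma^2_a + \sigma^2_w)}, with
#' variance components from the standard sum-of-squared-distances
#' decomposition and the unbiased n-coefficient for unequal group sizes. The
#' null distribution is built by permuting individuals across groups while
#' holding group sizes fixed; the p-value uses the +1 correction
#' \eqn{p = (\#\{\phi^* \ge \phi\} + 1)/(B + 1)}.
#'
#' @param aln A filtered [hap_alignment()].
#' @param groups Grouping factor/character per record; defaults to the
#'   alignment's `region_id` (one population per mountain region).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `amova_result`: `phi`, `ss_among`, `ss_within`,
#'   `variance_among`, `variance_within`, `p_value`, `n_permutations`.
#' @export
amova_phi <- function(aln, groups = aln$region_id, n_permutations = 999,
                      seed = 1L) {
  stopifnot(inherits(aln, "hap_alignment"))
  grp <- as.character(groups)
  if (length(grp) != length(aln$seq)) stop("groups must match records")
  if (length(unique(grp)) < 2) stop("AMOVA requires at least 2 groups")
  d2 <- hamming_matrix(aln$seq)^2
  obs <- amova_components(d2, grp)
  perm_phi <- numeric(n_permutations)
  if (n_permutations > 0) {
    rng <- local_rng(seed)
    on.exit(rng())
    for (b in seq_len(n_permutations)) {
      perm_phi[b] <- amova_components(d2, sample(grp))$phi
    }
  }
  p <- (sum(perm_phi >= obs$phi) + 1) / (n_permutations + 1)
  structure(c(obs, list(p_value = p, n_permutations = n_permutations)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: phi = %.4f, p = %.4g (%d permutations)\n",
              x$phi, x$p_value, x$n_permutations))
  cat(sprintf("  SS among = %.4f, SS within = %.4f\n", x$ss_among, x$ss_within))
  cat(sprintf("  var among = %.4f, var within = %.4f\n",
              x$variance_among, x$variance_within))
  invisible(x)
}

# seed the RNG locally and return a restore function; keeps package functions
# deterministic without clobbering the caller's RNG state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
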