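# Brute-force oracles, kept independent of the package's own code paths.

# haplotype diversity as the fraction of discordant unordered pairs,
# enumerated explicitly
brute_hd <- function(counts) {
  ids <- rep(seq_along(counts), counts)
  n <- length(ids)
  disc <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) disc <- disc + (ids[i] != ids[j])
  }
  disc / choose(n, 2)
}

# nucleotide diversity by explicit O(n^2) pair enumeration
brute_pi <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  tot <- 0
  for (i in seq_len(n - 1)) {
    a <- strsplit(seqs[i], "")[[1]]
    for (j in (i + 1):n) {
      b <- strsplit(seqs[j], "")[[1]]
      tot <- tot + sum(a != b)
    }
  }
  tot / (choose(n, 2) * L)
}

# AUC by explicit pair counting (concordant + half ties)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# two-level AMOVA variance components written out longhand
brute_phi <- function(d, groups) {
  d2 <- d^2
  N <- nrow(d2)
  glev <- unique(groups)
  ss_tot <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) ss_tot <- ss_tot + d2[i, j]
  ss_tot <- ss_tot / N
  ss_w <- 0
  sizes <- numeric(0)
  for (g in glev) {
    idx <- which(groups == g)
    sizes <- c(sizes, length(idx))
    s <- 0
    if (length(idx) >= 2) {
      for (a in seq_len(length(idx) - 1)) {
        for (b in (a + 1):length(idx)) s <- s + d2[idx[a], idx[b]]
      }
    }
    ss_w <- ss_w + s / length(idx)
  }
  G <- length(glev)
  ms_a <- (ss_tot - ss_w) / (G - 1)
  ms_w <- ss_w / (N - G)
  n0 <- (N - sum(sizes^2) / N) / (G - 1)
  va <- (ms_a - ms_w) / n0
  va / (va + ms_w)
}

# Moran's I evaluated straight from the definition with row-standardized w
brute_moran <- function(x, w) {
  n <- length(x)
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  w <- w / rs
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# random DNA sequences of length L
rand_seqs <- function(n, L, n_states = 4) {
  bases <- c("A", "C", "G", "T")[seq_len(n_states)]
  vapply(seq_len(n),
         function(i) paste(sample(bases, L, replace = TRUE), collapse = ""),
         character(1))
}

# tiny alignment builder with one region per sequence by default
tiny_aln <- function(seqs, regions = rep("A", length(seqs))) {
  hap_alignment(seqs, paste0("s", seq_along(seqs)), regions)
}

# compact synthetic world for pipeline-level tests: 10x10 coarse cells,
# 5x5 fine factor, same 13-region panel on scaled ridge positions
small_world_spec <- function(...) {
  rg <- default_regions()
  rg$row <- pmax(1, pmin(10, ceiling(rg$row / 2)))
  rg$col <- pmax(1, pmin(10, ceiling(rg$col / 2)))
  rg$sd_km <- rg$sd_km * 0.7
  world_spec(coarse_nrow = 10, coarse_ncol = 10, factor = 5,
             regions = rg, ...)
}

# minimal hand-built ensemble holding a single rectilinear envelope member;
# deterministic and instantaneous, for exercising the projection plumbing
stub_envelope_model <- function(lower, upper) {
  fn <- feature_names()
  member <- list(family = "envelope",
                 fit = list(kind = "envelope",
                            lower = stats::setNames(lower, fn),
                            upper = stats::setNames(upper, fn)),
                 holdout_auc = 1, included = TRUE)
  structure(list(members = list(envelope = member),
                 center = stats::setNames(rep(0, 8), fn),
                 scale = stats::setNames(rep(1, 8), fn),
                 inclusion_threshold = 0.85, split_fraction = 0.7,
                 feature_names = fn, seed = 1L),
            class = "ensemble_model")
}
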