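#' Construct an aligned sequence set with regional assignments
#'
#' Bundles an alignment of equal-length DNA sequences with the mountain-region
#' membership of each sample. Sequences are stored uppercase over the alphabet
#' `A,C,G,T,N,-`; downstream haplotype and diversity computations require the
#' alignment to be filtered first (see [crop_and_filter()]).
#'
#' @param sequences Character vector of aligned sequences (equal length),
#'   optionally named by sample id.
#' @param sample_id Character vector of unique sample identifiers. Defaults to
#'   the names of `sequences`.
#' @param region_id Character vector assigning each sample to a named region.
#' @return An object of class `hap_alignment`: a list with elements
#'   `sample_id`, `region_id`, `seq` (character vector) and `length`.
#' @export
hap_alignment <- function(sequences, sample_id = names(sequences), region_id) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("alignment has no records")
  if (is.null(sample_id)) sample_id <- paste0("s", seq_along(sequences))
  sample_id <- as.character(sample_id)
  region_id <- as.character(region_id)
  if (length(sample_id) != length(sequences) ||
      length(region_id) != length(sequences)) {
    stop("sample_id, region_id and sequences must have equal length")
  }
  if (anyDuplicated(sample_id)) stop("sample_ids must be unique")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("sequences have unequal lengths")
  if (lens[1] == 0L) stop("alignment length must be > 0")
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad)) {
    stop("sequence(s) contain characters outside {A,C,G,T,N,-}: ",
         paste(utils::head(sample_id[bad], 3), collapse = ", "))
  }
  structure(
    list(sample_id = sample_id, region_id = region_id,
         seq = unname(sequences), length = lens[1]),
    class = "hap_alignment"
  )
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("hap_alignment:", length(x$seq), "sequences x", x$length, "sites,",
      length(unique(x$region_id)), "regions\n")
  invisible(x)
}

#' @export
length.hap_alignment <- function(x) length(x$seq)

#' Read an aligned FASTA plus a sample-to-region map
#'
#' @param fasta_file Path to an aligned FASTA (wrapped or single-line).
#' @param region_file Path to a CSV with header `sample_id,region_id`.
#' @return A [hap_alignment()].
#' @export
read_alignment <- function(fasta_file, region_file) {
  dna <- ape::read.FASTA(fasta_file)
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  map <- utils::read.csv(region_file, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "region_id") %in% names(map))) {
    stop("region map must have columns sample_id,region_id")
  }
  idx <- match(names(seqs), map$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from region map: ",
         paste(utils::head(names(seqs)[is.na(idx)], 5), collapse = ", "))
  }
  hap_alignment(seqs, names(seqs), map$region_id[idx])
}

# character matrix view of an alignment (rows = samples, cols = sites)
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$seq), byrow = TRUE)
  rownames(m) <- aln$sample_id
  m
}

#' Crop an alignment to unambiguous columns
#'
#' The default policy (`"drop-ambiguous-columns"`, the complete-deletion
#' convention) removes every column in which any record carries a character
#' outside `{A,C,G,T}`, so that haplotype identity is well defined on the
#' retained sites. `"keep-all"` leaves the alignment untouched.
#'
#' @param aln A [hap_alignment()].
#' @param policy `"drop-ambiguous-columns"` (default) or `"keep-all"`.
#' @return A filtered `hap_alignment`; the number of retained sites is in
#'   `$length` and the dropped column indices in `attr(, "dropped")`.
#' @export
crop_and_filter <- function(aln, policy = c("drop-ambiguous-columns", "keep-all")) {
  stopifnot(inherits(aln, "hap_alignment"))
  policy <- match.arg(policy)
  if (policy == "keep-all") {
    attr(aln, "dropped") <- integer(0)
    return(aln)
  }
  m <- aln_matrix(aln)
  keep <- colSums(!(m == "A" | m == "C" | m == "G" | m == "T")) == 0L
  if (!any(keep)) stop("alignment collapsed to zero length")
  m2 <- m[, keep, drop = FALSE]
  out <- hap_alignment(apply(m2, 1, paste, collapse = ""),
                       aln$sample_id, aln$region_id)
  attr(out, "dropped") <- which(!keep)
  out
}

#' Collapse an alignment into haplotypes with per-region counts
#'
#' Records are grouped by exact sequence identity; haplotype ids are assigned
#' in order of first appearance in the alignment.
#'
#' @param aln A filtered [hap_alignment()] (all characters in `{A,C,G,T}`).
#' @return An object of class `haplotype_table`: list with `hap_id`,
#'   `sequence`, `counts` (haplotype x region integer matrix), `total_n` and
#'   `assignment` (per-record hap_id).
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (any(grepl("[^ACGT]", aln$seq))) {
    stop("alignment contains ambiguous characters; run crop_and_filter() first")
  }
  uniq <- unique(aln$seq)
  assignment <- match(aln$seq, uniq)
  regions <- unique(aln$region_id)
  counts <- table(factor(assignment, levels = seq_along(uniq)),
                  factor(aln$region_id, levels = regions))
  counts <- matrix(as.integer(counts), nrow = length(uniq),
                   dimnames = list(hap_id = seq_along(uniq), region = regions))
  structure(
    list(hap_id = seq_along(uniq), sequence = uniq, counts = counts,
         total_n = length(aln$seq), assignment = assignment),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$hap_id), "haplotypes,", x$total_n,
      "sequences,", ncol(x$counts), "regions\n")
  invisible(x)
}

#' Write a haplotype table as a long-format CSV
#'
#' One row per (haplotype, region) with nonzero count; columns
#' `hap_id,sequence,region,count`.
#'
#' @param table A `haplotype_table`.
#' @param file Output CSV path.
#' @export
write_haplotype_table <- function(table, file) {
  idx <- which(table$counts > 0, arr.ind = TRUE)
  df <- data.frame(
    hap_id = table$hap_id[idx[, 1]],
    sequence = table$sequence[idx[, 1]],
    region = colnames(table$counts)[idx[, 2]],
    count = table$counts[idx]
  )
  df <- df[order(df$hap_id, df$region), ]
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(df)
}
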