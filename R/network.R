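#' Minimum-spanning haplotype network
#'
#' Builds a haplotype network on pairwise Hamming distances in the spirit of
#' statistical-parsimony (TCS-style) networks: a minimum spanning tree is
#' grown first, then every non-tree edge is restored whose weight ties the
#' longest edge on the tree path between its endpoints (so alternative
#' equally-parsimonious connections are retained), and finally edges longer
#' than `connection_limit` substitutions are dropped. Each retained edge is
#' annotated with its substitution count.
#'
#' @param table A `haplotype_table` from [collapse_haplotypes()].
#' @param connection_limit Maximum substitutions per retained edge, or
#'   `"none"` (default) for no limit.
#' @return List of class `haplotype_network`: `nodes` (data.frame
#'   `hap_id, frequency`), `edges` (data.frame `hap_a, hap_b, substitutions`).
#' @export
build_network <- function(table, connection_limit = "none") {
  stopifnot(inherits(table, "haplotype_table"))
  if (!identical(connection_limit, "none")) {
    connection_limit <- as.numeric(connection_limit)
    if (is.na(connection_limit) || connection_limit < 1) {
      stop("connection_limit must be >= 1 or \"none\"")
    }
  }
  k <- length(table$hap_id)
  freq <- rowSums(table$counts)
  nodes <- data.frame(hap_id = table$hap_id, frequency = as.integer(freq))
  if (k == 1L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(hap_a = integer(0),
                                             hap_b = integer(0),
                                             substitutions = integer(0))),
                     class = "haplotype_network"))
  }
  d <- hamming_matrix(table$sequence)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  in_tree <- rep(FALSE, igraph::ecount(g))
  ends_all <- igraph::ends(g, igraph::E(g))
  ends_mst <- igraph::ends(mst, igraph::E(mst))
  key_all <- paste(pmin(ends_all[, 1], ends_all[, 2]),
                   pmax(ends_all[, 1], ends_all[, 2]))
  key_mst <- paste(pmin(ends_mst[, 1], ends_mst[, 2]),
                   pmax(ends_mst[, 1], ends_mst[, 2]))
  in_tree <- key_all %in% key_mst
  keep <- in_tree
  # tie retention: a non-tree edge survives if its weight equals the heaviest
  # edge on the unique tree path between its endpoints
  for (e in which(!in_tree)) {
    a <- ends_all[e, 1]; b <- ends_all[e, 2]
    path <- igraph::shortest_paths(mst, from = a, to = b, output = "epath",
                                   weights = NA)$epath[[1]]
    if (length(path) > 0 && d[a, b] == max(igraph::E(mst)$weight[path])) {
      keep[e] <- TRUE
    }
  }
  edges <- data.frame(hap_a = as.integer(pmin(ends_all[, 1], ends_all[, 2])),
                      hap_b = as.integer(pmax(ends_all[, 1], ends_all[, 2])),
                      substitutions = as.integer(igraph::E(g)$weight))[keep, ]
  if (!identical(connection_limit, "none")) {
    edges <- edges[edges$substitutions <= connection_limit, ]
  }
  edges <- edges[order(edges$hap_a, edges$hap_b), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write a haplotype network as an edge-list CSV and GML file
#'
#' @param network A `haplotype_network`.
#' @param csv_file Path for the edge list (`hap_a,hap_b,substitutions`).
#' @param gml_file Optional path for a GML dump (readable by igraph/Gephi).
#' @export
write_network <- function(network, csv_file, gml_file = NULL) {
  utils::write.csv(network$edges, csv_file, row.names = FALSE, quote = FALSE)
  if (!is.null(gml_file)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, gml_file, format = "gml")
  }
  invisible(network)
}
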