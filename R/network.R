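#' Extract the seed-anchored tissue-specific subnetwork
#'
#' Starting from disease seed genes, takes the seeds plus every direct
#' neighbor reached through an edge with confidence at or above the cutoff,
#' then keeps ALL edges with confidence >= cutoff among the selected nodes
#' (the induced subgraph, not just seed-neighbor edges). Seeds with no
#' qualifying neighbor are retained as isolated nodes.
#'
#' @param network A `TissueNetwork` (see [read_network()]).
#' @param seeds Character vector of seed gene ids.
#' @param cutoff Confidence cutoff in \[0, 1\]; comparison is `>=`.
#' @return A `Subnetwork`: list with `nodes`, `edges` (data frame), `seeds`.
#' @export
extract_subnetwork <- function(network, seeds, cutoff = 0.1) {
  stopifnot(inherits(network, "TissueNetwork"), length(seeds) > 0,
            cutoff >= 0, cutoff <= 1)
  seeds <- unique(as.character(seeds))
  net_genes <- unique(c(network$gene_a, network$gene_b))
  if (!any(seeds %in% net_genes)) {
    stop("none of the seed genes are present in the network", call. = FALSE)
  }
  strong <- network[network$confidence >= cutoff, , drop = FALSE]
  touch_seed <- strong$gene_a %in% seeds | strong$gene_b %in% seeds
  neighbors <- setdiff(unique(c(strong$gene_a[touch_seed], strong$gene_b[touch_seed])), seeds)
  nodes <- sort(unique(c(seeds, neighbors)))
  induced <- strong[strong$gene_a %in% nodes & strong$gene_b %in% nodes, , drop = FALSE]
  rownames(induced) <- NULL
  structure(list(nodes = nodes, edges = as.data.frame(induced), seeds = seeds),
            class = "Subnetwork")
}

#' @export
print.Subnetwork <- function(x, ...) {
  cat(sprintf("Subnetwork: %d nodes (%d seeds), %d edges\n",
              length(x$nodes), length(x$seeds), nrow(x$edges)))
  invisible(x)
}

subnetwork_igraph <- function(sub) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(sub$nodes), name = sub$nodes)
  if (nrow(sub$edges) > 0) {
    g <- igraph::add_edges(g, rbind(sub$edges$gene_a, sub$edges$gene_b))
    igraph::E(g)$weight <- sub$edges$confidence
  }
  g
}

#' Topology attributes of a subnetwork
#'
#' Computes the standard descriptive statistics of the extracted subnetwork:
#' node and edge counts, average node degree, average local clustering
#' coefficient (nodes of degree < 2 contribute 0), and average shortest path
#' length and diameter over the largest connected component (unweighted,
#' ordered pairs).
#'
#' @param sub A `Subnetwork`.
#' @return A list with `n_nodes`, `n_edges`, `avg_degree`, `avg_clustering`,
#'   `avg_shortest_path`, `diameter`.
#' @export
topology_stats <- function(sub) {
  stopifnot(inherits(sub, "Subnetwork"))
  if (length(sub$nodes) == 0) stop("empty subnetwork", call. = FALSE)
  g <- subnetwork_igraph(sub)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  list(
    n_nodes = n,
    n_edges = e,
    avg_degree = mean(igraph::degree(g)),
    avg_clustering = mean(cc),
    avg_shortest_path = if (igraph::vcount(giant) > 1) {
      igraph::mean_distance(giant, weights = NA)
    } else 0,
    diameter = if (igraph::vcount(giant) > 1) {
      igraph::diameter(giant, weights = NA)
    } else 0
  )
}

#' Write a subnetwork edge list and its seeds as TSVs
#' @param sub A `Subnetwork`.
#' @param path Output path for the edge TSV (columns gene_a, gene_b,
#'   confidence).
#' @export
write_subnetwork <- function(sub, path) {
  utils::write.table(sub$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sub)
}
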