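#' Build a signed undirected network from an edge table
#'
#' Deduplicates edges (an unordered pair listed twice, in either orientation,
#' keeps its first occurrence), canonicalizes pair order to
#' `gene_a < gene_b`, and collects the node set from edge endpoints
#' (isolated genes are not represented). Self-loops are an error.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` and optionally
#'   `sign` (+1/-1), `pcor`, `pcc`. Missing `sign` defaults to +1.
#' @return A `SignedNetwork`: list with `nodes` (character) and `edges`
#'   (data.frame gene_a, gene_b, sign, pcor, pcc).
#' @export
build_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("gene_a", "gene_b") %in% names(edges)))
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)
  loops <- a == b
  if (any(loops)) stop("self-loop in edge table: ", a[which(loops)[1L]])
  cp <- canonical_pairs(a, b)
  ed <- data.frame(
    gene_a = cp$gene_a, gene_b = cp$gene_b,
    sign = if ("sign" %in% names(edges)) as.integer(edges$sign) else 1L,
    pcor = if ("pcor" %in% names(edges)) edges$pcor else NA_real_,
    pcc = if ("pcc" %in% names(edges)) edges$pcc else NA_real_,
    stringsAsFactors = FALSE)
  ed <- ed[!duplicated(paste(ed$gene_a, ed$gene_b, sep = "\r")), , drop = FALSE]
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(nodes = sort(unique(c(ed$gene_a, ed$gene_b))), edges = ed),
            class = "SignedNetwork")
}

#' @export
print.SignedNetwork <- function(x, ...) {
  cat(sprintf("SignedNetwork: %d genes, %d edges (%d +, %d -)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

# igraph view of a SignedNetwork (signs dropped; topology only)
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = net$nodes)
}

# adjacency list: node -> character vector of neighbors
neighbor_list <- function(net) {
  nb <- c(split(net$edges$gene_b, net$edges$gene_a),
          split(net$edges$gene_a, net$edges$gene_b))
  nb <- tapply(unlist(nb, use.names = FALSE),
               rep(names(nb), lengths(nb)), unique, simplify = FALSE)
  out <- setNames(vector("list", length(net$nodes)), net$nodes)
  out[names(nb)] <- nb
  out
}

#' Global clustering coefficient (transitivity)
#'
#' 3 x (number of triangles) / (number of connected triples), ignoring edge
#' signs; 0 when the network has no connected triple.
#'
#' @param net a `SignedNetwork` with >= 3 nodes.
#' @return Transitivity in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  if (length(net$nodes) < 3L) stop("clustering coefficient needs >= 3 nodes")
  tr <- igraph::transitivity(as_igraph(net), type = "global")
  if (is.nan(tr)) 0 else tr
}

#' Expected clustering coefficient of a same-size random network
#'
#' For an Erdos-Renyi graph with `n_nodes` nodes and `n_edges` edges the
#' expected transitivity equals the edge probability
#' `2 * E / (N * (N - 1))`.
#'
#' @param n_nodes node count (>= 2).
#' @param n_edges edge count; at most `choose(n_nodes, 2)`.
#' @return The Erdos-Renyi edge probability.
#' @export
random_expected_clustering <- function(n_nodes, n_edges) {
  stopifnot(n_nodes >= 2)
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    stop("n_edges exceeds the number of possible pairs")
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Basic network statistics
#'
#' Node and edge counts, global transitivity, and the transitivity expected
#' of an Erdos-Renyi random network of the same size.
#'
#' @param net a `SignedNetwork`.
#' @return list(n_nodes, n_edges, clustering_coefficient, random_expected_c).
#' @export
network_stats <- function(net) {
  n <- length(net$nodes)
  e <- nrow(net$edges)
  list(n_nodes = n, n_edges = e,
       clustering_coefficient = clustering_coefficient(net),
       random_expected_c = random_expected_clustering(n, e))
}

#' Write / read a signed edge list as TSV
#'
#' Columns gene_a, gene_b, sign, pcor, pcc with `gene_a < gene_b`.
#'
#' @param net a `SignedNetwork`.
#' @param path file path.
#' @return `write_network`: `path`, invisibly; `read_network`: a
#'   `SignedNetwork`.
#' @export
write_network <- function(net, path) {
  data.table::fwrite(net$edges, path, sep = "\t")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  build_network(data.table::fread(path, sep = "\t", header = TRUE,
                                  data.table = FALSE))
}
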