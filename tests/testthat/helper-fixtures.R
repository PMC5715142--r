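# Fixture builders and independent oracles used across the suite.

cliqueEdges <- function(ids) {
  pr <- utils::combn(ids, 2L)
  data.frame(node_a = pr[1L, ], node_b = pr[2L, ], stringsAsFactors = FALSE)
}

pathEdges <- function(ids) {
  data.frame(node_a = ids[-length(ids)], node_b = ids[-1L],
             stringsAsFactors = FALSE)
}

# Erdos-Renyi edge table over labelled nodes (deterministic given seed).
randomGraphEdges <- function(n, p, seed, prefix = "v") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  pr <- utils::combn(ids, 2L)
  keep <- withr::with_seed(seed, stats::runif(ncol(pr)) < p)
  data.frame(node_a = pr[1L, keep], node_b = pr[2L, keep],
             stringsAsFactors = FALSE)
}

# Independent MCODE stage-1 weight oracle built on igraph primitives
# (coreness + induced subgraphs); never touches the package's internals.
oracleVertexWeights <- function(edges_df, node_ids = NULL,
                                degree_cutoff = 2L) {
  ids <- sort(unique(c(node_ids, edges_df$node_a, edges_df$node_b)))
  g <- igraph::graph_from_data_frame(
    edges_df[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  w <- vapply(ids, function(v) {
    nb <- names(igraph::neighbors(g, v))
    if (length(nb) < degree_cutoff || length(nb) == 0L) return(0)
    sub <- igraph::induced_subgraph(g, c(v, nb))
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0L) return(0)
    top <- igraph::induced_subgraph(sub, names(core)[core == kmax])
    nn <- igraph::vcount(top)
    if (nn < 2L) return(0)
    kmax * 2 * igraph::ecount(top) / (nn * (nn - 1))
  }, numeric(1))
  stats::setNames(w, ids)
}

# Exact hypergeometric upper tail by direct enumeration over binomial
# coefficients (independent of stats::phyper).
enumUpperTail <- function(k, K, n, N) {
  j <- seq(k, min(K, n))
  if (length(j) == 0L) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Synthetic network with exactly the requested node and edge totals
# (circulant construction: node i linked to i+1, i+2, ... mod n).  Used to
# exercise count arithmetic at published network sizes without any claim of
# realistic topology.
syntheticSizedNetwork <- function(n_nodes, n_edges) {
  stopifnot(n_edges <= choose(n_nodes, 2))
  ids <- sprintf("N%05d", seq_len(n_nodes))
  a <- integer(0); b <- integer(0); d <- 1L
  while (length(a) < n_edges) {
    i <- seq_len(n_nodes - d)
    a <- c(a, i); b <- c(b, i + d)
    d <- d + 1L
  }
  a <- a[seq_len(n_edges)]; b <- b[seq_len(n_edges)]
  netpharm::typedNetwork(ids,
                         data.frame(node_a = ids[a], node_b = ids[b],
                                    stringsAsFactors = FALSE),
                         role = "other_protein")
}

edgeKeysForTest <- function(edges_df) {
  paste(pmin(edges_df$node_a, edges_df$node_b),
        pmax(edges_df$node_a, edges_df$node_b), sep = "|")
}

# Gene universe with block module labels, for enrichment simulations.
labelledUniverse <- function(n_genes, module_size) {
  genes <- sprintf("U%04d", seq_len(n_genes))
  stats::setNames(rep(seq_len(ceiling(n_genes / module_size)),
                      each = module_size)[seq_len(n_genes)], genes)
}
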