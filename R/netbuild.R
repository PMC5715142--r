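# Construction of the four typed networks: disease PPI network, compound ->
# target bipartite network, their merged drug-disease network, and the
# one-hop expansion over the full interactome.

#' Filter PPI edges by confidence
#'
#' Retains exactly the edges whose confidence is strictly greater than
#' `min_confidence` (default 0.4, the conventional medium-confidence cut for
#' STRING-style scores).  Undirected duplicates are collapsed keeping the
#' maximum confidence.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `confidence`.
#' @param min_confidence exclusive lower bound on confidence.
#' @return canonical edge data.frame.
#' @examples
#' filterPPI(data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
#'                      confidence = c(0.39, 0.41)))
#' @export
filterPPI <- function(edges, min_confidence = 0.4) {
  stopifnot(is.data.frame(edges))
  conf <- as.numeric(edges$confidence)
  bad <- which(is.na(conf) | conf < 0 | conf > 1)
  if (length(bad) > 0L) {
    stop("malformed confidence in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (must be a number in [0, 1])", call. = FALSE)
  }
  canonicalEdges(edges[conf > min_confidence, , drop = FALSE])
}

#' Build the disease (gene-gene interaction) network
#'
#' Induced subnetwork of the confidence-filtered PPI on the disease gene
#' set.  Disease genes with no within-set interaction are dropped, so the
#' node count can be smaller than the input gene list; all retained nodes
#' get role `disease_target`.
#'
#' @param disease_genes character vector of disease gene symbols.
#' @param ppi_edges confidence-filtered PPI edge table.
#' @return a [TypedNetwork-class].
#' @export
buildDiseaseNetwork <- function(disease_genes, ppi_edges) {
  disease_genes <- unique(as.character(disease_genes))
  if (length(disease_genes) == 0L) {
    stop("empty disease gene list", call. = FALSE)
  }
  ed <- canonicalEdges(ppi_edges)
  keep <- ed$node_a %in% disease_genes & ed$node_b %in% disease_genes
  ed <- ed[keep, , drop = FALSE]
  ids <- sort(unique(c(ed$node_a, ed$node_b)))
  typedNetwork(ids, ed, role = "disease_target")
}

#' Build the compound-target bipartite network
#'
#' Compounds get role `compound`, genes role `compound_target`; one edge per
#' distinct association pair.  No target-target edges are added here; those
#' enter at merge time from the PPI layer.
#'
#' @param associations data.frame with columns `compound_id`, `gene_id`.
#' @return a [TypedNetwork-class].
#' @export
buildBipartiteNetwork <- function(associations) {
  stopifnot(is.data.frame(associations))
  need <- c("compound_id", "gene_id")
  if (!all(need %in% names(associations))) {
    stop("association table needs columns 'compound_id' and 'gene_id'",
         call. = FALSE)
  }
  compounds <- unique(as.character(associations$compound_id))
  genes <- unique(as.character(associations$gene_id))
  clash <- intersect(compounds, genes)
  if (length(clash) > 0L) {
    stop("identifier collision between compounds and genes: ",
         paste(utils::head(clash, 5L), collapse = ", "), call. = FALSE)
  }
  nodes <- data.frame(
    id = c(compounds, genes),
    role = c(rep("compound", length(compounds)),
             rep("compound_target", length(genes))),
    stringsAsFactors = FALSE)
  ed <- data.frame(node_a = as.character(associations$compound_id),
                   node_b = as.character(associations$gene_id),
                   confidence = rep(NA_real_, nrow(associations)),
                   stringsAsFactors = FALSE)
  typedNetwork(nodes, ed)
}

#' Merge the compound-target and disease networks
#'
#' Node set is the exact union; roles are recomputed so that a node that is
#' both a compound target and a disease gene becomes `shared_target`.  The
#' edge set is the union of both networks' edges plus the confidence-filtered
#' PPI edges among all protein-role nodes of the merged set.  Incremental
#' counts against each component are available via [networkIncrement()].
#'
#' @param drug_net compound-target [TypedNetwork-class].
#' @param disease_net disease [TypedNetwork-class].
#' @param ppi_edges confidence-filtered PPI edge table.
#' @return a [TypedNetwork-class].
#' @export
mergeNetworks <- function(drug_net, disease_net, ppi_edges) {
  stopifnot(is(drug_net, "TypedNetwork"), is(disease_net, "TypedNetwork"))
  droles <- nodeRoles(drug_net)
  compounds <- names(droles)[droles == "compound"]
  drugTargets <- names(droles)[droles != "compound"]
  diseaseGenes <- nodes(disease_net)$id
  shared <- intersect(drugTargets, diseaseGenes)
  allIds <- union(nodes(drug_net)$id, diseaseGenes)
  role <- rep("compound_target", length(allIds))
  names(role) <- allIds
  role[allIds %in% diseaseGenes] <- "disease_target"
  role[allIds %in% shared] <- "shared_target"
  role[allIds %in% compounds] <- "compound"
  proteins <- allIds[role != "compound"]
  ppi <- canonicalEdges(ppi_edges)
  ppi <- ppi[ppi$node_a %in% proteins & ppi$node_b %in% proteins, ,
             drop = FALSE]
  ed <- canonicalEdges(rbind(edges(drug_net), edges(disease_net), ppi))
  typedNetwork(data.frame(id = allIds, role = unname(role),
                          stringsAsFactors = FALSE), ed)
}

#' Expand a network by the first PPI neighborhood of its protein nodes
#'
#' Adds every first neighbor (in the confidence-filtered PPI) of the core
#' network's protein-role nodes, plus all filtered PPI edges among the
#' expanded node set.  Added nodes get role `other_protein`, unless they
#' match a known disease gene, in which case they are labelled
#' `disease_target` (disease genes do turn up among the interactome
#' neighbors of compound targets).
#'
#' @param core_net core [TypedNetwork-class] (e.g. the merged network).
#' @param ppi_edges confidence-filtered PPI edge table.
#' @param disease_genes optional character vector used to relabel added
#'   nodes that are disease genes.
#' @return a [TypedNetwork-class].
#' @export
expandNetwork <- function(core_net, ppi_edges, disease_genes = character()) {
  stopifnot(is(core_net, "TypedNetwork"))
  roles <- nodeRoles(core_net)
  proteins <- names(roles)[roles != "compound"]
  ppi <- canonicalEdges(ppi_edges)
  touch <- ppi$node_a %in% proteins | ppi$node_b %in% proteins
  neighborIds <- unique(c(ppi$node_a[touch], ppi$node_b[touch]))
  newIds <- setdiff(neighborIds, names(roles))
  newRole <- ifelse(newIds %in% disease_genes, "disease_target",
                    "other_protein")
  allIds <- c(names(roles), newIds)
  keep <- ppi$node_a %in% allIds & ppi$node_b %in% allIds
  ed <- canonicalEdges(rbind(edges(core_net), ppi[keep, , drop = FALSE]))
  nodesDf <- data.frame(id = allIds,
                        role = c(unname(roles), newRole),
                        stringsAsFactors = FALSE)
  typedNetwork(nodesDf, ed)
}
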