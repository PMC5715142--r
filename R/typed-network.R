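#' @import methods
NULL

.NODE_ROLES <- c("compound", "compound_target", "disease_target",
                 "shared_target", "other_protein")

#' TypedNetwork: an undirected simple graph with node roles
#'
#' Central network container of the package.  Nodes carry a role label
#' (`compound`, `compound_target`, `disease_target`, `shared_target` or
#' `other_protein`); edges are undirected, stored canonically with
#' `node_a < node_b`, and carry an optional confidence in `[0, 1]`
#' (`NA` for compound-target associations, which have no interaction score).
#'
#' @slot nodes data.frame with columns `id` (character, unique) and `role`.
#' @slot edges data.frame with columns `node_a`, `node_b`, `confidence`.
#'
#' @export
setClass("TypedNetwork",
         slots = c(nodes = "data.frame", edges = "data.frame"))

setValidity("TypedNetwork", function(object) {
  msg <- character()
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("id", "role") %in% names(nd))) {
    return("'nodes' must have columns 'id' and 'role'")
  }
  if (!all(c("node_a", "node_b", "confidence") %in% names(ed))) {
    return("'edges' must have columns 'node_a', 'node_b', 'confidence'")
  }
  if (anyDuplicated(nd$id)) msg <- c(msg, "duplicate node ids")
  bad <- setdiff(unique(nd$role), .NODE_ROLES)
  if (length(bad) > 0L) {
    msg <- c(msg, paste0("unknown role(s): ", paste(bad, collapse = ", ")))
  }
  if (nrow(ed) > 0L) {
    if (any(ed$node_a == ed$node_b)) msg <- c(msg, "self-loop present")
    if (any(ed$node_a > ed$node_b)) {
      msg <- c(msg, "edges not in canonical order (node_a < node_b)")
    }
    if (anyDuplicated(edgeKeys(ed))) msg <- c(msg, "duplicate edges")
    ends <- unique(c(ed$node_a, ed$node_b))
    if (!all(ends %in% nd$id)) {
      msg <- c(msg, "edge endpoint(s) missing from node table")
    }
    conf <- ed$confidence
    if (any(!is.na(conf) & (conf < 0 | conf > 1))) {
      msg <- c(msg, "confidence values outside [0, 1]")
    }
  }
  if (length(msg) > 0L) msg else TRUE
})

#' Construct a TypedNetwork
#'
#' @param nodes data.frame with columns `id` and `role`, or a character
#'   vector of ids combined with a single `role`.
#' @param edges data.frame with columns `node_a`, `node_b` and optionally
#'   `confidence`; canonicalized (undirected, deduplicated keeping maximum
#'   confidence) on construction.
#' @param role default role used when `nodes` is a character vector.
#' @return a validated [TypedNetwork-class] object.
#' @examples
#' net <- typedNetwork(c("TP53", "VEGFA"),
#'                     data.frame(node_a = "TP53", node_b = "VEGFA",
#'                                confidence = 0.9),
#'                     role = "disease_target")
#' numNodes(net)
#' @export
typedNetwork <- function(nodes = character(),
                         edges = data.frame(node_a = character(),
                                            node_b = character(),
                                            confidence = numeric()),
                         role = "other_protein") {
  if (is.character(nodes)) {
    nodes <- data.frame(id = nodes,
                        role = rep(role, length(nodes)),
                        stringsAsFactors = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  nodes$role <- as.character(nodes$role)
  nodes <- nodes[order(nodes$id), c("id", "role"), drop = FALSE]
  rownames(nodes) <- NULL
  edges <- canonicalEdges(edges)
  new("TypedNetwork", nodes = nodes, edges = edges)
}

#' @rdname typedNetwork
#' @param x,object a `TypedNetwork`.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname typedNetwork
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname typedNetwork
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname typedNetwork
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname typedNetwork
#' @export
setGeneric("nodeRoles", function(x) standardGeneric("nodeRoles"))

#' @rdname typedNetwork
#' @export
setMethod("nodes", "TypedNetwork", function(x) x@nodes)

#' @rdname typedNetwork
#' @export
setMethod("edges", "TypedNetwork", function(x) x@edges)

#' @rdname typedNetwork
#' @export
setMethod("numNodes", "TypedNetwork", function(x) nrow(x@nodes))

#' @rdname typedNetwork
#' @export
setMethod("numEdges", "TypedNetwork", function(x) nrow(x@edges))

#' @rdname typedNetwork
#' @export
setMethod("nodeRoles", "TypedNetwork", function(x) {
  stats::setNames(x@nodes$role, x@nodes$id)
})

setMethod("show", "TypedNetwork", function(object) {
  cat("TypedNetwork with", numNodes(object), "nodes and",
      numEdges(object), "edges\n")
  if (numNodes(object) > 0L) {
    tab <- table(factor(object@nodes$role, levels = .NODE_ROLES))
    tab <- tab[tab > 0L]
    cat("  roles:", paste(names(tab), unname(tab), sep = "=", collapse = ", "),
        "\n")
  }
})

#' Convert a TypedNetwork to an igraph object
#'
#' Node roles become the vertex attribute `role`; confidences become the
#' edge attribute `confidence`.
#'
#' @param net a [TypedNetwork-class].
#' @return an undirected [igraph::igraph] graph.
#' @export
asIgraph <- function(net) {
  stopifnot(is(net, "TypedNetwork"))
  igraph::graph_from_data_frame(
    d = net@edges,
    directed = FALSE,
    vertices = data.frame(name = net@nodes$id, role = net@nodes$role,
                          stringsAsFactors = FALSE))
}

#' Summarize a TypedNetwork
#'
#' @param net a [TypedNetwork-class].
#' @return list with total node/edge counts and per-role node counts,
#'   suitable for JSON serialization.
#' @export
networkSummary <- function(net) {
  stopifnot(is(net, "TypedNetwork"))
  tab <- table(factor(net@nodes$role, levels = .NODE_ROLES))
  list(nodes = numNodes(net),
       edges = numEdges(net),
       roles = as.list(stats::setNames(as.integer(tab), names(tab))))
}

#' Incremental node/edge counts of a network over a component network
#'
#' Reports how many nodes and edges a merged or expanded network adds
#' relative to one of its input networks.
#'
#' @param net the larger (merged/expanded) [TypedNetwork-class].
#' @param component one of its input networks.
#' @return named integer vector `c(nodes = ..., edges = ...)`.
#' @export
networkIncrement <- function(net, component) {
  stopifnot(is(net, "TypedNetwork"), is(component, "TypedNetwork"))
  c(nodes = numNodes(net) - numNodes(component),
    edges = numEdges(net) - numEdges(component))
}

# ---- serialization -------------------------------------------------------

#' Read an undirected edge list from TSV
#'
#' Expects a header with columns `node_a`, `node_b` and optionally
#' `confidence`.
#'
#' @param path file path.
#' @return canonical edge data.frame.
#' @export
readEdgeList <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if ("confidence" %in% names(df)) {
    df$confidence <- as.numeric(df$confidence)
  }
  canonicalEdges(df)
}

#' Write an edge table to TSV
#' @param edges canonical edge data.frame.
#' @param path file path.
#' @export
writeEdgeList <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a TypedNetwork in SIF format
#'
#' One line per edge (`node_a  pp  node_b`); isolated nodes, if any, get a
#' bare-node line, per the SIF convention.
#'
#' @param net a [TypedNetwork-class].
#' @param path file path.
#' @param relation interaction type written on edge lines.
#' @export
writeSIF <- function(net, path, relation = "pp") {
  stopifnot(is(net, "TypedNetwork"))
  ed <- net@edges
  lines <- character()
  if (nrow(ed) > 0L) {
    lines <- paste(ed$node_a, relation, ed$node_b, sep = "\t")
  }
  isolated <- setdiff(net@nodes$id, unique(c(ed$node_a, ed$node_b)))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Read a SIF file as an edge table
#'
#' @param path file path.
#' @return canonical edge data.frame (confidence `NA`; SIF carries none).
#' @export
readSIF <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  out <- list()
  for (p in parts) {
    # SIF: source, relation, one or more targets; bare lines are isolated nodes
    if (length(p) >= 3L) {
      out[[length(out) + 1L]] <- data.frame(node_a = p[1L],
                                            node_b = p[3:length(p)],
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(canonicalEdges(data.frame(node_a = character(),
                                     node_b = character())))
  }
  canonicalEdges(do.call(rbind, out))
}

#' Write a TypedNetwork as GraphML
#'
#' Delegates to [igraph::write_graph()]; the vertex attribute `role` and
#' edge attribute `confidence` are preserved.
#'
#' @param net a [TypedNetwork-class].
#' @param path file path.
#' @export
writeGraphML <- function(net, path) {
  g <- asIgraph(net)
  # GraphML cannot carry NA doubles portably; drop the attribute when unset
  conf <- igraph::edge_attr(g, "confidence")
  if (!is.null(conf) && all(is.na(conf))) {
    g <- igraph::delete_edge_attr(g, "confidence")
  } else if (!is.null(conf) && anyNA(conf)) {
    g <- igraph::set_edge_attr(g, "confidence", value = ifelse(is.na(conf), -1, conf))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write node roles as a two-column TSV attribute table
#' @param net a [TypedNetwork-class].
#' @param path file path.
#' @export
writeNodeAttributes <- function(net, path) {
  utils::write.table(nodes(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
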