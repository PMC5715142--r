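# MCODE molecular-complex detection, implemented from scratch:
# stage 1 k-core-based vertex weighting, stage 2 seeded greedy complex
# prediction, stage 3 post-processing (k-core filter, haircut, fluff).
# All tie-breaking is lexicographic by node identifier so results are
# deterministic.

#' MCODE parameters
#'
#' Defaults follow the widely used molecular-complex-detection convention:
#' degree cutoff 2, node score cutoff 0.2, K-core filter 2, maximum search
#' depth 100, haircut on, fluff off.
#'
#' @param degree_cutoff nodes with degree below this are weighted 0.
#' @param node_score_cutoff fraction in `[0, 1]`; a neighbor joins a complex
#'   when its weight is at least `seed_weight * (1 - node_score_cutoff)`.
#' @param k_core_filter complexes lacking a k-core of this order are
#'   discarded.
#' @param max_depth maximum breadth-first search depth from the seed.
#' @param haircut iteratively remove singly-connected complex members
#'   (i.e. keep the complex's 2-core).
#' @param fluff add neighbors whose closed-neighborhood density exceeds
#'   `fluff_density_cutoff` (applied before haircut; fluffed complexes may
#'   overlap).
#' @param fluff_density_cutoff density threshold for fluff.
#' @return a named list of class `McodeParams`.
#' @export
mcodeParams <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                        k_core_filter = 2L, max_depth = 100L,
                        haircut = TRUE, fluff = FALSE,
                        fluff_density_cutoff = 0.1) {
  stopifnot(degree_cutoff >= 0, k_core_filter >= 0, max_depth >= 0,
            node_score_cutoff >= 0, node_score_cutoff <= 1,
            fluff_density_cutoff >= 0, is.logical(haircut), is.logical(fluff))
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core_filter = as.integer(k_core_filter),
                 max_depth = as.integer(max_depth),
                 haircut = haircut, fluff = fluff,
                 fluff_density_cutoff = fluff_density_cutoff),
            class = "McodeParams")
}

# ---- internal graph machinery --------------------------------------------

# Integer adjacency list (sorted neighbor vectors) from a TypedNetwork,
# an edge data.frame, or an igraph object.
.mcodeAdjacency <- function(net) {
  if (is(net, "TypedNetwork")) {
    ids <- nodes(net)$id
    ed <- edges(net)
  } else if (is.data.frame(net)) {
    ed <- canonicalEdges(net)
    ids <- sort(unique(c(ed$node_a, ed$node_b)))
  } else if (inherits(net, "igraph")) {
    ids <- igraph::V(net)$name
    if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(net)))
    em <- igraph::as_edgelist(net, names = TRUE)
    ed <- canonicalEdges(data.frame(node_a = em[, 1L], node_b = em[, 2L],
                                    stringsAsFactors = FALSE))
  } else {
    stop("unsupported graph input", call. = FALSE)
  }
  ids <- sort(as.character(ids))
  n <- length(ids)
  adj <- rep(list(integer(0)), n)
  if (nrow(ed) > 0L) {
    a <- match(ed$node_a, ids)
    b <- match(ed$node_b, ids)
    grp <- split(c(b, a), c(a, b))
    for (nm in names(grp)) {
      adj[[as.integer(nm)]] <- sort(unique(grp[[nm]]))
    }
  }
  list(ids = ids, adj = adj)
}

# Core numbers of every vertex (Batagelj-Zaversnik peeling).
.coreNumbers <- function(adj) {
  n <- length(adj)
  if (n == 0L) return(integer(0))
  deg <- as.integer(lengths(adj))
  md <- max(deg)
  bin <- integer(md + 1L)
  for (v in seq_len(n)) bin[deg[v] + 1L] <- bin[deg[v] + 1L] + 1L
  start <- cumsum(c(1L, bin[-length(bin)]))
  pos <- integer(n); vert <- integer(n)
  nxt <- start
  for (v in seq_len(n)) {
    d <- deg[v] + 1L
    pos[v] <- nxt[d]
    vert[pos[v]] <- v
    nxt[d] <- nxt[d] + 1L
  }
  binStart <- start
  core <- deg
  for (i in seq_len(n)) {
    v <- vert[i]
    for (u in adj[[v]]) {
      if (core[u] > core[v]) {
        du <- core[u]; pu <- pos[u]
        pw <- binStart[du + 1L]; w <- vert[pw]
        if (u != w) {
          vert[pu] <- w; vert[pw] <- u
          pos[u] <- pw; pos[w] <- pu
        }
        binStart[du + 1L] <- binStart[du + 1L] + 1L
        core[u] <- du - 1L
      }
    }
  }
  core
}

# Subgraph adjacency on a set of vertex indices; returns local adjacency
# (indices into `members`) and the edge count.
.subAdjacency <- function(adj, members, n) {
  k <- length(members)
  inSet <- logical(n)
  inSet[members] <- TRUE
  localIdx <- integer(n)
  localIdx[members] <- seq_len(k)
  sub <- vector("list", k)
  m <- 0L
  for (i in seq_len(k)) {
    nb <- adj[[members[i]]]
    nb <- nb[inSet[nb]]
    sub[[i]] <- localIdx[nb]
    m <- m + length(nb)
  }
  list(adj = sub, edges = m %/% 2L)
}

.density <- function(nNodes, nEdges) {
  if (nNodes < 2L) return(0)
  2 * nEdges / (nNodes * (nNodes - 1))
}

# Weight of one vertex: k_max * density of the highest k-core of its closed
# neighborhood.
.vertexWeight <- function(adj, v, n, degree_cutoff) {
  nb <- adj[[v]]
  if (length(nb) < degree_cutoff || length(nb) == 0L) return(0)
  members <- c(v, nb)
  sub <- .subAdjacency(adj, members, n)
  core <- .coreNumbers(sub$adj)
  kmax <- max(core)
  if (kmax == 0L) return(0)
  top <- which(core == kmax)
  # edges within the highest k-core
  inTop <- logical(length(members))
  inTop[top] <- TRUE
  m <- 0L
  for (i in top) m <- m + sum(inTop[sub$adj[[i]]])
  kmax * .density(length(top), m %/% 2L)
}

#' MCODE stage-1 vertex weights
#'
#' The weight of a vertex is `k_max * density` of the highest k-core of its
#' closed neighborhood, where density is `2E / (n (n - 1))`.  Vertices whose
#' degree is below `degree_cutoff` get weight 0.
#'
#' @param net a [TypedNetwork-class], an edge data.frame (`node_a`,
#'   `node_b`) or an igraph object.
#' @param params an [mcodeParams()] list.
#' @return named numeric vector of weights, one per node.
#' @export
vertexWeights <- function(net, params = mcodeParams()) {
  g <- .mcodeAdjacency(net)
  n <- length(g$ids)
  w <- vapply(seq_len(n), function(v) {
    .vertexWeight(g$adj, v, n, params$degree_cutoff)
  }, numeric(1))
  stats::setNames(w, g$ids)
}

# ---- result container ----------------------------------------------------

#' McodeResult: ranked molecular complexes
#'
#' Result of [mcode()].  Clusters are ranked by score (graph density times
#' member count) in decreasing order; score ties are broken
#' lexicographically by seed identifier.
#'
#' @slot members list of character vectors (one per cluster).
#' @slot seeds character vector of seed node identifiers.
#' @slot scores numeric cluster scores.
#' @slot params the `McodeParams` used.
#' @export
setClass("McodeResult",
         slots = c(members = "list", seeds = "character",
                   scores = "numeric", params = "list"))

setValidity("McodeResult", function(object) {
  msg <- character()
  k <- length(object@members)
  if (length(object@seeds) != k || length(object@scores) != k) {
    msg <- c(msg, "members, seeds and scores must have equal length")
  }
  if (any(lengths(object@members) < 2L)) {
    msg <- c(msg, "clusters must have at least 2 members")
  }
  if (any(object@scores <= 0)) msg <- c(msg, "scores must be positive")
  if (length(msg) > 0L) msg else TRUE
})

#' @rdname McodeResult-class
#' @param x,object an `McodeResult`.
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname McodeResult-class
#' @export
setGeneric("clusterScores", function(x) standardGeneric("clusterScores"))

#' @rdname McodeResult-class
#' @export
setGeneric("clusterSeeds", function(x) standardGeneric("clusterSeeds"))

#' @rdname McodeResult-class
#' @export
setMethod("clusterMembers", "McodeResult", function(x) x@members)

#' @rdname McodeResult-class
#' @export
setMethod("clusterScores", "McodeResult", function(x) x@scores)

#' @rdname McodeResult-class
#' @export
setMethod("clusterSeeds", "McodeResult", function(x) x@seeds)

#' @rdname McodeResult-class
#' @export
setMethod("length", "McodeResult", function(x) length(x@members))

setMethod("show", "McodeResult", function(object) {
  cat("McodeResult with", length(object), "cluster(s)\n")
  k <- min(length(object), 5L)
  for (i in seq_len(k)) {
    cat(sprintf("  rank %d: score %.3f, %d nodes, seed %s\n", i,
                object@scores[i], length(object@members[[i]]),
                object@seeds[i]))
  }
  if (length(object) > k) cat("  ...\n")
})

#' Convert an McodeResult to a data.frame
#'
#' @param x an [McodeResult-class].
#' @param ... ignored.
#' @return data.frame with columns rank, score, seed, size, members
#'   (comma-separated).
#' @export
setMethod("as.data.frame", "McodeResult", function(x, ...) {
  data.frame(rank = seq_along(x@members),
             score = x@scores,
             seed = x@seeds,
             size = lengths(x@members),
             members = vapply(x@members, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
})

# ---- the algorithm -------------------------------------------------------

#' Detect molecular complexes with MCODE
#'
#' Stage 1 weights every vertex by the density-scaled order of the highest
#' k-core of its closed neighborhood.  Stage 2 seeds a complex at the
#' highest-weight unassigned vertex and grows it breadth-first, adding
#' neighbors whose weight is at least `seed_weight * (1 - node_score_cutoff)`
#' up to `max_depth`; assigned vertices cannot join a second complex, so
#' clusters are node-disjoint (unless `fluff` is on).  Stage 3 discards
#' complexes lacking a `k_core_filter`-core, optionally fluffs, and
#' optionally haircuts (keeps the 2-core).  Node role labels play no part in
#' clustering; compound nodes may appear in clusters.
#'
#' @inheritParams vertexWeights
#' @return an [McodeResult-class]; empty result (0 clusters) is valid.
#' @examples
#' ed <- data.frame(node_a = c("a", "a", "a", "b", "b", "c"),
#'                  node_b = c("b", "c", "d", "c", "d", "d"))
#' mcode(ed)  # one 4-clique, score 4
#' @export
mcode <- function(net, params = mcodeParams()) {
  g <- .mcodeAdjacency(net)
  n <- length(g$ids)
  if (n == 0L) {
    return(new("McodeResult", members = list(), seeds = character(),
               scores = numeric(), params = unclass(params)))
  }
  w <- vapply(seq_len(n), function(v) {
    .vertexWeight(g$adj, v, n, params$degree_cutoff)
  }, numeric(1))

  # stage 2: seeded greedy growth; ids are pre-sorted so index order is
  # lexicographic order, giving deterministic tie-breaks
  ord <- order(-w, seq_len(n))
  assigned <- logical(n)
  complexes <- list()
  for (s in ord) {
    if (assigned[s]) next
    thresh <- w[s] * (1 - params$node_score_cutoff)
    assigned[s] <- TRUE
    members <- s
    frontier <- s
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in g$adj[[v]]) {
          if (!assigned[u] && w[u] >= thresh) {
            assigned[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- sort(nxt)
      depth <- depth + 1L
    }
    if (length(members) >= 2L) {
      complexes[[length(complexes) + 1L]] <- list(seed = s,
                                                  members = sort(members))
    }
  }

  # stage 3: post-processing
  out <- list()
  for (cx in complexes) {
    members <- cx$members
    sub <- .subAdjacency(g$adj, members, n)
    core <- .coreNumbers(sub$adj)
    if (max(core) < params$k_core_filter) next
    if (params$fluff) {
      inC <- logical(n); inC[members] <- TRUE
      cand <- sort(unique(unlist(lapply(members, function(v) g$adj[[v]]))))
      cand <- cand[!inC[cand]]
      add <- cand[vapply(cand, function(u) {
        nb <- c(u, g$adj[[u]])
        subU <- .subAdjacency(g$adj, nb, n)
        .density(length(nb), subU$edges) > params$fluff_density_cutoff
      }, logical(1))]
      if (length(add) > 0L) {
        members <- sort(c(members, add))
        sub <- .subAdjacency(g$adj, members, n)
        core <- .coreNumbers(sub$adj)
      }
    }
    if (params$haircut) {
      keep <- which(core >= 2L)
      if (length(keep) < length(members)) {
        members <- members[keep]
        if (length(members) < 2L) next
        sub <- .subAdjacency(g$adj, members, n)
      }
    }
    score <- .density(length(members), sub$edges) * length(members)
    if (length(members) < 2L || score <= 0) next
    out[[length(out) + 1L]] <- list(seed = g$ids[cx$seed],
                                    members = g$ids[members],
                                    score = score)
  }
  if (length(out) == 0L) {
    return(new("McodeResult", members = list(), seeds = character(),
               scores = numeric(), params = unclass(params)))
  }
  seeds <- vapply(out, `[[`, character(1), "seed")
  scores <- vapply(out, `[[`, numeric(1), "score")
  o <- order(-scores, seeds)
  new("McodeResult",
      members = lapply(out[o], `[[`, "members"),
      seeds = seeds[o],
      scores = scores[o],
      params = unclass(params))
}

#' Score recovery of planted modules
#'
#' For each planted module, finds the detected cluster with the highest
#' Jaccard index against it and reports the mean of these best matches.
#'
#' @param result an [McodeResult-class].
#' @param truth_labels named vector mapping every node identifier to its
#'   planted module label.
#' @return list with `per_module` (data.frame: module, size, best_jaccard,
#'   best_cluster rank or NA) and `mean_jaccard`.
#' @export
recoverPlanted <- function(result, truth_labels) {
  stopifnot(is(result, "McodeResult"))
  if (is.null(names(truth_labels))) {
    stop("'truth_labels' must be a named vector (node -> module)",
         call. = FALSE)
  }
  modules <- split(names(truth_labels), as.character(truth_labels))
  best <- lapply(names(modules), function(m) {
    genes <- modules[[m]]
    if (length(result) == 0L) {
      return(data.frame(module = m, size = length(genes), best_jaccard = 0,
                        best_cluster = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    j <- vapply(clusterMembers(result), function(cl) {
      length(intersect(cl, genes)) / length(union(cl, genes))
    }, numeric(1))
    data.frame(module = m, size = length(genes), best_jaccard = max(j),
               best_cluster = which.max(j), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, best)
  list(per_module = per, mean_jaccard = mean(per$best_jaccard))
}

#' Write clusters as TSV
#' @param result an [McodeResult-class].
#' @param path file path.
#' @export
writeClusters <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
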