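# Synthetic-data generators: every input the pipeline consumes can be
# produced with known ground truth, so all downstream stages are testable
# without any database download.  Each generator owns one documented
# pseudo-random stream derived from the configuration seed, and restores the
# caller's RNG state.

.GEN_STREAMS <- c(compounds = 101L, ppi = 211L, bipartite = 307L,
                  annotation = 401L, disease = 503L)

#' SimulationConfig: parameters of the synthetic study
#'
#' Holds the conditions under which synthetic inputs are drawn: compound
#' pass rate at the ADME thresholds, planted-partition PPI layer (dense
#' modules with within/between edge probabilities and uniform confidence
#' scores), compound-target bipartite density, annotation catalog with
#' planted enriched terms, and a disease gene set with a controllable
#' expected overlap against compound targets.
#'
#' @slot seed integer master seed.
#' @slot nCompounds number of compounds.
#' @slot passFraction expected fraction of compounds passing the ADME rule.
#' @slot nModules,moduleSize planted PPI modules and their size.
#' @slot pIn,pOut within-/between-module edge probabilities (`pOut < pIn`).
#' @slot confidenceRange uniform range of edge confidence scores.
#' @slot nTerms number of annotation terms.
#' @slot plantedTerms list of `list(term_id =, module =, strength =)`.
#' @slot termDensity baseline probability that a gene joins a term set.
#' @slot bipartiteDensity probability of each compound-gene association.
#' @slot diseaseOverlapFraction expected fraction of disease genes that are
#'   compound targets.
#' @slot nDiseaseGenes disease gene list length.
#' @export
setClass("SimulationConfig",
         slots = c(seed = "integer", nCompounds = "integer",
                   passFraction = "numeric", nModules = "integer",
                   moduleSize = "integer", pIn = "numeric", pOut = "numeric",
                   confidenceRange = "numeric", nTerms = "integer",
                   plantedTerms = "list", termDensity = "numeric",
                   bipartiteDensity = "numeric",
                   diseaseOverlapFraction = "numeric",
                   nDiseaseGenes = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  frac <- c(passFraction = object@passFraction,
            bipartiteDensity = object@bipartiteDensity,
            diseaseOverlapFraction = object@diseaseOverlapFraction,
            termDensity = object@termDensity)
  bad <- names(frac)[frac < 0 | frac > 1]
  if (length(bad) > 0L) {
    msg <- c(msg, paste0("fraction(s) outside [0, 1]: ",
                         paste(bad, collapse = ", ")))
  }
  if (!(object@pOut >= 0 && object@pOut < object@pIn && object@pIn <= 1)) {
    msg <- c(msg, "need 0 <= p_out < p_in <= 1")
  }
  if (length(object@confidenceRange) != 2L ||
      any(object@confidenceRange < 0 | object@confidenceRange > 1) ||
      object@confidenceRange[1L] > object@confidenceRange[2L]) {
    msg <- c(msg, "confidence_range must be an increasing pair in [0, 1]")
  }
  if (object@nCompounds < 1L) msg <- c(msg, "n_compounds must be >= 1")
  if (object@nModules < 1L) msg <- c(msg, "n_modules must be >= 1")
  if (object@moduleSize < 3L) msg <- c(msg, "module_size must be >= 3")
  if (object@nTerms < 1L) msg <- c(msg, "n_terms must be >= 1")
  for (pt in object@plantedTerms) {
    if (!all(c("term_id", "module", "strength") %in% names(pt))) {
      msg <- c(msg, "planted terms need fields term_id, module, strength")
    } else if (pt$module < 1 || pt$module > object@nModules) {
      msg <- c(msg, paste0("planted term '", pt$term_id,
                           "' references unknown module ", pt$module))
    }
  }
  if (length(msg) > 0L) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults mirror the scale of a published two-herb formula / hypertensive
#' disorder analysis: 77 active compounds, a compound-target layer dense
#' enough to yield a ~17k-edge bipartite network (density 0.52 over 432
#' targets), a 131-gene disease set, and a planted-module PPI layer.
#'
#' @param seed master seed (integer below 2^31).
#' @param n_compounds,pass_fraction compound table size and expected ADME
#'   pass rate.
#' @param n_modules,module_size,p_in,p_out planted-partition PPI layer.
#' @param confidence_range uniform confidence score range.
#' @param n_terms,planted_terms,term_density annotation catalog.
#' @param bipartite_density compound-target association probability.
#' @param disease_overlap_fraction,n_disease_genes disease gene list.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed,
                             n_compounds = 77L,
                             pass_fraction = 1.0,
                             n_modules = 30L,
                             module_size = 20L,
                             p_in = 0.9,
                             p_out = 0.01,
                             confidence_range = c(0.2, 1.0),
                             n_terms = 100L,
                             planted_terms = list(),
                             term_density = 0.02,
                             bipartite_density = 0.52,
                             disease_overlap_fraction = 0.5,
                             n_disease_genes = 131L) {
  new("SimulationConfig",
      seed = as.integer(seed), nCompounds = as.integer(n_compounds),
      passFraction = pass_fraction, nModules = as.integer(n_modules),
      moduleSize = as.integer(module_size), pIn = p_in, pOut = p_out,
      confidenceRange = as.numeric(confidence_range),
      nTerms = as.integer(n_terms), plantedTerms = planted_terms,
      termDensity = term_density, bipartiteDensity = bipartite_density,
      diseaseOverlapFraction = disease_overlap_fraction,
      nDiseaseGenes = as.integer(n_disease_genes))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed", object@seed, "\n")
  cat(sprintf("  %d compounds (pass fraction %.2f)\n", object@nCompounds,
              object@passFraction))
  cat(sprintf("  PPI: %d modules x %d nodes, p_in %.2f, p_out %.3f\n",
              object@nModules, object@moduleSize, object@pIn, object@pOut))
  cat(sprintf("  %d terms (%d planted), bipartite density %.2f, %d disease genes (overlap %.2f)\n",
              object@nTerms, length(object@plantedTerms),
              object@bipartiteDensity, object@nDiseaseGenes,
              object@diseaseOverlapFraction))
})

#' Generate a compound property table with a known pass rate
#'
#' Each compound passes the ADME rule (OB >= 30, Caco-2 > -0.4, DL >= 0.18)
#' independently with probability `pass_fraction`.  Passing compounds draw
#' all three properties from the passing side of each threshold; failing
#' compounds fail exactly one property, chosen uniformly, and pass the other
#' two.  The ground-truth labels are emitted as a `true_pass` column.
#'
#' @param cfg a [SimulationConfig-class].
#' @return data.frame with columns `compound_id`, `name`, `herb`, `ob`,
#'   `caco2`, `dl`, `true_pass`.
#' @export
genCompoundTable <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  n <- cfg@nCompounds
  withSeed(cfg@seed + .GEN_STREAMS[["compounds"]], {
    pass <- stats::runif(n) < cfg@passFraction
    ob <- stats::runif(n, 30, 100)
    caco2 <- stats::runif(n, -0.3, 1.5)
    dl <- stats::runif(n, 0.18, 1)
    failDim <- sample.int(3L, n, replace = TRUE)
    ob[!pass & failDim == 1L] <- stats::runif(sum(!pass & failDim == 1L), 0, 29.9)
    caco2[!pass & failDim == 2L] <- stats::runif(sum(!pass & failDim == 2L), -2, -0.4)
    dl[!pass & failDim == 3L] <- stats::runif(sum(!pass & failDim == 3L), 0, 0.17)
    data.frame(
      compound_id = sprintf("C%04d", seq_len(n)),
      name = sprintf("compound-%04d", seq_len(n)),
      herb = rep_len(c("herbA", "herbB"), n),
      ob = ob, caco2 = caco2, dl = dl,
      true_pass = pass,
      stringsAsFactors = FALSE)
  })
}

#' Generate a PPI layer with planted dense modules
#'
#' Planted-partition model over `n_modules * module_size` synthetic gene
#' symbols (`G0001`, ...): within-module pairs are linked with probability
#' `p_in`, between-module pairs with `p_out`; every edge receives a
#' confidence drawn uniformly from `confidence_range`.  The graph is simple
#' by construction.
#'
#' @param cfg a [SimulationConfig-class].
#' @return list with `edges` (canonical edge data.frame), `labels` (named
#'   integer vector node -> module) and `genes` (all node ids).
#' @export
genPlantedPPI <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  n <- cfg@nModules * cfg@moduleSize
  genes <- sprintf("G%04d", seq_len(n))
  labels <- stats::setNames(rep(seq_len(cfg@nModules),
                                each = cfg@moduleSize), genes)
  pairs <- utils::combn(n, 2L)
  sameModule <- labels[pairs[1L, ]] == labels[pairs[2L, ]]
  prob <- ifelse(sameModule, cfg@pIn, cfg@pOut)
  withSeed(cfg@seed + .GEN_STREAMS[["ppi"]], {
    keep <- stats::runif(ncol(pairs)) < prob
    conf <- stats::runif(sum(keep), cfg@confidenceRange[1L],
                         cfg@confidenceRange[2L])
    edges <- data.frame(node_a = genes[pairs[1L, keep]],
                        node_b = genes[pairs[2L, keep]],
                        confidence = conf, stringsAsFactors = FALSE)
    list(edges = canonicalEdges(edges), labels = labels, genes = genes)
  })
}

#' Generate compound-target associations
#'
#' Every (compound, gene) pair is linked independently with probability
#' `bipartite_density`; there are no duplicate rows.
#'
#' @param compounds character vector of compound ids.
#' @param genes character vector of candidate target gene ids.
#' @param cfg a [SimulationConfig-class].
#' @return data.frame with columns `compound_id`, `gene_id`.
#' @export
genBipartiteTargets <- function(compounds, genes, cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  compounds <- unique(as.character(compounds))
  genes <- unique(as.character(genes))
  if (length(compounds) == 0L || length(genes) == 0L) {
    stop("compound and gene sets must be non-empty", call. = FALSE)
  }
  withSeed(cfg@seed + .GEN_STREAMS[["bipartite"]], {
    grid <- expand.grid(compound_id = compounds, gene_id = genes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < cfg@bipartiteDensity
    out <- grid[keep, , drop = FALSE]
    out <- out[order(out$compound_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate an annotation catalog with planted enriched terms
#'
#' Background terms include each gene independently with probability
#' `term_density`.  A planted term targeting module `m` with strength `s`
#' includes module genes with probability `min(1, s * term_density)` and
#' non-module genes with probability `term_density / s`; as `s` grows the
#' term set converges to exactly its module's gene set.  Empty term sets are
#' re-drawn deterministically by including one universe gene.
#'
#' @param genes gene universe (character).
#' @param cfg a [SimulationConfig-class]; planted term `module` values are
#'   interpreted against `module_labels`.
#' @param module_labels named vector (gene -> module) from [genPlantedPPI()];
#'   required when planted terms are configured.
#' @return list with `catalog` (an [AnnotationCatalog-class]) and
#'   `planted` (character vector of planted term ids).
#' @export
genAnnotation <- function(genes, cfg, module_labels = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  genes <- unique(as.character(genes))
  planted <- cfg@plantedTerms
  if (length(planted) > 0L && is.null(module_labels)) {
    stop("planted terms configured but no 'module_labels' supplied",
         call. = FALSE)
  }
  for (pt in planted) {
    if (!is.null(module_labels) &&
        !any(module_labels == pt$module & names(module_labels) %in% genes)) {
      stop("planted term '", pt$term_id, "' references unknown module ",
           pt$module, call. = FALSE)
    }
  }
  q0 <- cfg@termDensity
  withSeed(cfg@seed + .GEN_STREAMS[["annotation"]], {
    plantedIds <- vapply(planted, function(p) as.character(p$term_id),
                         character(1))
    ids <- sprintf("T%04d", seq_len(cfg@nTerms))
    ids[seq_along(plantedIds)] <- plantedIds
    sets <- vector("list", cfg@nTerms)
    names(sets) <- ids
    for (i in seq_len(cfg@nTerms)) {
      if (i <= length(planted)) {
        pt <- planted[[i]]
        s <- pt$strength
        inModule <- genes %in% names(module_labels)[module_labels == pt$module]
        if (is.infinite(s)) {
          sets[[i]] <- genes[inModule]
          next
        }
        prob <- ifelse(inModule, min(1, s * q0), q0 / s)
      } else {
        prob <- rep(q0, length(genes))
      }
      pick <- stats::runif(length(genes)) < prob
      if (!any(pick)) pick[1L] <- TRUE   # no empty term sets
      sets[[i]] <- genes[pick]
    }
    list(catalog = annotationCatalog(sets, universe = genes),
         planted = plantedIds)
  })
}

#' Generate a disease gene list with controllable target overlap
#'
#' Draws `n_disease_genes` distinct genes so that the expected fraction
#' shared with `compound_targets` equals `disease_overlap_fraction` (the
#' realized count is binomial).  Ground truth shared-target labels are
#' returned alongside.
#'
#' @param genes gene universe (character).
#' @param compound_targets character vector of compound target genes.
#' @param cfg a [SimulationConfig-class].
#' @return list with `genes` (the disease list) and `shared` (the subset
#'   that are compound targets).
#' @export
genDiseaseGenes <- function(genes, compound_targets, cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  genes <- unique(as.character(genes))
  n <- cfg@nDiseaseGenes
  if (n > length(genes)) {
    stop("requested disease list longer than the gene universe",
         call. = FALSE)
  }
  inTargets <- intersect(genes, as.character(compound_targets))
  outTargets <- setdiff(genes, inTargets)
  withSeed(cfg@seed + .GEN_STREAMS[["disease"]], {
    k <- stats::rbinom(1L, n, cfg@diseaseOverlapFraction)
    k <- min(k, length(inTargets))
    k <- max(k, n - length(outTargets))
    shared <- sort(sample(inTargets, k))
    rest <- sort(sample(outTargets, n - k))
    list(genes = sort(c(shared, rest)), shared = shared)
  })
}

#' Write generator ground truth as JSON
#'
#' @param truth named list (e.g. module labels, true pass labels, planted
#'   term ids, shared disease targets).
#' @param path file path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Write a gene list, one symbol per line
#' @param genes character vector.
#' @param path file path.
#' @export
writeGeneList <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#' @param path file path.
#' @return character vector.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
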