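# Orchestration: simulate/ingest -> ADME filter -> network construction ->
# MCODE clustering -> enrichment -> drug-disease overlap, behind one YAML
# configuration.  Stages communicate through files on disk so each stage is
# independently inspectable, and the manifest records a checksum for every
# artifact.

.CONFIG_KEYS <- c("seed", "simulate", "inputs", "min_confidence",
                  "thresholds", "mcode", "enrichment", "etiology_mapping",
                  "outdir")
.SIM_KEYS <- c("n_compounds", "pass_fraction", "n_modules", "module_size",
               "p_in", "p_out", "confidence_range", "n_terms",
               "planted_terms", "term_density", "bipartite_density",
               "disease_overlap_fraction", "n_disease_genes", "n_targets")
.INPUT_KEYS <- c("compounds", "ppi_edges", "associations", "disease_genes",
                 "annotations")

#' Validate a pipeline configuration
#'
#' Checks the whole configuration and reports every problem found, not just
#' the first: unknown keys, missing mandatory fields (a seed is mandatory
#' whenever a simulation block is present), out-of-range fractions, and
#' missing input files.
#'
#' @param config path to a YAML file, or an already-parsed list.
#' @param stop_on_error if `TRUE` (default) signal one error listing every
#'   problem; if `FALSE` return the character vector of problems (empty when
#'   valid).
#' @return the normalized configuration list (invisibly) when valid;
#'   otherwise see `stop_on_error`.
#' @export
validateConfig <- function(config, stop_on_error = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("configuration must be a YAML file path or a list", call. = FALSE)
  }
  errs <- character()
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown) > 0L) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  hasSim <- !is.null(config$simulate)
  hasInputs <- !is.null(config$inputs) && length(config$inputs) > 0L
  if (!hasSim && !hasInputs) {
    errs <- c(errs, "either a 'simulate' block or an 'inputs' block is required")
  }
  if (hasSim && is.null(config$seed)) {
    errs <- c(errs, "'seed' is mandatory when a simulate block is present")
  }
  if (hasSim) {
    unknownSim <- setdiff(names(config$simulate), .SIM_KEYS)
    if (length(unknownSim) > 0L) {
      errs <- c(errs, paste0("unknown simulate key(s): ",
                             paste(unknownSim, collapse = ", ")))
    }
    sim <- config$simulate
    for (f in c("pass_fraction", "bipartite_density",
                "disease_overlap_fraction", "term_density")) {
      v <- sim[[f]]
      if (!is.null(v) && (v < 0 || v > 1)) {
        errs <- c(errs, paste0("simulate$", f, " outside [0, 1]"))
      }
    }
    if (!is.null(sim$p_in) && !is.null(sim$p_out) && sim$p_out >= sim$p_in) {
      errs <- c(errs, "simulate$p_out must be < simulate$p_in")
    }
  }
  if (hasInputs) {
    unknownIn <- setdiff(names(config$inputs), .INPUT_KEYS)
    if (length(unknownIn) > 0L) {
      errs <- c(errs, paste0("unknown inputs key(s): ",
                             paste(unknownIn, collapse = ", ")))
    }
    for (f in names(config$inputs)) {
      p <- config$inputs[[f]]
      if (!is.null(p) && !file.exists(p)) {
        errs <- c(errs, paste0("inputs$", f, " does not exist: ", p))
      }
    }
  }
  mc <- config$min_confidence
  if (!is.null(mc) && (mc < 0 || mc > 1)) {
    errs <- c(errs, "'min_confidence' outside [0, 1]")
  }
  if (!is.null(config$etiology_mapping) &&
      !file.exists(config$etiology_mapping)) {
    errs <- c(errs, paste0("etiology_mapping file does not exist: ",
                           config$etiology_mapping))
  }
  if (length(errs) > 0L) {
    if (stop_on_error) {
      stop("invalid configuration:\n  - ",
           paste(errs, collapse = "\n  - "), call. = FALSE)
    }
    return(errs)
  }
  if (!stop_on_error) return(character())
  # normalized echo with defaults filled in
  config$min_confidence <- config$min_confidence %||% 0.4
  config$outdir <- config$outdir %||% "netpharm_out"
  config$thresholds <- config$thresholds %||% list()
  config$mcode <- config$mcode %||% list()
  config$enrichment <- config$enrichment %||% list()
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.writeNetworkFiles <- function(net, name, outdir, extra = list()) {
  writeSIF(net, file.path(outdir, paste0(name, ".sif")))
  writeNodeAttributes(net, file.path(outdir, paste0(name, "_nodes.tsv")))
  summ <- c(networkSummary(net), extra)
  jsonlite::write_json(summ, file.path(outdir, paste0(name, "_summary.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full network-pharmacology pipeline
#'
#' Executes, in order: input simulation (or ingestion), ADME filtering,
#' construction of the four typed networks (disease, compound-target,
#' merged, expanded), MCODE clustering of the disease, merged and expanded
#' networks, per-cluster GO over-representation, and the drug-disease
#' biological-process overlap partitioned by etiology.  All artifacts are
#' written under `outdir` and recorded with MD5 checksums in
#' `manifest.json`; re-running with an identical configuration reproduces
#' byte-identical primary outputs.
#'
#' @param config path to a YAML configuration or a list (see
#'   [validateConfig()]).
#' @return (invisibly) the manifest as a list, which also carries the main
#'   in-memory results (`networks`, `clusters`, `enrichment`, `overlap`).
#' @export
runPipeline <- function(config) {
  config <- validateConfig(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[netpharm] ", ...)

  # ---- stage: simulate or ingest ----------------------------------------
  sim <- NULL
  truth <- list()
  if (!is.null(config$simulate)) {
    simArgs <- config$simulate
    nTargets <- simArgs$n_targets %||% 432L
    simArgs$n_targets <- NULL
    planted <- simArgs$planted_terms %||% list()
    simArgs$planted_terms <- NULL
    cfg <- .stage("simulate", do.call(simulationConfig,
                                      c(list(seed = config$seed,
                                             planted_terms = planted),
                                        simArgs)))
    sim <- .stage("simulate", {
      compounds <- genCompoundTable(cfg)
      ppi <- genPlantedPPI(cfg)
      targetPool <- ppi$genes[seq_len(min(nTargets, length(ppi$genes)))]
      ann <- genAnnotation(ppi$genes, cfg, module_labels = ppi$labels)
      list(cfg = cfg, compounds = compounds, ppi = ppi,
           targetPool = targetPool, ann = ann)
    })
    writeCompoundTable(sim$compounds, file.path(outdir, "compounds.tsv"))
    writeEdgeList(sim$ppi$edges, file.path(outdir, "ppi_edges.tsv"))
    writeGMT(sim$ann$catalog, file.path(outdir, "annotations.gmt"))
    truth <- list(module_labels = as.list(sim$ppi$labels),
                  true_pass = as.list(stats::setNames(sim$compounds$true_pass,
                                                      sim$compounds$compound_id)),
                  planted_terms = sim$ann$planted)
    compounds <- sim$compounds
    ppiEdges <- sim$ppi$edges
    catalog <- sim$ann$catalog
    log("simulate: ", nrow(compounds), " compounds, ",
        nrow(ppiEdges), " PPI edges, ",
        length(catalog@terms), " annotation terms")
  } else {
    inp <- config$inputs
    compounds <- .stage("ingest", readCompoundTable(inp$compounds))
    ppiEdges <- .stage("ingest", readEdgeList(inp$ppi_edges))
    catalog <- .stage("ingest", readGMT(inp$annotations))
    log("ingest: ", nrow(compounds), " compounds, ", nrow(ppiEdges),
        " PPI edges")
  }

  # ---- stage: ADME filter -------------------------------------------------
  thr <- do.call(filterThresholds, config$thresholds)
  filt <- .stage("filter", applyAdmeFilter(compounds, thr))
  if (nrow(filt$retained) == 0L) {
    stop("pipeline stage 'filter' failed: no compounds retained",
         call. = FALSE)
  }
  writeCompoundTable(filt$retained, file.path(outdir, "compounds_retained.tsv"))
  writeCompoundTable(filt$excluded, file.path(outdir, "compounds_excluded.tsv"))
  log("filter: ", nrow(filt$retained), " retained / ",
      nrow(compounds), " input compounds")

  # ---- stage: associations & disease genes --------------------------------
  if (!is.null(sim)) {
    assoc <- .stage("simulate",
                    genBipartiteTargets(filt$retained$compound_id,
                                        sim$targetPool, sim$cfg))
    disease <- .stage("simulate",
                      genDiseaseGenes(sim$ppi$genes,
                                      unique(assoc$gene_id), sim$cfg))
    diseaseGenes <- disease$genes
    truth$shared_targets <- disease$shared
    utils::write.table(assoc, file.path(outdir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeGeneList(diseaseGenes, file.path(outdir, "disease_genes.txt"))
    writeGroundTruth(truth, file.path(outdir, "ground_truth.json"))
  } else {
    assoc <- .stage("ingest",
                    utils::read.delim(config$inputs$associations,
                                      stringsAsFactors = FALSE,
                                      colClasses = "character"))
    assoc <- assoc[assoc$compound_id %in% filt$retained$compound_id, ,
                   drop = FALSE]
    diseaseGenes <- .stage("ingest",
                           readGeneList(config$inputs$disease_genes))
  }

  # ---- stage: network construction ---------------------------------------
  nets <- .stage("build", {
    ppiFilt <- filterPPI(ppiEdges, config$min_confidence)
    netDisease <- buildDiseaseNetwork(diseaseGenes, ppiFilt)
    netDrug <- buildBipartiteNetwork(assoc)
    netMerged <- mergeNetworks(netDrug, netDisease, ppiFilt)
    netExpanded <- expandNetwork(netMerged, ppiFilt, diseaseGenes)
    list(ppi_filtered = ppiFilt, disease = netDisease, drug = netDrug,
         merged = netMerged, expanded = netExpanded)
  })
  writeEdgeList(nets$ppi_filtered, file.path(outdir, "ppi_filtered.tsv"))
  .writeNetworkFiles(nets$disease, "net_disease", outdir)
  .writeNetworkFiles(nets$drug, "net_drug", outdir)
  .writeNetworkFiles(
    nets$merged, "net_merged", outdir,
    extra = list(increment_vs_drug =
                   as.list(networkIncrement(nets$merged, nets$drug)),
                 increment_vs_disease =
                   as.list(networkIncrement(nets$merged, nets$disease))))
  .writeNetworkFiles(
    nets$expanded, "net_expanded", outdir,
    extra = list(increment_vs_merged =
                   as.list(networkIncrement(nets$expanded, nets$merged))))
  for (nm in c("disease", "drug", "merged", "expanded")) {
    log("build: ", nm, " network ", numNodes(nets[[nm]]), " nodes / ",
        numEdges(nets[[nm]]), " edges")
  }

  # ---- stage: clustering --------------------------------------------------
  params <- do.call(mcodeParams, config$mcode)
  clusters <- .stage("cluster", {
    lapply(list(disease = nets$disease, merged = nets$merged,
                expanded = nets$expanded), mcode, params = params)
  })
  for (nm in names(clusters)) {
    writeClusters(clusters[[nm]],
                  file.path(outdir, paste0("clusters_", nm, ".tsv")))
    log("cluster: ", nm, " network -> ", length(clusters[[nm]]),
        " clusters")
  }

  # ---- stage: enrichment --------------------------------------------------
  method <- config$enrichment$method %||% "hypergeom"
  alpha <- config$enrichment$alpha %||% 0.05
  compoundIds <- unique(as.character(assoc$compound_id))
  enrTables <- .stage("enrich", {
    lapply(names(clusters), function(nm) {
      res <- clusters[[nm]]
      tabs <- list()
      for (i in seq_along(res)) {
        genesIn <- setdiff(clusterMembers(res)[[i]], compoundIds)
        genesIn <- intersect(genesIn, catalog@universe)
        if (length(genesIn) == 0L) next
        tab <- enrich(genesIn, catalog, method = method, alpha = alpha)
        fn <- file.path(outdir, sprintf("enrichment_%s_cluster%02d.tsv",
                                        nm, i))
        writeEnrichment(tab, fn)
        tabs[[length(tabs) + 1L]] <- tab
      }
      tabs
    })
  })
  names(enrTables) <- names(clusters)
  for (nm in names(enrTables)) {
    log("enrich: ", nm, " network -> ",
        length(collectSignificant(enrTables[[nm]])), " significant terms")
  }

  # ---- stage: overlap -----------------------------------------------------
  mapping <- if (is.null(config$etiology_mapping)) {
    pihEtiologyMapping()
  } else {
    readEtiologyMapping(config$etiology_mapping)
  }
  report <- .stage("overlap", {
    drugTerms <- collectSignificant(c(enrTables$merged, enrTables$expanded))
    diseaseTerms <- collectSignificant(enrTables$disease)
    overlapReport(drugTerms, diseaseTerms, mapping)
  })
  writeOverlapReport(report,
                     json_path = file.path(outdir, "overlap_report.json"),
                     tsv_path = file.path(outdir, "overlap_report.tsv"))
  log("overlap: ", length(report@overlap), " shared terms")

  # ---- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  checks <- tools::md5sum(file.path(outdir, files))
  manifest <- list(
    package = "netpharm",
    version = as.character(utils::packageVersion("netpharm")),
    seed = config$seed,
    parameters = list(min_confidence = config$min_confidence,
                      thresholds = unclass(thr),
                      mcode = unclass(params),
                      enrichment = list(method = method, alpha = alpha)),
    artifacts = as.list(stats::setNames(unname(checks), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$networks <- nets
  manifest$clusters <- clusters
  manifest$enrichment <- enrTables
  manifest$overlap <- report
  if (!is.null(sim)) manifest$truth <- truth
  invisible(manifest)
}
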