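# Drug-disease overlap of significant biological-process terms, partitioned
# by disease-etiology category.

#' EtiologyMapping: disease-etiology categories of annotation terms
#'
#' Named categories, each holding a set of term identifiers.  A term may
#' belong to at most one category; duplicates are rejected at validation
#' because partition counts must conserve cardinality.
#'
#' @slot categories named list of character vectors (category -> term ids).
#' @export
setClass("EtiologyMapping", slots = c(categories = "list"))

setValidity("EtiologyMapping", function(object) {
  msg <- character()
  cats <- object@categories
  if (is.null(names(cats)) || anyDuplicated(names(cats)) ||
      any(!nzchar(names(cats)))) {
    msg <- c(msg, "category names must be unique and non-empty")
  }
  all_terms <- unlist(cats, use.names = FALSE)
  dup <- unique(all_terms[duplicated(all_terms)])
  if (length(dup) > 0L) {
    msg <- c(msg, paste0("term(s) in more than one category: ",
                         paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (length(msg) > 0L) msg else TRUE
})

#' Construct an EtiologyMapping
#'
#' @param categories named list of character term-id vectors.
#' @return an [EtiologyMapping-class].
#' @export
etiologyMapping <- function(categories) {
  categories <- lapply(categories, function(x) sort(unique(as.character(x))))
  new("EtiologyMapping", categories = categories)
}

setMethod("show", "EtiologyMapping", function(object) {
  cat("EtiologyMapping with", length(object@categories), "categories:\n")
  for (nm in names(object@categories)) {
    cat("  ", nm, ": ", length(object@categories[[nm]]), " terms\n",
        sep = "")
  }
})

#' Read an etiology mapping from JSON or YAML
#'
#' The file maps category names to lists of term identifiers.
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return an [EtiologyMapping-class].
#' @export
readEtiologyMapping <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("unsupported mapping format: .", ext, call. = FALSE))
  etiologyMapping(lapply(lst, as.character))
}

#' Packaged etiology mapping for pregnancy-induced hypertension
#'
#' The default mapping assigns GO biological-process identifiers to the four
#' PIH etiology modules: endothelial cell activation and injury, placental
#' or trophoblast cell ischemia, hypoxia and oxidative stress, and
#' maternal-fetal immune tolerance disorders.  The assignment is editorial
#' domain knowledge shipped as a versioned data file
#' (`extdata/pih_etiology_go_terms.json`), editable by users.
#'
#' @return an [EtiologyMapping-class].
#' @export
pihEtiologyMapping <- function() {
  path <- system.file("extdata", "pih_etiology_go_terms.json",
                      package = "netpharm", mustWork = TRUE)
  readEtiologyMapping(path)
}

#' Collect significant terms across enrichment tables
#'
#' Union of `term_id`s flagged significant across all clusters of one side
#' (drug or disease) of the analysis.
#'
#' @param enrichment_tables a single data.frame from [enrich()] or a list of
#'   them.
#' @return sorted character vector of term ids.
#' @export
collectSignificant <- function(enrichment_tables) {
  if (is.data.frame(enrichment_tables)) {
    enrichment_tables <- list(enrichment_tables)
  }
  terms <- unlist(lapply(enrichment_tables, function(tab) {
    if (nrow(tab) == 0L) return(character())
    tab$term_id[tab$significant]
  }))
  sort(unique(terms))
}

#' Intersect drug-side and disease-side term sets
#'
#' @param drug_terms,disease_terms character vectors of term ids.
#' @return sorted character vector: the exact set intersection.
#' @export
overlapTerms <- function(drug_terms, disease_terms) {
  sort(intersect(unique(as.character(drug_terms)),
                 unique(as.character(disease_terms))))
}

#' Partition a term set by etiology category
#'
#' Each term is assigned to its (unique) category or reported as unassigned;
#' counts conserve cardinality: `sum(counts) + length(unassigned)` equals
#' the number of input terms.
#'
#' @param terms character vector of term ids.
#' @param mapping an [EtiologyMapping-class].
#' @return list with `counts` (named integer per category), `assigned`
#'   (named list of term vectors) and `unassigned` (character vector).
#' @export
partitionByEtiology <- function(terms, mapping) {
  stopifnot(is(mapping, "EtiologyMapping"))
  terms <- sort(unique(as.character(terms)))
  assigned <- lapply(mapping@categories, function(cat) intersect(terms, cat))
  unassigned <- setdiff(terms, unlist(assigned))
  list(counts = vapply(assigned, length, integer(1)),
       assigned = assigned,
       unassigned = unassigned)
}

#' OverlapReport: drug-disease biological-process overlap
#'
#' @slot drugTerms,diseaseTerms,overlap,unassigned character vectors of
#'   term identifiers.
#' @slot perCategory named integer vector of overlap counts per etiology
#'   category.
#' @slot assigned named list of overlap terms per category.
#' @export
setClass("OverlapReport",
         slots = c(drugTerms = "character", diseaseTerms = "character",
                   overlap = "character", perCategory = "integer",
                   assigned = "list", unassigned = "character"))

setValidity("OverlapReport", function(object) {
  msg <- character()
  if (!setequal(object@overlap,
                intersect(object@drugTerms, object@diseaseTerms))) {
    msg <- c(msg, "overlap must equal the drug/disease intersection")
  }
  if (sum(object@perCategory) + length(object@unassigned) !=
      length(object@overlap)) {
    msg <- c(msg, "category counts plus unassigned must sum to |overlap|")
  }
  if (length(msg) > 0L) msg else TRUE
})

#' Build an overlap report
#'
#' @param drug_terms significant terms on the drug side.
#' @param disease_terms significant terms on the disease side.
#' @param mapping an [EtiologyMapping-class]; defaults to the packaged PIH
#'   mapping.
#' @return an [OverlapReport-class].
#' @export
overlapReport <- function(drug_terms, disease_terms,
                          mapping = pihEtiologyMapping()) {
  ov <- overlapTerms(drug_terms, disease_terms)
  part <- partitionByEtiology(ov, mapping)
  new("OverlapReport",
      drugTerms = sort(unique(as.character(drug_terms))),
      diseaseTerms = sort(unique(as.character(disease_terms))),
      overlap = ov,
      perCategory = part$counts,
      assigned = part$assigned,
      unassigned = part$unassigned)
}

setMethod("show", "OverlapReport", function(object) {
  cat("OverlapReport:", length(object@drugTerms), "drug terms,",
      length(object@diseaseTerms), "disease terms,",
      length(object@overlap), "overlapping\n")
  for (nm in names(object@perCategory)) {
    cat(sprintf("  %s: %d\n", nm, object@perCategory[[nm]]))
  }
  cat("  unassigned:", length(object@unassigned), "\n")
})

#' Write an overlap report (JSON and TSV)
#'
#' @param report an [OverlapReport-class].
#' @param json_path path for the JSON report; `NULL` to skip.
#' @param tsv_path path for a human-readable term/category TSV; `NULL` to
#'   skip.
#' @export
writeOverlapReport <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(is(report, "OverlapReport"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(drug_terms = report@drugTerms,
           disease_terms = report@diseaseTerms,
           overlap = report@overlap,
           per_category_counts = as.list(report@perCategory),
           assigned = report@assigned,
           unassigned = report@unassigned),
      json_path, auto_unbox = FALSE, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    cat_of <- rep(names(report@assigned), lengths(report@assigned))
    df <- data.frame(term_id = c(unlist(report@assigned, use.names = FALSE),
                                 report@unassigned),
                     category = c(cat_of,
                                  rep("unassigned",
                                      length(report@unassigned))),
                     stringsAsFactors = FALSE)
    df <- df[order(df$category, df$term_id), , drop = FALSE]
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
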