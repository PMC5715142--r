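# Over-representation analysis of gene sets against an annotation catalog,
# with Bonferroni family-wise error control.  Replaces a web-service ORA
# with an in-package exact hypergeometric test (plain and EASE variants).

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` is the overlap between a random `n`-subset of an
#' `N`-gene universe and a fixed `K`-gene term set.  Evaluated with
#' [stats::phyper()].
#'
#' @param k observed overlap count.
#' @param K term (annotation) set size.
#' @param n query set size (restricted to the universe).
#' @param N universe size.
#' @return probability; vectorized over `k`, `K`, `n`.
#' @examples
#' hypergeomUpper(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeomUpper <- function(k, K, n, N) {
  if (any(N < 1) || any(K > N) || any(n > N) || any(k < 0) ||
      any(K < 0) || any(n < 0) || any(k > pmin(K, n))) {
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) ",
         "and K, n <= N", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score
#'
#' Conservative ORA variant: the hypergeometric upper tail computed with the
#' overlap count reduced by one, i.e. `P(X >= k - 1)`.  Always at least as
#' large as the plain score.
#'
#' @inheritParams hypergeomUpper
#' @return probability.
#' @export
easeScore <- function(k, K, n, N) {
  if (any(k < 1)) {
    stop("EASE score requires k >= 1", call. = FALSE)
  }
  hypergeomUpper(k - 1, K, n, N)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` where `m` is the number of tests in the family.  `m` is a
#' parameter (rather than `length(p)`) because the family may include terms
#' not present in `p` (e.g. all catalog terms vs only terms with non-zero
#' overlap).
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param m number of tests; must be at least `length(p_values)`.
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p_values, m) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p_values)) {
    stop("'m' must be at least the number of p-values supplied",
         call. = FALSE)
  }
  pmin(1, p_values * m)
}

# ---- annotation catalog --------------------------------------------------

#' AnnotationCatalog: gene-set annotations over a gene universe
#'
#' A single-namespace catalog (e.g. GO biological process): a named list of
#' term gene sets, human-readable term names, and the universe of annotated
#' genes that serves as the default test background.
#'
#' @slot terms named list of character vectors (term_id -> gene set).
#' @slot termNames named character vector (term_id -> description).
#' @slot universe character vector of all annotated genes.
#' @export
setClass("AnnotationCatalog",
         slots = c(terms = "list", termNames = "character",
                   universe = "character"))

setValidity("AnnotationCatalog", function(object) {
  msg <- character()
  if (length(object@terms) == 0L) msg <- c(msg, "catalog has no terms")
  if (is.null(names(object@terms)) || anyDuplicated(names(object@terms))) {
    msg <- c(msg, "terms must have unique names")
  }
  if (any(lengths(object@terms) == 0L)) msg <- c(msg, "empty term set(s)")
  if (!all(unlist(object@terms) %in% object@universe)) {
    msg <- c(msg, "term gene(s) outside the universe")
  }
  if (!identical(sort(names(object@termNames)), sort(names(object@terms)))) {
    msg <- c(msg, "termNames must cover exactly the term ids")
  }
  if (length(msg) > 0L) msg else TRUE
})

#' Construct an AnnotationCatalog
#'
#' @param terms named list of character gene vectors.
#' @param universe gene universe; defaults to the union of all term sets.
#' @param term_names optional named character vector of descriptions.
#' @return an [AnnotationCatalog-class].
#' @export
annotationCatalog <- function(terms, universe = NULL, term_names = NULL) {
  terms <- lapply(terms, function(g) sort(unique(as.character(g))))
  if (is.null(universe)) universe <- sort(unique(unlist(terms)))
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(terms), names(terms))
  }
  new("AnnotationCatalog", terms = terms,
      termNames = term_names[names(terms)],
      universe = sort(unique(as.character(universe))))
}

setMethod("show", "AnnotationCatalog", function(object) {
  cat("AnnotationCatalog:", length(object@terms), "terms over",
      length(object@universe), "genes\n")
})

#' Read a GMT gene-set file
#'
#' Tab-separated: term id, description, then member genes.
#'
#' @param path file path.
#' @param universe optional explicit universe; defaults to the union of all
#'   term sets.
#' @return an [AnnotationCatalog-class].
#' @export
readGMT <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  annotationCatalog(sets, universe = universe,
                    term_names = stats::setNames(desc, ids))
}

#' Write an AnnotationCatalog as GMT
#' @param catalog an [AnnotationCatalog-class].
#' @param path file path.
#' @export
writeGMT <- function(catalog, path) {
  stopifnot(is(catalog, "AnnotationCatalog"))
  lines <- vapply(names(catalog@terms), function(id) {
    paste(c(id, catalog@termNames[[id]], catalog@terms[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- the test ------------------------------------------------------------

#' Over-representation analysis of a query gene set
#'
#' Tests every catalog term with non-zero overlap against the query using
#' the upper-tail hypergeometric test (or its conservative EASE variant),
#' then applies a Bonferroni correction.  The default background is the
#' catalog universe (all annotated genes) and the default Bonferroni
#' multiplier is the number of terms actually tested for this query
#' (overlap k >= 1); both are conventional ORA choices and configurable.
#' A term is significant when its Bonferroni-adjusted p-value is below
#' `alpha`.
#'
#' @param query_genes character vector of query gene identifiers.
#' @param catalog an [AnnotationCatalog-class].
#' @param method `"hypergeom"` (default) or `"ease"`.
#' @param alpha family-wise significance level (default 0.05).
#' @param multiplier `"tested"` (terms with k >= 1, default) or `"all"`
#'   (every catalog term).
#' @return data.frame with one row per term with k >= 1, columns `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p_raw`, `p_bonferroni`,
#'   `significant`, sorted by `p_bonferroni` then `term_id`.
#' @export
enrich <- function(query_genes, catalog, method = c("hypergeom", "ease"),
                   alpha = 0.05, multiplier = c("tested", "all")) {
  stopifnot(is(catalog, "AnnotationCatalog"))
  method <- match.arg(method)
  multiplier <- match.arg(multiplier)
  q <- intersect(unique(as.character(query_genes)), catalog@universe)
  if (length(q) == 0L) {
    stop("query is disjoint from the annotation universe", call. = FALSE)
  }
  n <- length(q)
  N <- length(catalog@universe)
  k <- vapply(catalog@terms, function(g) length(intersect(g, q)), integer(1))
  K <- lengths(catalog@terms)
  keep <- k >= 1L
  if (!any(keep)) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(),
                      p_bonferroni = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  k <- k[keep]; K <- K[keep]
  ids <- names(catalog@terms)[keep]
  p <- switch(method,
              hypergeom = hypergeomUpper(k, K, n, N),
              ease = easeScore(k, K, n, N))
  m <- if (multiplier == "tested") sum(keep) else length(catalog@terms)
  pb <- bonferroniAdjust(p, m)
  out <- data.frame(term_id = ids,
                    term_name = unname(catalog@termNames[ids]),
                    k = as.integer(k), K = as.integer(K),
                    n = n, N = N,
                    p_raw = p, p_bonferroni = pb,
                    significant = pb < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_bonferroni, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#' @param result data.frame from [enrich()].
#' @param path file path.
#' @export
writeEnrichment <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
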