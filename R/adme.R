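# ADME triage: Tanimoto drug-likeness scoring and the three-threshold
# inclusion rule (oral bioavailability, Caco-2 permeability, drug-likeness).

#' Tanimoto drug-likeness score
#'
#' Continuous Tanimoto coefficient between a compound's molecular-descriptor
#' vector `x` and a reference vector `y` representing the average molecular
#' properties of known drugs:
#'
#' \deqn{f(x, y) = \frac{x \cdot y}{|x|^2 + |y|^2 - x \cdot y}}
#'
#' For non-negative inputs the score lies in `[0, 1]` and equals 1 iff
#' `x == y` (up to both being nonzero).  The descriptor is treated as an
#' opaque fixed-dimension vector; which molecular parameters compose it is
#' the caller's choice.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return a single numeric score.
#' @examples
#' dlScore(c(1, 2), c(2, 1))  # 4/6
#' @export
dlScore <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(x) != length(y)) {
    stop("descriptor vectors must be non-empty and of equal dimension",
         call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("descriptor vectors contain NA", call. = FALSE)
  if (any(x < 0) || any(y < 0)) {
    stop("descriptor components must be non-negative; the score is only ",
         "bounded in [0, 1] for non-negative inputs", call. = FALSE)
  }
  xy <- sum(x * y)
  denom <- sum(x^2) + sum(y^2) - xy
  if (denom == 0) {
    stop("undefined score: both descriptor vectors are zero", call. = FALSE)
  }
  xy / denom
}

#' ADME filter thresholds
#'
#' Defaults encode the standard inclusion rule for orally active herbal
#' compounds: oral bioavailability at least 30 percent (inclusive), Caco-2
#' permeability strictly greater than -0.4, drug-likeness at least 0.18
#' (inclusive).
#'
#' @param ob_min minimum oral bioavailability in percent (inclusive).
#' @param caco2_min Caco-2 permeability lower bound (exclusive).
#' @param dl_min minimum drug-likeness (inclusive).
#' @return a named list of class `FilterThresholds`.
#' @export
filterThresholds <- function(ob_min = 30, caco2_min = -0.4, dl_min = 0.18) {
  stopifnot(is.numeric(ob_min), is.numeric(caco2_min), is.numeric(dl_min))
  structure(list(ob_min = ob_min, caco2_min = caco2_min, dl_min = dl_min),
            class = "FilterThresholds")
}

#' Apply the ADME inclusion rule to a compound table
#'
#' A compound is retained iff `ob >= ob_min` AND `caco2 > caco2_min` AND
#' `dl >= dl_min`.  Note the boundary semantics: the oral-bioavailability
#' and drug-likeness bounds are inclusive, the Caco-2 bound is strict.  If
#' the table has no `dl` column but `descriptor` columns (`d1`, `d2`, ...)
#' and a `reference` vector is supplied, drug-likeness is computed with
#' [dlScore()] first.
#'
#' @param compounds data.frame with columns `compound_id`, `name`, `herb`,
#'   `ob`, `caco2`, `dl` (or descriptor columns, see above).
#' @param thresholds a [filterThresholds()] object.
#' @param reference optional reference descriptor vector for computing `dl`.
#' @return list with elements `retained` (subset of the input table) and
#'   `excluded` (excluded rows plus a `failed` column naming the first
#'   failing criterion, checked in order ob, caco2, dl).
#' @export
applyAdmeFilter <- function(compounds, thresholds = filterThresholds(),
                            reference = NULL) {
  stopifnot(is.data.frame(compounds))
  if (!inherits(thresholds, "FilterThresholds")) {
    stop("'thresholds' must come from filterThresholds()", call. = FALSE)
  }
  if (!"dl" %in% names(compounds) && !is.null(reference)) {
    dcols <- grep("^d[0-9]+$", names(compounds), value = TRUE)
    if (length(dcols) == 0L) {
      stop("no 'dl' column and no descriptor columns to compute it from",
           call. = FALSE)
    }
    compounds$dl <- apply(compounds[, dcols, drop = FALSE], 1L,
                          dlScore, y = reference)
  }
  need <- c("compound_id", "ob", "caco2", "dl")
  miss <- setdiff(need, names(compounds))
  if (length(miss) > 0L) {
    stop("compound table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("ob", "caco2", "dl")) {
    v <- compounds[[col]]
    if (anyNA(v) || !is.numeric(v)) {
      bad <- compounds$compound_id[is.na(v)]
      stop("missing or non-numeric '", col, "' for compound(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  failOB <- compounds$ob < thresholds$ob_min
  failCaco <- compounds$caco2 <= thresholds$caco2_min
  failDL <- compounds$dl < thresholds$dl_min
  pass <- !(failOB | failCaco | failDL)
  failed <- rep(NA_character_, nrow(compounds))
  failed[failDL] <- "dl"
  failed[failCaco] <- "caco2"
  failed[failOB] <- "ob"   # first failing criterion in order ob, caco2, dl
  excluded <- compounds[!pass, , drop = FALSE]
  excluded$failed <- failed[!pass]
  rownames(excluded) <- NULL
  retained <- compounds[pass, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Read/write compound property tables
#'
#' Tab-separated with header `compound_id`, `name`, `herb`, `ob`, `caco2`,
#' `dl` (extra columns preserved).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readCompoundTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(c("ob", "caco2", "dl"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' @rdname readCompoundTable
#' @param compounds data.frame to write.
#' @export
writeCompoundTable <- function(compounds, path) {
  utils::write.table(compounds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
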