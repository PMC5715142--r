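# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators do not disturb the
#' caller's random stream.  Each generator in the synthetic-data module owns
#' one documented stream derived from the configuration seed.
#'
#' @param seed integer seed (must be < 2^31).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      abs(seed) >= 2^31) {
    stop("'seed' must be a single integer below 2^31", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Canonicalize an undirected edge table: node_a < node_b lexicographically,
# no self-loops, duplicate pairs collapsed keeping the maximum confidence.
canonicalEdges <- function(edges) {
  if (!is.data.frame(edges)) stop("'edges' must be a data.frame", call. = FALSE)
  need <- c("node_a", "node_b")
  miss <- setdiff(need, names(edges))
  if (length(miss) > 0L) {
    stop("edge table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  conf <- if ("confidence" %in% names(edges)) {
    as.numeric(edges$confidence)
  } else {
    rep(NA_real_, length(a))
  }
  if (length(a) == 0L) {
    return(data.frame(node_a = character(), node_b = character(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  }
  loops <- a == b
  if (any(loops)) {
    stop("self-loop(s) in edge table, e.g. node '", a[which(loops)[1L]], "'",
         call. = FALSE)
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  # keep the highest confidence per undirected pair; NA sorts last
  rank <- ifelse(is.na(conf), -Inf, conf)
  o <- order(key, -rank)
  keep <- o[!duplicated(key[o])]
  keep <- keep[order(a[keep], b[keep])]
  data.frame(node_a = a[keep], node_b = b[keep], confidence = conf[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Edge key helper for set operations on canonical edge tables.
edgeKeys <- function(edges) paste(edges$node_a, edges$node_b, sep = "\r")
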