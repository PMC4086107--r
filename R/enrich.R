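# Function Explorer: hypergeometric over-representation analysis of a node
# selection against GMT gene-set collections.

#' Load a gene-set collection from a GMT file
#'
#' Standard GMT: one tab-delimited line per term -- term ID, description,
#' then member genes. Members are deduplicated within a term. The testing
#' universe defaults to the union of all term members; when an interactome
#' is supplied it is intersected with the interactome's proteins (the genes
#' actually eligible to appear in a network), or set to all interactome
#' proteins with `universe = "db"`.
#'
#' @param path Path to the GMT file.
#' @param db Optional `interaction_db` used to restrict the universe.
#' @param universe `"collection"` (union of members, intersected with the
#'   interactome when given) or `"db"` (all interactome proteins; requires
#'   `db`).
#' @return A `gene_set_collection`: list with `sets` (named list of member
#'   vectors), `descriptions` and `universe`.
#' @export
load_gmt <- function(path, db = NULL, universe = c("collection", "db")) {
  universe <- match.arg(universe)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  if (length(keep) == 0L) stop("empty GMT file: '", path, "'", call. = FALSE)
  sets <- list(); desc <- character(0)
  for (i in keep) {
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1L]])
    f <- f[nzchar(f) | seq_along(f) <= 2L]
    if (length(f) < 3L) {
      stop(sprintf("line %d: GMT lines need term, description and >=1 member", i),
           call. = FALSE)
    }
    sets[[f[1L]]] <- unique(f[-(1:2)])
    desc[f[1L]] <- f[2L]
  }
  univ <- sort(unique(unlist(sets, use.names = FALSE)))
  if (universe == "db") {
    if (is.null(db)) stop("universe = \"db\" requires an interaction_db", call. = FALSE)
    univ <- db$proteins
  } else if (!is.null(db)) {
    univ <- intersect(univ, db$proteins)
  }
  structure(list(sets = sets, descriptions = desc, universe = univ),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `collection`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(term) {
    paste(c(term, collection$descriptions[[term]], collection$sets[[term]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(collection)
}

#' Hypergeometric over-representation analysis
#'
#' For each term, with universe size `N`, term size `K` (within the
#' universe), effective selection size `n = |selection ∩ universe|` and
#' overlap `k`, the enrichment p-value is the upper hypergeometric tail
#' `P(X >= k)`; terms with no overlap get p = 1. Benjamini-Hochberg
#' adjustment is applied across all tested terms.
#'
#' @param selection Character vector of node/gene IDs.
#' @param collection A `gene_set_collection`.
#' @return An `enrichment_result` data frame, sorted by p-value: `term`,
#'   `description`, `k`, `n`, `K`, `N`, `p_value`, `p_adjusted`, `matched`
#'   (semicolon-joined overlapping IDs).
#' @export
enrichment <- function(selection, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  univ <- collection$universe
  sel <- intersect(unique(selection), univ)
  if (length(sel) == 0L) {
    stop("selection has no genes in the testing universe", call. = FALSE)
  }
  N <- length(univ); n <- length(sel)
  rows <- lapply(names(collection$sets), function(term) {
    members <- intersect(collection$sets[[term]], univ)
    hit <- intersect(sel, members)
    K <- length(members); k <- length(hit)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term,
               description = unname(collection$descriptions[term]),
               k = k, n = n, K = K, N = N, p_value = p,
               matched = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$term),
             c("term", "description", "k", "n", "K", "N", "p_value",
               "p_adjusted", "matched")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
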