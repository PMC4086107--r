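# Synthetic fixture generators: scale-free interactomes, planted-community
# graphs, two-group expression matrices with planted effects, and random GMT
# collections. All are deterministic under a fixed seed and emit exactly the
# text dialects the parsing modules consume, so the whole workflow runs
# without downloads.

#' Simulate a scale-free interactome
#'
#' Preferential attachment: starting from `m` isolated proteins, each new
#' protein attaches to `m` distinct existing proteins sampled with
#' probability proportional to degree + 1. The emitted graph has exactly
#' `(n - m) * m` edges, no self-loops and no duplicates, mimicking the
#' hub-dominated degree distribution of curated interactomes.
#'
#' @param n Number of proteins (>= m + 1).
#' @param m Edges added per new protein.
#' @param seed RNG seed (set when non-NULL).
#' @param path Optional path; when given, the edge list is written there in
#'   the tab-delimited interactome dialect.
#' @param prefix Protein ID prefix.
#' @return Two-column data frame of interactions (invisibly when `path` is
#'   given).
#' @export
simulate_ppi <- function(n = 500L, m = 3L, seed = NULL, path = NULL,
                         prefix = "P") {
  stopifnot(n >= 2L, m >= 1L, n > m)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  deg <- integer(n)
  from <- character((n - m) * m); to <- character((n - m) * m)
  pos <- 0L
  for (i in seq.int(m + 1L, n)) {
    targets <- sample.int(i - 1L, m, prob = deg[seq_len(i - 1L)] + 1)
    idx <- pos + seq_len(m)
    from[idx] <- ids[i]
    to[idx] <- ids[targets]
    deg[targets] <- deg[targets] + 1L
    deg[i] <- deg[i] + m
    pos <- pos + m
  }
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(edges))
  }
  edges
}

#' Simulate a planted-community graph
#'
#' Stochastic block model: `blocks` groups of `block_size` nodes; each
#' within-block pair is an edge with probability `p_in`, each between-block
#' pair with probability `p_out`. True block labels are returned for scoring
#' community recovery.
#'
#' @param blocks Number of blocks (>= 2).
#' @param block_size Nodes per block.
#' @param p_in,p_out Within-/between-block edge probabilities.
#' @param seed RNG seed (set when non-NULL).
#' @param path Optional path for the tab-delimited edge list.
#' @return List with `edges` (two-column data frame) and `labels` (named
#'   integer vector: node -> true block).
#' @export
simulate_communities <- function(blocks = 4L, block_size = 20L, p_in = 0.3,
                                 p_out = 0.02, seed = NULL, path = NULL) {
  stopifnot(blocks >= 2L, block_size >= 1L,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  if (p_in <= p_out) {
    warning("p_in <= p_out: no community structure to recover", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- blocks * block_size
  ids <- sprintf("N%03d", seq_len(n))
  labels <- setNames(rep(seq_len(blocks), each = block_size), ids)
  pairs <- utils::combn(n, 2L)
  same <- labels[pairs[1L, ]] == labels[pairs[2L, ]]
  prob <- ifelse(same, p_in, p_out)
  hit <- runif(ncol(pairs)) < prob
  edges <- data.frame(from = ids[pairs[1L, hit]], to = ids[pairs[2L, hit]],
                      stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  list(edges = edges, labels = labels)
}

#' Simulate a two-group expression dataset with planted effects
#'
#' Gaussian noise `N(baseline, sigma^2)` per gene and sample across two
#' groups (`A`, `B`; factor name `group`); a random subset of `n_planted`
#' genes is shifted by `effect` in group B. The baseline of 8 puts values on
#' a realistic log2-intensity scale. The truth (planted gene IDs) is
#' returned for scoring.
#'
#' @param genes Character vector of gene IDs, or a single integer count
#'   (IDs are then `G0001`, ...).
#' @param n_per_group Samples in each of the two groups (>= 2).
#' @param n_planted Number of genes receiving the effect.
#' @param effect Log2 shift added to planted genes in group B.
#' @param sigma Noise standard deviation.
#' @param baseline Mean log2 expression.
#' @param seed RNG seed (set when non-NULL).
#' @param path Optional path for the #CLASS-format text file.
#' @return List with `dataset` (an `expression_dataset`) and `planted`
#'   (character vector of shifted gene IDs).
#' @export
simulate_expression <- function(genes = 1000L, n_per_group = 10L,
                                n_planted = 50L, effect = 2, sigma = 0.5,
                                baseline = 8, seed = NULL, path = NULL) {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- sprintf("G%04d", seq_len(genes))
  }
  stopifnot(n_per_group >= 2L, n_planted <= length(genes), sigma > 0)
  if (!is.null(seed)) set.seed(seed)
  n_genes <- length(genes)
  samples <- c(paste0("A", seq_len(n_per_group)), paste0("B", seq_len(n_per_group)))
  values <- matrix(rnorm(n_genes * 2L * n_per_group, baseline, sigma),
                   n_genes, 2L * n_per_group,
                   dimnames = list(genes, samples))
  planted <- sort(sample(genes, n_planted))
  if (n_planted > 0L) {
    values[planted, seq.int(n_per_group + 1L, 2L * n_per_group)] <-
      values[planted, seq.int(n_per_group + 1L, 2L * n_per_group)] + effect
  }
  ds <- new_expression_dataset(
    values, factors = list(group = rep(c("A", "B"), each = n_per_group)),
    data_kind = "intensity")
  if (!is.null(path)) write_expression(ds, path)
  out <- list(dataset = ds, planted = planted)
  if (!is.null(path)) invisible(out) else out
}

#' Simulate a GMT gene-set collection
#'
#' Random term memberships drawn from a gene pool; optionally one planted
#' term is made a superset of a given selection (so that selection attains
#' the maximal possible overlap for the planted term).
#'
#' @param genes Character vector: the gene pool.
#' @param n_terms Number of random terms.
#' @param term_size Two-element range of term sizes.
#' @param planted Optional character vector; when given, an extra term
#'   `TPLANTED` containing all of it (plus a few random genes) is prepended.
#' @param seed RNG seed (set when non-NULL).
#' @param path Optional path for the GMT file.
#' @return A `gene_set_collection` (universe = union of members).
#' @export
simulate_gmt <- function(genes, n_terms = 20L, term_size = c(10L, 40L),
                         planted = NULL, seed = NULL, path = NULL) {
  stopifnot(n_terms >= 0L, max(term_size) <= length(genes))
  if (!is.null(seed)) set.seed(seed)
  sets <- list()
  if (!is.null(planted)) {
    extra <- sample(setdiff(genes, planted),
                    min(5L, length(setdiff(genes, planted))))
    sets[["TPLANTED"]] <- unique(c(planted, extra))
  }
  for (i in seq_len(n_terms)) {
    size <- sample(seq.int(term_size[1L], term_size[2L]), 1L)
    sets[[sprintf("T%03d", i)]] <- sort(sample(genes, size))
  }
  if (length(sets) == 0L) stop("no terms generated", call. = FALSE)
  desc <- setNames(paste("synthetic term", names(sets)), names(sets))
  collection <- structure(
    list(sets = sets, descriptions = desc,
         universe = sort(unique(unlist(sets, use.names = FALSE)))),
    class = "gene_set_collection")
  if (!is.null(path)) {
    write_gmt(collection, path)
    return(invisible(collection))
  }
  collection
}
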