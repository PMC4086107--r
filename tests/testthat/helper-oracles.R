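# Independent oracles used to validate the implementation: brute-force
# shortest-path enumeration for betweenness, exhaustive set-partition
# modularity search, explicit hypergeometric tail summation, and full
# permutation enumeration for the rank-sum test. None of these share code
# with the paths they check.

# Fractional betweenness by explicit enumeration of every shortest path
# (recursion over the BFS distance field; endpoints excluded).
brute_betweenness <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  btw <- setNames(numeric(n), nm)
  if (n < 3L) return(btw)
  d <- igraph::distances(g, weights = NA)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), names)
  names(adj) <- nm
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- nm[i]; t <- nm[j]
      if (!is.finite(d[s, t])) next
      paths <- list()
      recurse <- function(path, cur) {
        if (cur == t) {
          paths[[length(paths) + 1L]] <<- path
          return(invisible())
        }
        for (nb in adj[[cur]]) {
          if (d[s, nb] == d[s, cur] + 1 && d[nb, t] == d[cur, t] - 1) {
            recurse(c(path, nb), nb)
          }
        }
      }
      recurse(s, s)
      sigma <- length(paths)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / sigma
      }
    }
  }
  btw
}

# Newman-Girvan modularity of a membership vector (unit weights).
modularity_of <- function(edges_idx, membership, n_edges = nrow(edges_idx)) {
  m1 <- membership[edges_idx[, 1L]]
  m2 <- membership[edges_idx[, 2L]]
  deg <- tabulate(c(edges_idx[, 1L], edges_idx[, 2L]), length(membership))
  q <- 0
  for (c in unique(membership)) {
    ec <- sum(m1 == c & m2 == c)
    dc <- sum(deg[membership == c])
    q <- q + ec / n_edges - (dc / (2 * n_edges))^2
  }
  q
}

# Enumerate every set partition of n elements as restricted growth strings,
# calling fn(membership) on each.
for_each_partition <- function(n, fn) {
  recurse <- function(prefix, maxv) {
    i <- length(prefix) + 1L
    if (i > n) {
      fn(prefix)
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) recurse(c(prefix, v), max(maxv, v))
  }
  recurse(integer(0), 0L)
}

# Upper hypergeometric tail P(X >= k) by explicit summation.
hyper_tail_sum <- function(N, K, n, k) {
  if (k <= 0L) return(1)
  i <- seq.int(k, min(n, K))
  if (length(i) == 0L) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# One-sided rank-sum p by full enumeration of all C(n1+n2, n1) assignments.
enum_rank_sum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(r), n1)
  hits <- sum(apply(sets, 2L, function(idx) sum(r[idx]) >= w - 1e-9))
  hits / ncol(sets)
}

# Write an edge table (with a header line, so the loader's header heuristic
# never mistakes a data row for one) and load it as an interactome.
make_db <- function(edges, mapping = NULL) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(edges, f, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("protein_a", "protein_b"))
  mf <- NULL
  if (!is.null(mapping)) {
    mf <- tempfile(fileext = ".tsv")
    utils::write.table(mapping, mf, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  suppressMessages(load_interactions(f, mf))
}

# Erdos-Renyi edge table over lettered nodes (connectedness not required).
random_edge_table <- function(n, p) {
  ids <- sprintf("V%02d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  hit <- stats::runif(ncol(pairs)) < p
  while (!any(hit)) hit <- stats::runif(ncol(pairs)) < p
  data.frame(from = ids[pairs[1L, hit]], to = ids[pairs[2L, hit]],
             stringsAsFactors = FALSE)
}

clique_edges <- function(ids) {
  p <- utils::combn(ids, 2L)
  data.frame(from = p[1L, ], to = p[2L, ], stringsAsFactors = FALSE)
}

zero_order_all <- function(db) {
  suppressMessages(build_network(db, seed_set_from_list(db$proteins),
                                 order = "zero"))
}

edge_keys <- function(net) {
  e <- network_edges(net)
  paste(e$from, e$to, sep = "|")
}
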