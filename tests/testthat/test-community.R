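barbell_net <- function() {
  zero_order_all(make_db(rbind(clique_edges(paste0("a", 1:5)),
                               clique_edges(paste0("b", 1:5)),
                               data.frame(from = "a1", to = "b1"))))
}

test_that("edge weights follow the squared-mean-|logFC| formula with baseline", {
  db <- make_db(data.frame(from = c("X", "Y", "P"), to = c("Y", "Z", "Q")))
  net <- build_network(db, seed_set_from_list(c("X", "Y"), c(2, 4)),
                       order = "zero")
  w <- edge_weights(net)
  expect_equal(unname(w["X|Y"]), 1 + ((2 + 4) / 2)^2)  # 10
  # seed against non-seed: fc 2 vs absent (0)
  net2 <- build_network(db, seed_set_from_list("Y", 2))
  w2 <- edge_weights(net2)
  expect_equal(unname(w2["Y|Z"]), 1 + 1)
  # two non-seeds: baseline only
  expect_equal(unname(w2["X|Y"]), 1 + ((2 + 0) / 2)^2)
  net3 <- zero_order_all(db)
  expect_true(all(edge_weights(net3) == 1))
  expect_true(all(edge_weights(net2, baseline = 0.5) > 0))
})

test_that("walktrap splits a barbell into its two cliques", {
  part <- detect_modules(barbell_net(), steps = 4,
                         weights = rep(1, 21))
  expect_length(part$modules, 2L)
  expect_setequal(part$modules[[1L]], paste0("a", 1:5))
  expect_setequal(part$modules[[2L]], paste0("b", 1:5))
})

test_that("the barbell two-clique split is the exhaustive modularity optimum", {
  net <- barbell_net()
  nodes <- sort(network_nodes(net))
  e <- network_edges(net)
  idx <- cbind(match(e$from, nodes), match(e$to, nodes))
  best <- -Inf; best_membership <- NULL
  for_each_partition(10L, function(mem) {
    q <- modularity_of(idx, mem)
    if (q > best) {
      best <<- q
      best_membership <<- mem
    }
  })
  split <- split(nodes, best_membership)
  expect_length(split, 2L)
  expect_setequal(split[[which(vapply(split, function(s) "a1" %in% s, TRUE))]],
                  paste0("a", 1:5))
  # and walktrap attains that optimum
  part <- detect_modules(net, weights = rep(1, 21))
  mem_wt <- module_membership(part)[nodes]
  expect_equal(modularity_of(idx, as.integer(factor(mem_wt))), best)
})

test_that("structureless graphs yield a single module", {
  k6 <- zero_order_all(make_db(clique_edges(paste0("k", 1:6))))
  part <- detect_modules(k6, weights = rep(1, 15))
  expect_length(part$modules, 1L)
})

test_that("partitions disjointly cover the nodes, per component", {
  set.seed(55)
  for (i in 1:10) {
    net <- zero_order_all(make_db(random_edge_table(20, 0.15)))
    part <- detect_modules(net)
    nodes <- unlist(part$modules)
    expect_identical(sort(nodes), sort(network_nodes(net)))
    expect_equal(anyDuplicated(nodes), 0L)
  }
})

test_that("zero expression reduces weighted walktrap to the unweighted one", {
  set.seed(19)
  db <- make_db(random_edge_table(24, 0.18))
  unweighted <- zero_order_all(db)
  seeded <- build_network(db, seed_set_from_list(db$proteins, fc = 0),
                          order = "zero")
  p1 <- detect_modules(unweighted, weights = rep(1, length(edge_keys(unweighted))))
  p2 <- detect_modules(seeded)   # all fc = 0 -> every weight = baseline
  expect_identical(lapply(p1$modules, sort), lapply(p2$modules, sort))
})

test_that("module significance matches exact enumeration, ties included", {
  # 4-clique with no outgoing edges inside an 8-node network
  db <- make_db(rbind(clique_edges(paste0("m", 1:4)),
                      data.frame(from = c("o1", "o2", "o3"),
                                 to = c("o2", "o3", "o4"))))
  net <- zero_order_all(db)
  p <- module_significance(net, paste0("m", 1:4))
  expect_equal(p, 1 / 70)
  # internal == external: one-sided p about one half
  db2 <- make_db(data.frame(from = c("u1", "u2", "u1", "u2"),
                            to = c("u2", "u3", "v1", "v2")))
  # u1: internal 1 (to u2), external 1 (v1); u2: internal 2, external 1
  p2 <- module_significance(zero_order_all(db2), c("u1", "u2", "u3"))
  expect_gt(p2, 0.2)
  expect_lt(p2, 0.9)
  # random small modules: exact branch equals full permutation enumeration
  set.seed(66)
  for (i in 1:15) {
    net3 <- zero_order_all(make_db(random_edge_table(12, 0.3)))
    msize <- sample(2:6, 1)
    module <- sample(network_nodes(net3), msize)
    g <- net3$graph
    internal <- unname(igraph::degree(
      igraph::induced_subgraph(g, module))[module])
    external <- unname(igraph::degree(g)[module]) - internal
    expect_equal(module_significance(net3, module),
                 enum_rank_sum_p(internal, external))
  }
  expect_error(module_significance(net, network_nodes(net)), "proper subset")
  expect_error(module_significance(net, "m1"), "proper subset")
})

test_that("module significance is invariant under node relabeling", {
  set.seed(91)
  edges <- random_edge_table(14, 0.3)
  db <- make_db(edges)
  net <- zero_order_all(db)
  module <- sort(network_nodes(net))[1:5]
  p_orig <- module_significance(net, module)
  relabel <- setNames(sprintf("Z%02d", sample(14)), sort(network_nodes(net)))
  edges2 <- data.frame(from = relabel[edges$from], to = relabel[edges$to])
  net2 <- zero_order_all(make_db(edges2))
  expect_equal(module_significance(net2, unname(relabel[module])), p_orig)
})

test_that("modules rank by seed count with p-value and size tie-breaks", {
  sizes <- c(3, 4, 2)
  part <- structure(list(
    modules = list(c("x1", "x2", "x3"), c("y1", "y2", "y3", "y4"),
                   c("z1", "z2")),
    stats = data.frame(module = 1:3, size = sizes,
                       seed_count = c(0L, 3L, 1L),
                       mean_abs_fc = c(0, 1, 2),
                       p_value = c(0.5, 0.2, 0.1)),
    steps = 4L), class = "module_partition")
  ranked <- rank_modules(part)
  expect_equal(ranked$stats$seed_count, c(3L, 1L, 0L))
  # equal seed counts: smaller p first
  part$stats$seed_count <- c(1L, 1L, 0L)
  part$stats$p_value <- c(0.2, 0.01, 0.5)
  expect_identical(rank_modules(part)$modules[[1L]][1L], "y1")
})

test_that("seed mean |logFC| averages absolute values", {
  db <- make_db(data.frame(from = c("A", "B"), to = c("B", "C")))
  net <- build_network(db, seed_set_from_list(c("A", "B"), c(-2, 4)))
  part <- detect_modules(net)
  whole <- which(vapply(part$modules, function(m) "A" %in% m, TRUE))
  expect_equal(part$stats$mean_abs_fc[whole], 3)
})

test_that("module extraction yields the attribute-preserving induced subgraph", {
  db <- make_db(rbind(clique_edges(c("A", "B", "C")),
                      clique_edges(c("D", "E", "F"))))
  net <- build_network(db, seed_set_from_list(c("A", "D"), c(1.5, -1)))
  tri <- extract_module(net, c("A", "B", "C"))
  expect_setequal(network_nodes(tri), c("A", "B", "C"))
  expect_length(edge_keys(tri), 3L)
  expect_equal(igraph::V(tri$graph)$expression[
    igraph::V(tri$graph)$name == "A"], 1.5)
  # identity extraction copies the network; parent is untouched
  copy <- extract_module(net, network_nodes(net))
  expect_setequal(edge_keys(copy), edge_keys(net))
  expect_equal(network_size(net), 6L)
  # induced-subgraph oracle on a random module
  set.seed(14)
  rnet <- zero_order_all(make_db(random_edge_table(16, 0.3)))
  mod <- sample(network_nodes(rnet), 6)
  sub <- extract_module(rnet, mod)
  e <- network_edges(rnet)
  keep <- e$from %in% mod & e$to %in% mod
  expect_setequal(edge_keys(sub), paste(e$from, e$to, sep = "|")[keep])
  expect_error(extract_module(rnet, character(0)), "empty")
})
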