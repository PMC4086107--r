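path_db <- function() make_db(data.frame(from = c("A", "B", "C", "D"),
                                         to = c("B", "C", "D", "E")))

test_that("first-order networks induce seeds plus direct interactors", {
  db <- make_db(data.frame(from = c("A", "B", "C", "D", "X"),
                           to = c("B", "C", "D", "E", "Y")))
  net <- build_network(db, seed_set_from_list(c("A", "C")))
  expect_setequal(network_nodes(net), c("A", "B", "C", "D"))
  expect_setequal(edge_keys(net), c("A|B", "B|C", "C|D"))
  expect_equal(net$order, 1L)
  # seeds = all proteins saturates the database graph
  full <- build_network(db, seed_set_from_list(db$proteins))
  expect_setequal(network_nodes(full), db$proteins)
  expect_equal(length(edge_keys(full)), nrow(db$interactions))
  expect_error(build_network(db, seed_set_from_list("ZZZ")),
               "no seeds in interactome")
})

test_that("zero-order networks restrict to seeds, keeping singletons", {
  db <- make_db(data.frame(from = c("A", "B", "C"), to = c("B", "D", "E")))
  net <- build_network(db, seed_set_from_list(c("A", "B", "C")),
                       order = "zero")
  expect_setequal(network_nodes(net), c("A", "B", "C"))
  expect_identical(edge_keys(net), "A|B")
  expect_equal(net$order, 0L)
  # mutually non-interacting seeds give an edgeless network
  lonely <- build_network(db, seed_set_from_list(c("A", "D")), order = "zero")
  expect_length(edge_keys(lonely), 0L)
})

test_that("expansion treats all nodes as seeds and reaches the component", {
  db <- path_db()
  n1 <- build_network(db, seed_set_from_list("C"))
  expect_setequal(network_nodes(n1), c("B", "C", "D"))
  n2 <- expand_order(db, n1)
  expect_setequal(network_nodes(n2), c("A", "B", "C", "D", "E"))
  expect_equal(n2$order, 2L)
  expect_identical(network_nodes(n2)[igraph::V(n2$graph)$is_seed], "C")
  # fixed point once the component is saturated
  n3 <- expand_order(db, n2)
  expect_setequal(network_nodes(n3), network_nodes(n2))
  expect_setequal(edge_keys(n3), edge_keys(n2))
})

test_that("trimming keeps seeds and shortest-path connectors only", {
  db <- path_db()
  net <- build_network(db, seed_set_from_list(c("A", "C")))
  trimmed <- trim_to_minimum(net)
  expect_setequal(network_nodes(trimmed), c("A", "B", "C"))
  # all-seed network is unchanged
  all_seed <- build_network(db, seed_set_from_list(db$proteins), order = "zero")
  expect_setequal(network_nodes(trim_to_minimum(all_seed)), db$proteins)
  # fewer than two seeds is an error
  one <- build_network(db, seed_set_from_list("C"))
  expect_error(trim_to_minimum(one), "2 seed")
})

test_that("node exclusion removes incident edges and splits stars", {
  db <- make_db(data.frame(from = rep("H", 4), to = paste0("L", 1:4)))
  star <- build_network(db, seed_set_from_list("H"))
  out <- suppressWarnings(exclude_nodes(star, c("H", "ghost")))
  expect_warning(exclude_nodes(star, "ghost"), "not in the network")
  expect_equal(network_size(out), 4L)
  expect_length(edge_keys(out), 0L)
  expect_length(net_components(out), 4L)
  # absent-only exclusion leaves the network identical
  same <- suppressWarnings(exclude_nodes(star, "ghost"))
  expect_setequal(network_nodes(same), network_nodes(star))
  # handshake accounting on a random instance
  set.seed(8)
  db2 <- make_db(random_edge_table(15, 0.3))
  net2 <- zero_order_all(db2)
  drop <- network_nodes(net2)[1:3]
  g <- net2$graph
  incident <- length(unique(unlist(igraph::incident_edges(
    g, drop))))
  after <- suppressWarnings(exclude_nodes(net2, drop))
  expect_equal(sum(igraph::degree(after$graph)),
               sum(igraph::degree(g)) - 2 * incident)
})

test_that("components come continent-first with deterministic ties", {
  db <- make_db(rbind(clique_edges(c("A", "B", "C")),
                      clique_edges(c("D", "E", "F"))))
  comps <- net_components(zero_order_all(db))
  expect_length(comps, 2L)
  expect_setequal(network_nodes(comps[[1L]]), c("A", "B", "C"))  # tie: lexicographic
  # connected graph: one component equal to the input
  db2 <- path_db()
  net2 <- zero_order_all(db2)
  comps2 <- net_components(net2)
  expect_length(comps2, 1L)
  expect_setequal(network_nodes(comps2[[1L]]), network_nodes(net2))
  summ <- component_summary(net2)
  expect_equal(summ$nodes, 5L)
  expect_equal(summ$edges, 4L)
})

test_that("construction invariants hold on random db/seed instances", {
  set.seed(77)
  for (i in 1:30) {
    db <- make_db(random_edge_table(25, 0.12))
    seeds <- seed_set_from_list(sample(db$proteins, 4),
                                fc = rnorm(4))
    zero <- build_network(db, seeds, order = "zero")
    first <- build_network(db, seeds, order = "first")
    expanded <- expand_order(db, first)

    # monotone containment as node and edge sets
    expect_true(all(network_nodes(zero) %in% network_nodes(first)))
    expect_true(all(network_nodes(first) %in% network_nodes(expanded)))
    expect_true(all(edge_keys(zero) %in% edge_keys(first)))
    expect_true(all(edge_keys(first) %in% edge_keys(expanded)))

    # every constructed edge exists in the source database
    db_keys <- paste(db$interactions$from, db$interactions$to, sep = "|")
    expect_true(all(edge_keys(expanded) %in% db_keys))

    # components partition the node set
    comps <- net_components(first)
    all_nodes <- unlist(lapply(comps, network_nodes), use.names = FALSE)
    expect_identical(sort(all_nodes), sort(network_nodes(first)))
    expect_equal(anyDuplicated(all_nodes), 0L)

    # trimming preserves seed-pair connectivity and keeps only
    # shortest-path nodes (all-pairs oracle)
    trimmed <- trim_to_minimum(first)
    g <- first$graph
    seed_ids <- network_nodes(first)[igraph::V(g)$is_seed]
    d_before <- igraph::distances(g, v = seed_ids, to = seed_ids)
    d_after <- igraph::distances(trimmed$graph, v = seed_ids, to = seed_ids)
    expect_identical(is.finite(d_before), is.finite(d_after))
    d_all <- igraph::distances(g)
    for (v in setdiff(network_nodes(trimmed), seed_ids)) {
      on_some <- FALSE
      for (s in seed_ids) for (t in seed_ids) {
        if (s < t && is.finite(d_all[s, t]) &&
            d_all[s, v] + d_all[v, t] == d_all[s, t]) on_some <- TRUE
      }
      expect_true(on_some)
    }
  }
})
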