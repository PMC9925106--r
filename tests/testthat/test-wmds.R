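test_that("node weights follow the -log p sum raised to -gamma", {
  # single edge with p = e^-1: both endpoints have sum 1, weight 1
  g <- graph_from_pairs("a", "b")
  igraph::E(g)$p_value <- exp(-1)
  expect_equal(unname(node_weights(g, gamma = 0.7)), c(1, 1))

  # two incident edges with p = e^-1 and e^-3: sum 4, w = 4^-0.01
  g2 <- graph_from_pairs("a", "b", "a", "c")
  igraph::E(g2)$p_value <- c(exp(-1), exp(-3))
  w <- node_weights(g2, gamma = 0.01)
  expect_equal(unname(w["a"]), 4^-0.01, tolerance = 1e-12)
  expect_equal(unname(w["a"]), 0.98623, tolerance = 1e-5)

  # gamma = 0 gives unit weights
  expect_equal(unname(node_weights(g2, gamma = 0)), c(1, 1, 1))

  # isolated node has no defined weight
  g3 <- igraph::add_vertices(g2, 1, name = "d")
  expect_error(node_weights(g3), "isolated")
  # weights stay finite even at extreme p-values
  g4 <- graph_from_pairs("a", "b")
  igraph::E(g4)$p_value <- 1e-320
  expect_true(all(is.finite(node_weights(g4))))
})

test_that("exact solver finds known minimum dominating sets", {
  path <- graph_from_pairs("A", "B", "B", "C")
  expect_equal(solve_mds(path)$genes, "B")

  star <- graph_from_pairs("h", "l1", "h", "l2", "h", "l3", "h", "l4",
                           "h", "l5", "h", "l6")
  expect_equal(solve_mds(star)$genes, "h")

  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- letters[1:5]
  sol <- solve_mds(ring)
  expect_equal(sol$cardinality, 2)
  expect_true(is_dominating_set(ring, sol$genes))
  expect_equal(sol$status, "optimal")
})

test_that("weighted optimum prefers the cheaper interior node on a path", {
  path4 <- graph_from_pairs("A", "B", "B", "C", "C", "D")
  wB <- stats::setNames(c(1, 0.9, 1, 1), c("A", "B", "C", "D"))
  solB <- solve_wmds(structure(list(graph = path4, weights = wB, gamma = NA),
                               class = "wmds_problem"))
  expect_true("B" %in% solB$genes)
  wC <- stats::setNames(c(1, 1, 0.9, 1), c("A", "B", "C", "D"))
  solC <- solve_wmds(structure(list(graph = path4, weights = wC, gamma = NA),
                               class = "wmds_problem"))
  expect_true("C" %in% solC$genes)
  # both agree with exhaustive enumeration
  expect_equal(solB$objective, brute_force_dominating(path4, wB)$min_weight)
  expect_equal(solC$objective, brute_force_dominating(path4, wC)$min_weight)
})

test_that("brute force enumerates all optima on canonical graphs", {
  tri <- graph_from_pairs("a", "b", "b", "c", "a", "c")
  bt <- brute_force_dominating(tri)
  expect_equal(bt$min_cardinality, 1)
  expect_equal(length(bt$optimal_sets), 3)

  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- letters[1:5]
  br <- brute_force_dominating(ring)
  expect_equal(br$min_cardinality, 2)
  expect_equal(length(br$optimal_sets), 5)

  iso <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(iso)$name <- c("x", "y", "z")
  bi <- brute_force_dominating(iso)
  expect_equal(bi$min_cardinality, 3)
  expect_error(brute_force_dominating(random_test_graph(21, 0.2, seed = 1)),
               "20 nodes")
})

test_that("branch and bound matches exhaustive enumeration on random graphs", {
  set.seed(101)
  for (i in 1:60) {
    g <- random_test_graph(sample(4:12, 1), runif(1, 0.15, 0.5))
    g <- with_edge_pvalues(g)
    w <- if (all(igraph::degree(g) > 0)) {
      node_weights(g, gamma = 0.01)
    } else {
      stats::setNames(runif(igraph::vcount(g), 0.5, 1.5), igraph::V(g)$name)
    }
    bf <- brute_force_dominating(g, w)
    sol <- solve_wmds(structure(list(graph = g, weights = w, gamma = 0.01),
                                class = "wmds_problem"))
    expect_equal(sol$objective, bf$min_weight, tolerance = 1e-9)
    expect_true(is_dominating_set(g, sol$genes))
    mds <- solve_mds(g)
    expect_equal(mds$cardinality, bf$min_cardinality)
  }
})

test_that("greedy heuristic always dominates and never beats the optimum", {
  star <- graph_from_pairs("h", "l1", "h", "l2", "h", "l3", "h", "l4",
                           "h", "l5", "h", "l6")
  w <- stats::setNames(rep(1, 7), igraph::V(star)$name)
  gr <- greedy_wmds(structure(list(graph = star, weights = w, gamma = NA),
                              class = "wmds_problem"))
  expect_equal(gr$genes, "h")
  expect_equal(gr$status, "heuristic")

  set.seed(202)
  for (i in 1:25) {
    g <- with_edge_pvalues(random_test_graph(12, 0.3))
    if (any(igraph::degree(g) == 0) || igraph::gsize(g) == 0) next
    prob <- wmds_problem(g)
    gr <- greedy_wmds(prob)
    ex <- solve_wmds(prob)
    expect_true(is_dominating_set(g, gr$genes))
    expect_gte(gr$cardinality, ex$cardinality)
    expect_gte(gr$objective, ex$objective - 1e-9)
  }
})

test_that("adding an edge never increases the minimum cardinality", {
  set.seed(303)
  for (i in 1:20) {
    g <- random_test_graph(9, 0.25)
    base <- solve_mds(g)$cardinality
    non_edges <- which(!as.matrix(igraph::as_adjacency_matrix(g)) &
                         upper.tri(matrix(0, 9, 9)), arr.ind = TRUE)
    if (nrow(non_edges) == 0) next
    pick <- non_edges[sample(nrow(non_edges), 1), ]
    g2 <- igraph::add_edges(g, igraph::V(g)$name[pick])
    expect_lte(solve_mds(g2)$cardinality, base)
  }
})

test_that("the selected set is invariant to the logarithm base", {
  set.seed(404)
  for (i in 1:10) {
    g <- with_edge_pvalues(random_test_graph(11, 0.35))
    if (any(igraph::degree(g) == 0) || igraph::gsize(g) == 0) next
    s_ln <- solve_wmds(wmds_problem(g, log_base = exp(1)))
    s_l2 <- solve_wmds(wmds_problem(g, log_base = 2))
    expect_identical(s_ln$genes, s_l2$genes)
  }
})

test_that("degree baseline ranks by differential degree with name ties", {
  star <- graph_from_pairs("h", "a", "h", "b", "h", "c")
  expect_equal(degree_only_baseline(star, 1), "h")
  expect_setequal(degree_only_baseline(star, 4), c("h", "a", "b", "c"))
  expect_equal(degree_only_baseline(star, 3), c("h", "a", "b"))
  expect_error(degree_only_baseline(star, 5), "exceeds")
})
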