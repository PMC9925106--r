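test_that("pearson_edge matches hand-computed correlations", {
  expect_equal(pearson_edge(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_edge(c(1, 2, 3), c(3, 2, 1)), -1)
  # 4-point case: cov = 4/3, var = 5/3 each => r = 4/5
  expect_equal(pearson_edge(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  r <- pearson_edge(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(r))
  expect_true(isTRUE(attr(r, "zero_variance")))
  expect_error(pearson_edge(1:2, 1:2), "at least 3")
})

test_that("fisher_z is the odd closed-form transform with clamping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2, tolerance = 1e-12)
  expect_equal(fisher_z(-0.5), -log(3) / 2, tolerance = 1e-12)
  # inverse round-trip across the admissible range
  r <- seq(-0.999999, 0.999999, length.out = 101)
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.01), ">")
})

test_that("delta_z_test matches the closed form and is antisymmetric", {
  eq <- delta_z_test(0.4, 10, 0.4, 25)
  expect_equal(eq$delta_z, 0)
  expect_equal(eq$p_value, 1)

  # r1 = 0.5, r2 = 0, n1 = n2 = 28: dz = (ln 3 / 2) / sqrt(2/25)
  out <- delta_z_test(0.5, 28, 0, 28)
  expect_equal(out$delta_z, (log(3) / 2) / sqrt(2 / 25), tolerance = 1e-12)
  expect_equal(out$delta_z, 1.94209, tolerance = 1e-5)
  expect_equal(out$p_value, 0.05213, tolerance = 1e-4)

  swapped <- delta_z_test(0, 28, 0.5, 28)
  expect_equal(swapped$delta_z, -out$delta_z)
  expect_equal(swapped$p_value, out$p_value)

  # antisymmetry over random configurations
  set.seed(5)
  for (i in 1:20) {
    r1 <- runif(1, -0.9, 0.9); r2 <- runif(1, -0.9, 0.9)
    n1 <- sample(5:100, 1); n2 <- sample(5:100, 1)
    a <- delta_z_test(r1, n1, r2, n2)
    b <- delta_z_test(r2, n2, r1, n1)
    expect_equal(a$delta_z, -b$delta_z, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
  expect_error(delta_z_test(0.2, 3, 0.1, 20), "exceed 3")
})

test_that("differential network retains exactly the sub-alpha edges", {
  set.seed(21)
  # reference: ring over 60 genes plus chords; identical generating
  # distributions except one planted edge pair
  n_genes <- 60
  genes <- sprintf("g%02d", 1:n_genes)
  g <- igraph::make_ring(n_genes)
  igraph::V(g)$name <- genes
  n <- 100
  expr1 <- matrix(rnorm(n_genes * n), n_genes, dimnames = list(genes, paste0("a", 1:n)))
  expr2 <- matrix(rnorm(n_genes * n), n_genes, dimnames = list(genes, paste0("b", 1:n)))
  # plant a strong condition-1-only correlation on the edge g01-g02
  expr1["g02", ] <- 0.9 * expr1["g01", ] + sqrt(1 - 0.81) * rnorm(n)

  dnet <- suppressMessages(suppressWarnings(
    build_differential_network(expr1, expr2, g, alpha = 0.05)))
  expect_true(all(dnet$edges$p_value < 0.05))
  expect_true(any(dnet$edges$gene_i == "g01" & dnet$edges$gene_j == "g02"))
  # recomputing the test from stored correlations reproduces stored values
  re <- delta_z_test(dnet$edges$r1, dnet$n1, dnet$edges$r2, dnet$n2)
  expect_equal(re$p_value, dnet$edges$p_value, tolerance = 1e-12)
  expect_equal(sign(dnet$edges$delta_z),
               sign(dnet$edges$z1 - dnet$edges$z2))
  # degrees consistent with the retained edge set
  expect_equal(sum(igraph::degree(dnet$graph)), 2 * dnet$n_retained)

  # alpha = 1 keeps every computable edge and removes no node
  all_edges <- suppressMessages(build_differential_network(expr1, expr2, g, alpha = 1))
  expect_equal(all_edges$n_retained, igraph::gsize(g))
  expect_equal(all_edges$removed_isolated, 0)
})

test_that("null inputs retain about alpha of the edges", {
  set.seed(33)
  n_genes <- 100
  genes <- sprintf("g%03d", 1:n_genes)
  g <- igraph::sample_gnm(n_genes, 1000)
  igraph::V(g)$name <- genes
  n <- 50
  expr1 <- matrix(rnorm(n_genes * n), n_genes, dimnames = list(genes, paste0("a", 1:n)))
  expr2 <- matrix(rnorm(n_genes * n), n_genes, dimnames = list(genes, paste0("b", 1:n)))
  dnet <- suppressMessages(build_differential_network(expr1, expr2, g))
  frac <- dnet$n_retained / dnet$n_tested
  # 1000 null edges at alpha 0.05: +/- 4 binomial SDs
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / 1000))
})

test_that("differential network is invariant to input row/column order", {
  set.seed(8)
  sc <- synthetic_scenario(n_genes = 80, attach_edges = 2, n_blocks = 2,
                           block_size = 5, n1 = 40, n2 = 40, seed = 8)
  sim <- generate_expression_pair(sc)
  base <- suppressMessages(
    build_differential_network(sim$expr1, sim$expr2, sim$reference))
  perm1 <- sim$expr1[sample(nrow(sim$expr1)), sample(ncol(sim$expr1))]
  perm2 <- sim$expr2[sample(nrow(sim$expr2)), sample(ncol(sim$expr2))]
  shuffled <- suppressMessages(
    build_differential_network(perm1, perm2, sim$reference))
  expect_equal(shuffled$edges, base$edges, tolerance = 1e-12)
})

test_that("zero-variance genes drop their edges rather than faking r = 0", {
  genes <- c("c1", "c2", "x", "y")
  g <- graph_from_pairs("c1", "x", "x", "y", "c2", "y")
  set.seed(2)
  mk <- function(tag) {
    m <- matrix(rnorm(4 * 30), 4, dimnames = list(genes, paste0(tag, 1:30)))
    m["c1", ] <- 7  # constant gene
    m
  }
  dnet <- suppressMessages(build_differential_network(mk("a"), mk("b"), g, alpha = 1))
  expect_equal(dnet$dropped_zero_variance, 1)
  expect_false("c1" %in% c(dnet$edges$gene_i, dnet$edges$gene_j))
})

test_that("scale-free fit recovers a planted power law", {
  # exact counts count(k) = round(400 k^-2), one node of degree k per count
  k <- 1:20
  cnt <- round(400 * k^-2)
  k <- k[cnt >= 1]; cnt <- cnt[cnt >= 1]
  fit <- scale_free_fit(rep(k, cnt))
  expect_gt(fit$r_squared, 0.99)
  expect_lt(fit$slope, 0)
  expect_equal(fit$r_squared,
               stats::cor(fit$points$log2_degree, fit$points$log2_count)^2,
               tolerance = 1e-12)

  flat <- scale_free_fit(rep(1:6, each = 10))
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  star <- igraph::make_star(6, mode = "undirected")
  expect_error(scale_free_fit(star), "3 distinct")
})

test_that("null calibration approaches the standard normal", {
  cal <- null_calibration(30, 30, reps = 2e4, seed = 99)
  expect_lt(cal$ks_statistic, 0.03)
  expect_lt(abs(cal$type_one_error - 0.05),
            4 * sqrt(0.05 * 0.95 / 2e4))
  expect_error(null_calibration(30, 30, reps = 100), "1e4")
})
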