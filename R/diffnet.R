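#' Pearson correlation between two expression vectors
#'
#' Plain product-moment correlation; exposed separately because it is the
#' edge statistic of the co-expression networks.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return The correlation, or `NA_real_` with a `"zero_variance"` attribute
#'   when either vector is constant (such edges are treated as uncomputable
#'   and dropped downstream).
#' @export
pearson_edge <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_
    attr(r, "zero_variance") <- TRUE
    return(r)
  }
  stats::cor(x, y)
}

#' Fisher Z-transformation of a correlation coefficient
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`. Correlations with
#' `|r| >= 1 - 1e-7` are clamped to that bound first so the transform stays
#' finite; for a sample correlation from `n` observations, `z` is
#' approximately normal with standard deviation `1 / sqrt(n - 3)`.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return Transformed values, same length as `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1")
  lim <- 1 - 1e-7
  atanh(pmin(pmax(r, -lim), lim))
}

#' Test the difference of two correlations (Fisher Z edge test)
#'
#' Standardized difference of Fisher-transformed correlations,
#' `delta_z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`, which is approximately
#' standard normal when the two population correlations are equal. The
#' returned p-value is two-sided.
#'
#' @param r1,r2 Correlation of the edge in condition 1 and 2 (vectorized).
#' @param n1,n2 Sample sizes of the two conditions; both must exceed 3.
#' @return A list with numeric vectors `delta_z` and `p_value` (floored at
#'   1e-300 so downstream `-log(p)` stays finite).
#' @export
delta_z_test <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  dz <- (fisher_z(r1) - fisher_z(r2)) / se
  p <- pmax(2 * stats::pnorm(-abs(dz)), 1e-300)
  list(delta_z = dz, p_value = p)
}

#' Build the differential co-expression network between two conditions
#'
#' For every reference-network edge whose endpoints are present (with
#' non-constant expression) in both expression matrices, computes the Pearson
#' correlation per condition, applies the Fisher Z edge test, and keeps the
#' edges with `p_value < alpha`. Nodes left without a significant edge are
#' removed.
#'
#' @param expr1,expr2 Genes-by-samples matrices for conditions 1 and 2 (gene
#'   rownames; at least 4 samples each). A warning is emitted below 15
#'   samples, where the normal approximation of the edge test degrades.
#' @param reference An `igraph` reference network over gene symbols.
#' @param alpha Edge significance threshold (default 0.05, strict `<`).
#' @return A `differential_network`: a list with `graph` (an `igraph` whose
#'   edges carry `r1`, `r2`, `z1`, `z2`, `delta_z`, `p_value`), `edges`
#'   (the same as a data.frame, canonically ordered), sample sizes `n1`,
#'   `n2`, `alpha`, and bookkeeping counts (`n_tested`, `n_retained`,
#'   `removed_isolated`, `dropped_zero_variance`, `clamped`).
#' @export
build_differential_network <- function(expr1, expr2, reference, alpha = 0.05) {
  stopifnot(is.matrix(expr1), is.matrix(expr2))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  n1 <- ncol(expr1)
  n2 <- ncol(expr2)
  if (n1 < 4 || n2 < 4) stop("need at least 4 samples per condition")
  if (min(n1, n2) < 15) {
    warning("sample size below 15: edge p-values are only roughly calibrated")
  }
  genes <- intersect(rownames(expr1), rownames(expr2))
  net <- restrict_to_expressed(reference, genes)

  sd1 <- apply(expr1[igraph::V(net)$name, , drop = FALSE], 1, stats::sd)
  sd2 <- apply(expr2[igraph::V(net)$name, , drop = FALSE], 1, stats::sd)
  constant <- names(sd1)[sd1 == 0 | sd2 == 0]

  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0L) stop("reference network has no testable edges")
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]
  computable <- !(el[, 1] %in% constant | el[, 2] %in% constant)
  dropped_zero_var <- sum(!computable)
  if (dropped_zero_var > 0) {
    message("dropped ", dropped_zero_var,
            " edge(s) with zero-variance expression")
  }
  el <- el[computable, , drop = FALSE]
  if (nrow(el) == 0L) stop("no computable edges (constant expression)")

  r1 <- edgewise_correlation(expr1, el)
  r2 <- edgewise_correlation(expr2, el)
  clamped <- sum(abs(r1) >= 1 - 1e-7) + sum(abs(r2) >= 1 - 1e-7)
  if (clamped > 0) {
    message(clamped, " correlation(s) at |r| ~ 1 clamped before the Fisher ",
            "transform")
  }
  test <- delta_z_test(r1, n1, r2, n2)

  keep <- test$p_value < alpha
  if (!any(keep)) stop("no differential signal at alpha = ", alpha)
  edges <- data.frame(gene_i = el[keep, 1], gene_j = el[keep, 2],
                      r1 = r1[keep], r2 = r2[keep],
                      z1 = fisher_z(r1[keep]), z2 = fisher_z(r2[keep]),
                      delta_z = test$delta_z[keep],
                      p_value = test$p_value[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
  rownames(edges) <- NULL

  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  removed_isolated <- length(setdiff(c(el[, 1], el[, 2]),
                                     igraph::V(g)$name))
  if (removed_isolated > 0) {
    message("removed ", removed_isolated,
            " node(s) isolated after edge filtering")
  }
  structure(list(graph = g, edges = edges, n1 = n1, n2 = n2, alpha = alpha,
                 n_tested = nrow(el), n_retained = nrow(edges),
                 removed_isolated = removed_isolated,
                 dropped_zero_variance = dropped_zero_var,
                 clamped = clamped),
            class = "differential_network")
}

#' @export
print.differential_network <- function(x, ...) {
  cat("Differential co-expression network\n")
  cat("  nodes:", igraph::vcount(x$graph),
      " edges:", x$n_retained, "of", x$n_tested, "tested\n")
  cat("  alpha:", x$alpha, " samples:", x$n1, "vs", x$n2, "\n")
  invisible(x)
}

#' Write the edge table of a differential network as TSV
#'
#' @param dnet A [differential_network].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_differential_network <- function(dnet, path) {
  stopifnot(inherits(dnet, "differential_network"))
  utils::write.table(dnet$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Scale-free topology fit of a degree distribution
#'
#' Ordinary least-squares fit of `log2(count of nodes with degree k)` on
#' `log2(k)` over the distinct observed degrees `k >= 1` (one point per
#' degree, no binning). The slope estimates the negative power-law exponent
#' and `r_squared` quantifies how well the network approximates scale-free
#' topology; values above 0.8 are conventionally taken as adequate.
#'
#' @param net An `igraph` graph, or a numeric vector of node degrees.
#' @return A list with `points` (data.frame `log2_degree`, `log2_count`),
#'   `slope`, `intercept` and `r_squared`.
#' @export
scale_free_fit <- function(net) {
  deg <- if (igraph::is_igraph(net)) igraph::degree(net) else net
  deg <- deg[deg >= 1]
  tab <- table(deg)
  if (length(tab) < 3L) {
    stop("need at least 3 distinct positive degrees to fit")
  }
  pts <- data.frame(log2_degree = log2(as.numeric(names(tab))),
                    log2_count = log2(as.numeric(tab)))
  fit <- stats::lm(log2_count ~ log2_degree, data = pts)
  # suppressed: lm warns on degenerate (constant-count) inputs
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(points = pts,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Null calibration of the Fisher Z edge test by simulation
#'
#' Simulates independent Gaussian expression pairs for both conditions
#' (population correlation zero in each, so the null of equal correlations
#' holds), computes the `delta_z` statistic per replicate, and summarizes its
#' agreement with the standard normal reference distribution.
#'
#' @param n1,n2 Sample sizes per condition (greater than 3).
#' @param reps Number of replicates (at least 1e4).
#' @param seed Integer seed.
#' @param alpha Significance level for the type-I error estimate.
#' @return A list with `delta_z` (the simulated statistics), `ks_statistic`
#'   (Kolmogorov-Smirnov distance to N(0,1)) and `type_one_error` (the
#'   fraction of replicates with `p < alpha`).
#' @export
null_calibration <- function(n1, n2, reps = 1e5, seed = 1, alpha = 0.05) {
  if (reps < 1e4) stop("reps must be at least 1e4 for a stable calibration")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  set.seed(seed)
  r1 <- simulate_null_correlations(n1, reps)
  r2 <- simulate_null_correlations(n2, reps)
  test <- delta_z_test(r1, n1, r2, n2)
  ks <- unname(stats::ks.test(test$delta_z, "pnorm")$statistic)
  list(delta_z = test$delta_z,
       ks_statistic = ks,
       type_one_error = mean(test$p_value < alpha))
}

# Correlations of `reps` independent standard-normal pairs of length n,
# computed column-wise without materializing per-replicate calls to cor().
simulate_null_correlations <- function(n, reps) {
  x <- matrix(stats::rnorm(n * reps), nrow = n)
  y <- matrix(stats::rnorm(n * reps), nrow = n)
  x <- sweep(x, 2, colMeans(x))
  y <- sweep(y, 2, colMeans(y))
  colSums(x * y) / sqrt(colSums(x^2) * colSums(y^2))
}

# Pearson correlations for a set of gene pairs, vectorized over edges.
# expr: genes x samples matrix; pairs: 2-column character matrix.
edgewise_correlation <- function(expr, pairs) {
  z <- expr[unique(c(pairs)), , drop = FALSE]
  z <- z - rowMeans(z)
  ss <- sqrt(rowSums(z^2))
  z <- z / ss
  r <- rowSums(z[pairs[, 1], , drop = FALSE] * z[pairs[, 2], , drop = FALSE])
  pmin(pmax(r, -1), 1)
}
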