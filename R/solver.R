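#' Node weights for the weighted minimum dominating set
#'
#' Each node's weight is `(sum over incident edges of -log(p)) ^ (-gamma)`:
#' high degree and strongly differential incident edges give a large sum,
#' hence a small weight, hence a node the minimization prefers. The natural
#' logarithm is used; any other base rescales all weights by a common positive
#' factor and cannot change which set is optimal. With `gamma = 0` all weights
#' are exactly 1 and the problem reduces to the unweighted minimum dominating
#' set.
#'
#' @param dnet A [differential_network], or an `igraph` whose edges carry a
#'   `p_value` attribute. Every node must have at least one incident edge.
#' @param gamma Non-negative weight exponent (default 0.01).
#' @param log_base Base of the logarithm in the weight sum (default `exp(1)`;
#'   exposed to make the invariance of the selected set testable).
#' @return A named numeric vector of positive node weights.
#' @export
node_weights <- function(dnet, gamma = 0.01, log_base = exp(1)) {
  g <- if (inherits(dnet, "differential_network")) dnet$graph else dnet
  if (gamma < 0) stop("gamma must be non-negative")
  if (igraph::vcount(g) == 0L) stop("empty graph")
  if (any(igraph::degree(g) == 0L)) {
    stop("weight undefined for isolated node(s); remove them first")
  }
  p <- igraph::E(g)$p_value
  if (is.null(p)) stop("edges carry no p_value attribute")
  # keep -log(p) strictly positive and finite
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  el <- igraph::as_edgelist(g)
  s <- rowsum(c(-log(p, base = log_base), -log(p, base = log_base)),
              c(el[, 1], el[, 2]))
  w <- drop(s)^(-gamma)
  w[sort(names(w))]
}

#' Construct a weighted minimum dominating set problem
#'
#' @param dnet A [differential_network] or an `igraph` with edge `p_value`s.
#' @param gamma Weight exponent passed to [node_weights()].
#' @param weights Optional named weight vector overriding [node_weights()].
#' @param log_base Passed to [node_weights()].
#' @return A `wmds_problem`: list with `graph`, `weights`, `gamma`.
#' @export
wmds_problem <- function(dnet, gamma = 0.01, weights = NULL,
                         log_base = exp(1)) {
  g <- if (inherits(dnet, "differential_network")) dnet$graph else dnet
  if (is.null(weights)) {
    weights <- node_weights(dnet, gamma = gamma, log_base = log_base)
  } else {
    if (is.null(names(weights)) ||
        !setequal(names(weights), igraph::V(g)$name)) {
      stop("weights must be named by the graph's genes")
    }
    if (any(!is.finite(weights)) || any(weights <= 0)) {
      stop("weights must be finite and positive")
    }
  }
  structure(list(graph = g, weights = weights, gamma = gamma),
            class = "wmds_problem")
}

#' Solve the weighted minimum dominating set exactly
#'
#' Minimizes the total weight of a dominating set: `sum(w_i * x_i)` over
#' binary `x` subject to `x_i + sum(x_j, j adjacent to i) >= 1` for every
#' node. Solved exactly by branch and bound per connected component; a node
#' budget / wall-clock limit triggers a greedy fallback for the affected
#' component, and the result is then flagged `"heuristic"`. The search order
#' is fixed (genes sorted, coverers tried by increasing weight), so the
#' returned optimum is deterministic even when several optima exist.
#'
#' @param problem A [wmds_problem], a [differential_network], or an `igraph`
#'   with edge `p_value`s (the latter two are wrapped with default `gamma`).
#' @param mode `"exact"` (default) or `"greedy"`.
#' @param time_limit Wall-clock limit in seconds for the exact search
#'   (default 600).
#' @param gamma Used when `problem` is not already a [wmds_problem].
#' @return A `driver_solution`: list with sorted `genes`, `objective`,
#'   `cardinality`, `status` (`"optimal"` or `"heuristic"`), `weights` and
#'   `gamma`. Every returned set is post-checked to dominate the graph.
#' @export
solve_wmds <- function(problem, mode = c("exact", "greedy"),
                       time_limit = 600, gamma = 0.01) {
  mode <- match.arg(mode)
  if (!inherits(problem, "wmds_problem")) {
    problem <- wmds_problem(problem, gamma = gamma)
  }
  g <- problem$graph
  w <- problem$weights
  vs <- sort(igraph::V(g)$name)
  comp <- igraph::components(g)
  selected <- character(0)
  status <- "optimal"

  for (k in seq_len(comp$no)) {
    members <- sort(igraph::V(g)$name[comp$membership == k])
    if (length(members) == 1L) {
      selected <- c(selected, members)
      next
    }
    sub <- igraph::induced_subgraph(g, members)
    # canonical vertex order inside the component
    perm <- match(sort(igraph::V(sub)$name), igraph::V(sub)$name)
    sub <- igraph::permute(sub, order(perm))
    nm <- igraph::V(sub)$name
    adj <- igraph::as_adj_list(sub)
    adj <- lapply(adj, as.integer)
    wk <- unname(w[nm])

    greedy_idx <- greedy_cover_indices(adj, wk)
    if (mode == "greedy") {
      selected <- c(selected, nm[greedy_idx])
      status <- "heuristic"
      next
    }
    res <- cpp_bb_wmds(adj, wk, greedy_idx, sum(wk[greedy_idx]) + 1e-9,
                       time_limit, 2^52)
    if (!res$optimal) status <- "heuristic"
    selected <- c(selected, nm[res$set])
  }

  selected <- sort(unique(selected))
  sol <- structure(list(genes = selected,
                        objective = sum(w[selected]),
                        cardinality = length(selected),
                        status = status,
                        weights = w,
                        gamma = problem$gamma),
                   class = "driver_solution")
  if (!is_dominating_set(g, selected)) {
    stop("internal error: returned set does not dominate the graph")
  }
  sol
}

#' Solve the unweighted minimum dominating set
#'
#' Unit-weight special case of [solve_wmds()]: returns a minimum-cardinality
#' dominating set.
#'
#' @param graph An `igraph` graph.
#' @inheritParams solve_wmds
#' @return A `driver_solution` with `gamma = 0` and unit weights.
#' @export
solve_mds <- function(graph, mode = c("exact", "greedy"), time_limit = 600) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  w <- stats::setNames(rep(1, igraph::vcount(graph)), igraph::V(graph)$name)
  prob <- structure(list(graph = graph, weights = w, gamma = 0),
                    class = "wmds_problem")
  solve_wmds(prob, mode = mode, time_limit = time_limit)
}

#' Greedy weighted dominating set (scalable heuristic)
#'
#' Repeatedly selects the node maximizing (number of newly dominated nodes) /
#' weight until all nodes are dominated; ties are broken by smaller weight
#' and then by gene name. The result is always a dominating set but carries
#' status `"heuristic"`.
#'
#' @param problem A [wmds_problem] (or anything [solve_wmds()] accepts).
#' @param gamma Used when wrapping a raw network.
#' @return A `driver_solution`.
#' @export
greedy_wmds <- function(problem, gamma = 0.01) {
  solve_wmds(problem, mode = "greedy", gamma = gamma)
}

#' Exhaustive dominating-set enumeration (oracle for small graphs)
#'
#' Enumerates all `2^n` node subsets (`n <= 20`) and returns the exact
#' minimum cardinality, every minimum-cardinality dominating set, and the
#' minimum weighted objective.
#'
#' @param graph An `igraph` graph with at most 20 nodes.
#' @param weights Optional named node weights (default all 1).
#' @return A list with `min_cardinality`, `optimal_sets` (list of character
#'   vectors), `min_weight` and `min_weight_set`.
#' @export
brute_force_dominating <- function(graph, weights = NULL) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  if (n > 20L) stop("brute-force enumeration is limited to 20 nodes")
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, n), nm)
  }
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  res <- cpp_brute_force_dominating(adj, unname(weights[nm]))
  list(min_cardinality = res$min_cardinality,
       optimal_sets = lapply(res$optimal_sets, function(i) sort(nm[i])),
       min_weight = res$min_weight,
       min_weight_set = sort(nm[res$min_weight_set]))
}

#' Degree-ranked baseline driver list
#'
#' Naive comparator: the top `k` nodes of the differential network ranked by
#' degree, ties broken lexicographically by gene name.
#'
#' @param dnet A [differential_network] or `igraph`.
#' @param k Number of genes to return (at most the node count).
#' @return Character vector of `k` gene symbols.
#' @export
degree_only_baseline <- function(dnet, k) {
  g <- if (inherits(dnet, "differential_network")) dnet$graph else dnet
  if (k > igraph::vcount(g)) stop("k exceeds the number of nodes")
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  names(deg)[ord][seq_len(k)]
}

#' Check whether a node set dominates a graph
#'
#' @param graph An `igraph` graph.
#' @param genes Character vector of node names.
#' @return `TRUE` if every node is in `genes` or adjacent to a member.
#' @export
is_dominating_set <- function(graph, genes) {
  if (igraph::vcount(graph) == 0L) return(TRUE)
  covered <- igraph::V(graph)$name %in% genes
  if (length(genes) > 0) {
    nbrs <- igraph::adjacent_vertices(graph, genes)
    covered[unique(unlist(nbrs))] <- TRUE
  }
  all(covered)
}

#' @export
print.driver_solution <- function(x, ...) {
  cat("Driver solution (", x$status, ")\n", sep = "")
  cat("  genes:", x$cardinality, " objective:", format(x$objective), "\n")
  if (x$cardinality > 0) {
    shown <- utils::head(x$genes, 10)
    cat("  ", paste(shown, collapse = ", "),
        if (x$cardinality > 10) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

# Greedy weighted set-cover on closed neighborhoods; returns 1-based indices.
greedy_cover_indices <- function(adj, w) {
  n <- length(adj)
  closed <- lapply(seq_len(n), function(i) c(i, adj[[i]]))
  undominated <- rep(TRUE, n)
  picked <- integer(0)
  avail <- rep(TRUE, n)
  while (any(undominated)) {
    gain <- vapply(seq_len(n), function(i) {
      if (!avail[i]) return(-Inf)
      sum(undominated[closed[[i]]]) / w[i]
    }, 0)
    best <- which(gain == max(gain))
    if (length(best) > 1L) best <- best[order(w[best], best)][1]
    picked <- c(picked, best)
    avail[best] <- FALSE
    undominated[closed[[best]]] <- FALSE
  }
  sort(picked)
}
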