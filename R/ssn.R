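#' Single-sample network edge perturbation test
#'
#' Tests whether adding one tumor sample to a cohort of `n` normal samples
#' perturbs an edge's correlation. The statistic is
#' `z = delta_r * (n - 1) / (1 - r_ref^2)` with `delta_r = r_pert - r_ref`,
#' the defining statistic of the sample-specific network method; the p-value
#' is the two-sided standard-normal tail. The normal reference is an
#' approximation (the exact null law of `z` is a quadratic form in Gaussians
#' with unit variance but heavier tails), so per-edge retention under the
#' null runs slightly above the nominal level.
#'
#' @param r_ref Edge correlation over the `n` normal samples (`|r_ref| < 1`).
#' @param r_pert Edge correlation over the `n` normals plus the tumor sample.
#' @param n Number of normal samples (at least 4).
#' @return A list with vectors `delta_r`, `z` and `p_value`.
#' @export
ssn_edge_test <- function(r_ref, r_pert, n) {
  if (n < 4) stop("need at least 4 normal samples")
  if (any(abs(r_ref) >= 1 - 1e-12)) {
    stop("degenerate reference correlation |r_ref| = 1")
  }
  delta_r <- r_pert - r_ref
  z <- delta_r * (n - 1) / (1 - r_ref^2)
  list(delta_r = delta_r, z = z,
       p_value = pmax(2 * stats::pnorm(-abs(z)), 1e-300))
}

#' Personalized differential network for one tumor sample
#'
#' Computes each reference edge's correlation over the normal cohort, then
#' over the cohort plus the single tumor sample, applies [ssn_edge_test()]
#' and keeps edges with `p_value < alpha`. The per-patient gene universe is
#' the intersection of the network genes with those present in both the
#' normal matrix and the tumor sample.
#'
#' @param normal_expr Genes-by-samples matrix of the normal cohort (n >= 4).
#' @param tumor_sample Named numeric vector (or one-column matrix) of one
#'   tumor sample's expression.
#' @param reference An `igraph` reference network.
#' @param alpha Edge significance threshold (default 0.05).
#' @return A `differential_network`-shaped object whose edges carry `r_ref`,
#'   `r_pert`, `delta_r`, `z` and `p_value`. When no edge is retained, the
#'   result has an empty graph and `n_retained = 0` (the patient simply
#'   yields no drivers); this is flagged, not an error.
#' @export
build_personalized_network <- function(normal_expr, tumor_sample, reference,
                                       alpha = 0.05) {
  stopifnot(is.matrix(normal_expr))
  if (is.matrix(tumor_sample)) {
    if (ncol(tumor_sample) != 1L) stop("tumor_sample must be a single column")
    tumor_sample <- stats::setNames(tumor_sample[, 1], rownames(tumor_sample))
  }
  n <- ncol(normal_expr)
  if (n < 4) stop("need at least 4 normal samples")
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  genes <- intersect(rownames(normal_expr), names(tumor_sample))
  net <- restrict_to_expressed(reference, genes)

  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0L) stop("reference network has no testable edges")
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]

  sdn <- apply(normal_expr[igraph::V(net)$name, , drop = FALSE], 1, stats::sd)
  constant <- names(sdn)[sdn == 0]
  el <- el[!(el[, 1] %in% constant | el[, 2] %in% constant), , drop = FALSE]
  if (nrow(el) == 0L) stop("no computable edges (constant normal expression)")

  r_ref <- edgewise_correlation(normal_expr, el)
  pert <- cbind(normal_expr[, , drop = FALSE],
                tumor = tumor_sample[rownames(normal_expr)])
  r_pert <- edgewise_correlation(pert, el)
  lim <- 1 - 1e-7
  r_ref <- pmin(pmax(r_ref, -lim), lim)
  test <- ssn_edge_test(r_ref, r_pert, n)

  keep <- test$p_value < alpha
  edges <- data.frame(gene_i = el[keep, 1], gene_j = el[keep, 2],
                      r_ref = r_ref[keep], r_pert = r_pert[keep],
                      delta_r = test$delta_r[keep], z = test$z[keep],
                      p_value = test$p_value[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
  rownames(edges) <- NULL
  g <- if (nrow(edges) > 0) {
    igraph::graph_from_data_frame(edges, directed = FALSE)
  } else {
    igraph::make_empty_graph(0, directed = FALSE)
  }
  structure(list(graph = g, edges = edges, n1 = n, n2 = 1L, alpha = alpha,
                 n_tested = nrow(el), n_retained = nrow(edges),
                 removed_isolated = length(setdiff(c(el[, 1], el[, 2]),
                                                   igraph::V(g)$name)),
                 dropped_zero_variance = length(constant),
                 clamped = 0L),
            class = "differential_network")
}

#' Personalized driver genes for a cohort of patients
#'
#' Solves the weighted minimum dominating set independently on each patient's
#' personalized network and aggregates per-gene driver frequencies across the
#' cohort. A solver failure for one patient is caught and logged; the patient
#' contributes an empty driver set instead of aborting the cohort.
#'
#' @param networks Named list of per-patient networks as returned by
#'   [build_personalized_network()].
#' @param gamma Weight exponent (default 0.01).
#' @param time_limit Per-patient solver time limit in seconds.
#' @return A `patient_driver_profiles` object: list with `profiles` (named
#'   list of per-patient list(drivers, status)) and `frequency` (data.frame
#'   gene / frequency / bin, see [classify_driver_frequency()]).
#' @export
personalized_drivers <- function(networks, gamma = 0.01, time_limit = 600) {
  if (length(networks) == 0L) stop("no patient networks supplied")
  if (is.null(names(networks))) {
    names(networks) <- sprintf("patient%03d", seq_along(networks))
  }
  profiles <- lapply(names(networks), function(id) {
    nw <- networks[[id]]
    if (nw$n_retained == 0L) {
      return(list(drivers = character(0), status = "empty"))
    }
    res <- tryCatch(
      solve_wmds(nw, gamma = gamma, time_limit = time_limit),
      error = function(e) {
        message("patient ", id, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) return(list(drivers = character(0), status = "failed"))
    list(drivers = res$genes, status = res$status)
  })
  names(profiles) <- names(networks)
  freq <- driver_frequency(profiles)
  structure(list(profiles = profiles, frequency = freq),
            class = "patient_driver_profiles")
}

#' Merge personalized drivers into a cohort-level list
#'
#' Genes whose personalized-driver frequency across patients is at least
#' `merge_threshold` (default 0.5, inclusive) form the cohort-level
#' prediction. The returned table also bins every gene by frequency:
#' high (>= 0.6), medium (0.3 <= f < 0.6), low (< 0.3).
#'
#' @param profiles A `patient_driver_profiles` object, or the list of
#'   per-patient profiles it contains.
#' @param merge_threshold Inclusive frequency cutoff (default 0.5).
#' @return A list with `genes` (the merged, sorted gene list) and `frequency`
#'   (data.frame gene / frequency / bin for every gene seen in any patient).
#' @export
aggregate_personalized <- function(profiles, merge_threshold = 0.5) {
  freq <- if (inherits(profiles, "patient_driver_profiles")) {
    profiles$frequency
  } else {
    driver_frequency(profiles)
  }
  list(genes = sort(freq$gene[freq$frequency >= merge_threshold]),
       frequency = freq)
}

#' Bin driver frequencies into high / medium / low classes
#'
#' @param frequency Numeric vector of frequencies in `[0, 1]`.
#' @return Factor with levels `low` (< 0.3), `medium` (0.3 <= f < 0.6) and
#'   `high` (>= 0.6).
#' @export
classify_driver_frequency <- function(frequency) {
  if (any(frequency < 0 | frequency > 1)) stop("frequencies must be in [0, 1]")
  cut(frequency, breaks = c(-Inf, 0.3, 0.6, Inf),
      labels = c("low", "medium", "high"), right = FALSE)
}

# Per-gene driver frequency across patient profiles.
driver_frequency <- function(profiles) {
  npat <- length(profiles)
  all_genes <- sort(unique(unlist(lapply(profiles, `[[`, "drivers"))))
  counts <- vapply(all_genes, function(g) {
    sum(vapply(profiles, function(p) g %in% p$drivers, TRUE))
  }, 0L)
  f <- if (npat > 0) counts / npat else numeric(0)
  data.frame(gene = all_genes, frequency = unname(f),
             bin = classify_driver_frequency(unname(f)),
             stringsAsFactors = FALSE)
}
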