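#' Two-condition driver discovery pipeline
#'
#' Runs the full multi-sample analysis: restricts the reference network to
#' expressed genes, builds the differential co-expression network at `alpha`,
#' computes the significance/degree node weights at `gamma`, and solves the
#' weighted minimum dominating set.
#'
#' @param expr1,expr2 Genes-by-samples expression matrices for the two
#'   conditions.
#' @param reference An `igraph` reference network; its largest connected
#'   component is used.
#' @param alpha Edge significance threshold (default 0.05).
#' @param gamma Node-weight exponent (default 0.01).
#' @param mode Solver mode, `"exact"` or `"greedy"`.
#' @param time_limit Solver time limit in seconds.
#' @return A list with `network` (the [differential_network]) and `solution`
#'   (the `driver_solution`).
#' @export
find_drivers <- function(expr1, expr2, reference, alpha = 0.05, gamma = 0.01,
                         mode = c("exact", "greedy"), time_limit = 600) {
  mode <- match.arg(mode)
  reference <- largest_connected_component(reference)
  dnet <- build_differential_network(expr1, expr2, reference, alpha = alpha)
  sol <- solve_wmds(dnet, mode = mode, time_limit = time_limit, gamma = gamma)
  list(network = dnet, solution = sol)
}

#' Personalized driver discovery pipeline
#'
#' Builds one perturbation network per tumor sample against the normal
#' cohort, solves the weighted minimum dominating set per patient, and
#' aggregates cohort-level driver frequencies.
#'
#' @param normal_expr Genes-by-samples matrix of the normal cohort.
#' @param tumor_expr Genes-by-samples matrix with one column per patient.
#' @param reference An `igraph` reference network; its largest connected
#'   component is used.
#' @param alpha Edge significance threshold (default 0.05).
#' @param gamma Node-weight exponent (default 0.01).
#' @param merge_threshold Cohort merge frequency (default 0.5, inclusive).
#' @param time_limit Per-patient solver time limit in seconds.
#' @return A list with `profiles` (a `patient_driver_profiles`), `merged`
#'   (the cohort-level gene list) and `frequency` (gene/frequency/bin table).
#' @export
find_personalized_drivers <- function(normal_expr, tumor_expr, reference,
                                      alpha = 0.05, gamma = 0.01,
                                      merge_threshold = 0.5,
                                      time_limit = 600) {
  reference <- largest_connected_component(reference)
  patients <- colnames(tumor_expr)
  if (is.null(patients)) {
    patients <- sprintf("patient%03d", seq_len(ncol(tumor_expr)))
  }
  nets <- lapply(seq_along(patients), function(i) {
    build_personalized_network(normal_expr, tumor_expr[, i, drop = FALSE],
                               reference, alpha = alpha)
  })
  names(nets) <- patients
  prof <- personalized_drivers(nets, gamma = gamma, time_limit = time_limit)
  agg <- aggregate_personalized(prof, merge_threshold = merge_threshold)
  list(profiles = prof, merged = agg$genes, frequency = agg$frequency)
}
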