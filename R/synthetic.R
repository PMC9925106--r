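#' Define a synthetic two-condition scenario with planted driver hubs
#'
#' Describes a fully self-contained test scenario: a scale-free reference
#' network, a block-correlation expression model, and a set of "rewired"
#' blocks whose within-block correlation changes between the two conditions.
#' Each rewired block is built around a high-degree hub of the reference
#' network (the hub plus its `block_size - 1` highest-degree neighbors); the
#' hub is the planted driver of that block. The remaining genes are grouped
#' into background blocks whose correlation is identical in both conditions,
#' so their edges carry no differential signal.
#'
#' Defaults describe the package's standard validation scenario: 500 genes,
#' a preferential-attachment reference with 2 edges per new node, 5 rewired
#' blocks of size 8 whose correlation drops from 0.8 to 0, background
#' co-expression 0.4, and 100 samples per condition.
#'
#' @param n_genes Number of genes (>= 10).
#' @param attach_edges Preferential-attachment edges per new node.
#' @param n_blocks Number of rewired (driver) blocks.
#' @param block_size Genes per rewired block (hub plus neighbors).
#' @param rho_block Within-block correlation of rewired blocks in condition 1.
#' @param rho_rewired Within-block correlation of rewired blocks in
#'   condition 2 (default 0: the block's co-expression is destroyed).
#' @param rho_background Within-block correlation of background blocks, the
#'   same in both conditions.
#' @param n1,n2 Samples per condition.
#' @param seed Integer seed governing both network generation and sampling.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_genes = 500, attach_edges = 2, n_blocks = 5,
                               block_size = 8, rho_block = 0.8,
                               rho_rewired = 0, rho_background = 0.4,
                               n1 = 100, n2 = 100, seed = 1) {
  if (n_genes < 10) stop("n_genes must be at least 10")
  rhos <- c(rho_block, rho_rewired, rho_background)
  if (any(rhos < 0 | rhos >= 1)) {
    stop("correlations must be in [0, 1) for the block factor model")
  }
  if (n_blocks * block_size > n_genes / 2) {
    stop("rewired blocks would cover more than half the genes")
  }
  structure(list(n_genes = n_genes, attach_edges = attach_edges,
                 n_blocks = n_blocks, block_size = block_size,
                 rho_block = rho_block, rho_rewired = rho_rewired,
                 rho_background = rho_background,
                 n1 = n1, n2 = n2, seed = seed),
            class = "synthetic_scenario")
}

#' Generate a scale-free reference network
#'
#' Preferential-attachment (Barabasi-Albert) graph: connected, with a heavy
#' right tail of hub degrees, mimicking gene-interaction reference networks.
#' Vertices are named `g0001`, `g0002`, ...
#'
#' @param n_genes Number of nodes (>= 10).
#' @param attach_edges Edges added per new node.
#' @param seed Integer seed (generation is reproducible).
#' @return An `igraph` graph.
#' @export
generate_reference <- function(n_genes, attach_edges = 2, seed = 1) {
  if (n_genes < 10) stop("n_genes must be at least 10")
  set.seed(seed)
  g <- igraph::sample_pa(n_genes, power = 1, m = attach_edges,
                         directed = FALSE)
  igraph::V(g)$name <- sprintf("g%04d", seq_len(n_genes))
  g
}

#' Generate paired two-condition expression matrices with planted drivers
#'
#' Samples both conditions from a block-factor Gaussian model: gene `g` in
#' block `b` with correlation `rho` is `sqrt(rho) * F_b + sqrt(1 - rho) * e`,
#' giving exact compound symmetry within blocks and independence across
#' blocks (the implied covariance is positive definite by construction).
#' Rewired blocks use `rho_block` in condition 1 and `rho_rewired` in
#' condition 2; background blocks use `rho_background` in both. Each matrix
#' is shifted by its minimum so all values are non-negative, which leaves
#' every Pearson correlation unchanged.
#'
#' @param scenario A [synthetic_scenario].
#' @return A list with `reference` (the `igraph` network), `expr1`, `expr2`
#'   (genes-by-samples matrices) and `truth`: list with `drivers` (planted
#'   hub genes), `blocks` (list of rewired block gene sets), `rewired_edges`
#'   (data.frame of reference edges inside rewired blocks) and
#'   `block_assignment` (named vector gene -> block label).
#' @export
generate_expression_pair <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  ref <- generate_reference(sc$n_genes, sc$attach_edges, sc$seed)
  layout <- plant_blocks(ref, sc)
  set.seed(sc$seed + 1L)
  expr1 <- sample_block_expression(layout$assignment, layout$rho1, sc$n1, "n")
  expr2 <- sample_block_expression(layout$assignment, layout$rho2, sc$n2, "t")
  expr1 <- expr1 - min(expr1)
  expr2 <- expr2 - min(expr2)
  list(reference = ref, expr1 = expr1, expr2 = expr2,
       truth = list(drivers = layout$drivers, blocks = layout$blocks,
                    rewired_edges = layout$rewired_edges,
                    block_assignment = layout$assignment))
}

#' Generate a normal cohort plus perturbed single tumor samples
#'
#' The normal cohort is drawn from the condition-1 model of the scenario.
#' Each tumor sample is drawn from the same model except that in its
#' perturbed blocks the block factor is replaced by independent noise
#' (`rho_rewired`). A fraction of the scenario's rewired blocks is shared by
#' every patient; the remaining blocks are private, assigned to single
#' patients in rotation, so the planted hubs of shared blocks should be
#' recovered at frequency about 1 and those of private blocks at frequency
#' about `1 / n_patients`.
#'
#' @param scenario A [synthetic_scenario]; its `n1` is the normal cohort size.
#' @param n_patients Number of tumor samples (>= 1).
#' @param perturbed_fraction Fraction of the rewired blocks shared by all
#'   patients (0 = all private, 1 = all shared).
#' @return A list with `reference`, `normal_expr`, `tumor_expr` (one column
#'   per patient) and `truth`: `drivers` per block, `shared_blocks`,
#'   `patient_blocks` (list: blocks perturbed in each patient) and
#'   `patient_drivers` (list: planted hubs perturbed in each patient).
#' @export
generate_cohort <- function(scenario, n_patients, perturbed_fraction = 1) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (n_patients < 1) stop("need at least one patient")
  if (perturbed_fraction < 0 || perturbed_fraction > 1) {
    stop("perturbed_fraction must be in [0, 1]")
  }
  sc <- scenario
  ref <- generate_reference(sc$n_genes, sc$attach_edges, sc$seed)
  layout <- plant_blocks(ref, sc)
  nb <- length(layout$blocks)
  n_shared <- round(perturbed_fraction * nb)
  shared <- seq_len(n_shared)
  private <- setdiff(seq_len(nb), shared)

  set.seed(sc$seed + 2L)
  normal <- sample_block_expression(layout$assignment, layout$rho1, sc$n1, "n")

  patients <- sprintf("patient%03d", seq_len(n_patients))
  patient_blocks <- vector("list", n_patients)
  names(patient_blocks) <- patients
  tumor <- matrix(NA_real_, nrow = sc$n_genes, ncol = n_patients,
                  dimnames = list(names(layout$assignment), patients))
  for (i in seq_len(n_patients)) {
    mine <- shared
    if (length(private) > 0) {
      mine <- c(mine, private[(i - 1) %% length(private) + 1])
    }
    patient_blocks[[i]] <- mine
    rho <- layout$rho1
    for (b in mine) {
      rho[layout$assignment == paste0("driver", b)] <- sc$rho_rewired
    }
    tumor[, i] <- sample_block_expression(layout$assignment, rho, 1, "p")[, 1]
  }
  # one common shift keeps tumor samples exchangeable with normals
  shift <- min(min(normal), min(tumor))
  normal <- normal - shift
  tumor <- tumor - shift

  list(reference = ref, normal_expr = normal, tumor_expr = tumor,
       truth = list(drivers = layout$drivers,
                    shared_blocks = shared,
                    patient_blocks = patient_blocks,
                    patient_drivers = lapply(patient_blocks, function(b) {
                      layout$drivers[b]
                    })))
}

# Choose rewired blocks around high-degree hubs and assign every gene to a
# block. Returns per-gene condition correlations and the planted truth.
plant_blocks <- function(ref, sc) {
  deg <- igraph::degree(ref)
  genes <- igraph::V(ref)$name
  ord <- order(-deg, genes)
  assignment <- stats::setNames(rep(NA_character_, length(genes)), genes)
  drivers <- character(0)
  blocks <- list()
  used <- character(0)
  for (cand in genes[ord]) {
    if (length(blocks) == sc$n_blocks) break
    if (cand %in% used) next
    nbrs <- igraph::V(ref)$name[igraph::neighbors(ref, cand)]
    nbrs <- setdiff(nbrs, used)
    if (length(nbrs) < sc$block_size - 1) next
    nbrs <- nbrs[order(-deg[nbrs], nbrs)][seq_len(sc$block_size - 1)]
    members <- c(cand, nbrs)
    b <- length(blocks) + 1L
    assignment[members] <- paste0("driver", b)
    blocks[[b]] <- sort(members)
    drivers <- c(drivers, cand)
    used <- c(used, members)
  }
  if (length(blocks) < sc$n_blocks) {
    stop("could not place ", sc$n_blocks, " disjoint blocks of size ",
         sc$block_size, "; use a denser or larger reference network")
  }
  rest <- genes[is.na(assignment)]
  assignment[rest] <- paste0("bg",
                             ceiling(seq_along(rest) / sc$block_size))
  rho1 <- ifelse(startsWith(assignment, "driver"),
                 sc$rho_block, sc$rho_background)
  rho2 <- ifelse(startsWith(assignment, "driver"),
                 sc$rho_rewired, sc$rho_background)
  names(rho1) <- names(rho2) <- genes

  el <- igraph::as_edgelist(ref)
  inside <- assignment[el[, 1]] == assignment[el[, 2]] &
    startsWith(assignment[el[, 1]], "driver")
  rewired_edges <- data.frame(gene_i = pmin(el[inside, 1], el[inside, 2]),
                              gene_j = pmax(el[inside, 1], el[inside, 2]),
                              stringsAsFactors = FALSE)
  list(assignment = assignment, rho1 = rho1, rho2 = rho2,
       drivers = sort(drivers), blocks = blocks,
       rewired_edges = rewired_edges)
}

# Draw n samples from the block factor model (zero-mean Gaussian; callers
# apply a location shift for non-negativity, which leaves correlations
# unchanged). assignment: gene -> block label; rho: per-gene within-block
# correlation.
sample_block_expression <- function(assignment, rho, n, sample_prefix) {
  genes <- names(assignment)
  blocks <- unique(assignment)
  fac <- matrix(stats::rnorm(length(blocks) * n), nrow = length(blocks),
                dimnames = list(blocks, NULL))
  eps <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes))
  x <- sqrt(rho) * fac[assignment, , drop = FALSE] + sqrt(1 - rho) * eps
  dimnames(x) <- list(genes,
                      sprintf("%s%03d", sample_prefix, seq_len(n)))
  x
}
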