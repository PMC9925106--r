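#' Read an undirected gene-interaction network from an edge list
#'
#' Reads a two-column tab-separated edge list (or a three-column SIF file,
#' whose middle interaction-type column is ignored) into a simple undirected
#' [igraph][igraph::igraph-package] graph over gene symbols. Duplicate rows,
#' reversed duplicates and self-loops are collapsed/dropped; counts of both
#' are reported via [message()].
#'
#' @param path Path to the file. Lines starting with `comment` are skipped.
#' @param delimiter Field separator (default tab).
#' @param header Logical; if `TRUE` the first non-comment line is skipped.
#' @param format `"auto"` infers from the column count (2 = edge list,
#'   3 = SIF); `"edgelist"` requires exactly two columns and errors otherwise;
#'   `"sif"` requires exactly three.
#' @param comment Prefix marking comment lines.
#' @param normalize_case If `TRUE`, gene symbols are upper-cased.
#' @return An undirected simple `igraph` graph whose vertices are gene symbols.
#' @export
read_edge_list <- function(path, delimiter = "\t", header = FALSE,
                           format = c("auto", "edgelist", "sif"),
                           comment = "#", normalize_case = FALSE) {
  format <- match.arg(format)
  lines <- read_data_lines(path, comment)
  if (header) lines <- lines[-1]
  if (length(lines) == 0L) stop("no edge rows in '", path, "'")
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  ncols <- lengths(fields)
  expected <- switch(format,
    auto = ncols[1],
    edgelist = 2L,
    sif = 3L
  )
  if (format == "auto" && !expected %in% c(2L, 3L)) {
    stop("expected 2 or 3 columns, found ", expected, " at line 1")
  }
  bad <- which(ncols != expected)
  if (length(bad) > 0L) {
    stop("malformed row at line ", bad[1], ": expected ", expected,
         " fields, found ", ncols[bad[1]])
  }
  from <- trimws(vapply(fields, `[`, "", 1L))
  to <- trimws(vapply(fields, `[`, "", expected))
  if (normalize_case) {
    from <- toupper(from)
    to <- toupper(to)
  }
  if (any(from == "" | to == "")) {
    stop("empty gene symbol at line ", which(from == "" | to == "")[1])
  }
  self <- from == to
  if (any(self)) {
    message("dropped ", sum(self), " self-loop(s)")
    from <- from[!self]
    to <- to[!self]
  }
  if (length(from) == 0L) stop("no edges left after dropping self-loops")
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  ndup <- igraph::gsize(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  ndup <- ndup - igraph::gsize(g)
  if (ndup > 0) message("collapsed ", ndup, " duplicate edge(s)")
  g
}

#' Read a genes-by-samples expression matrix
#'
#' Parses a tab-separated file with gene identifiers in the first column and a
#' sample-name header row. Values must be finite, numeric and non-negative
#' (e.g. FPKM); violations are reported with their coordinates.
#'
#' @param path Path to the TSV file.
#' @param comment Prefix marking comment lines.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, comment = "#") {
  lines <- read_data_lines(path, comment)
  if (length(lines) < 2L) stop("expression file '", path, "' has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  samples <- trimws(fields[[1]][-1])
  if (length(samples) == 0L) stop("no sample columns in '", path, "'")
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ", samples[duplicated(samples)][1])
  }
  body <- fields[-1]
  nf <- lengths(body)
  bad <- which(nf != length(samples) + 1L)
  if (length(bad) > 0L) {
    stop("malformed row at line ", bad[1] + 1L, ": expected ",
         length(samples) + 1L, " fields, found ", nf[bad[1]])
  }
  genes <- trimws(vapply(body, `[`, "", 1L))
  if (anyDuplicated(genes)) {
    stop("duplicate gene id: ", genes[duplicated(genes)][1])
  }
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop("non-numeric value '", body[[i]][j + 1L], "' at gene '", genes[i],
           "', sample '", samples[j], "'")
    }
    vals[i, ] <- v
  }
  if (any(!is.finite(vals))) stop("non-finite expression value present")
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value at gene '", genes[idx[1]], "', sample '",
         samples[idx[2]], "'")
  }
  vals
}

#' Read a gene list (one symbol per line)
#'
#' @param path Path to a plain-text file, one gene symbol per line.
#' @param name Label for the list (defaults to the file name).
#' @param normalize_case If `TRUE`, symbols are upper-cased before
#'   de-duplication.
#' @return A character vector of unique gene symbols with attribute `name`.
#' @export
read_gene_list <- function(path, name = basename(path), normalize_case = FALSE) {
  lines <- trimws(read_data_lines(path, "#", allow_empty = TRUE))
  genes <- lines[lines != ""]
  if (normalize_case) genes <- toupper(genes)
  genes <- genes[!duplicated(genes)]
  attr(genes, "name") <- name
  genes
}

#' Read a somatic mutation table
#'
#' Two-column TSV of (gene symbol, sample id) records, one row per mutated
#' gene per sample.
#'
#' @param path Path to the TSV file.
#' @param total_samples Total number of tumor samples in the cohort;
#'   defaults to the number of distinct sample ids in the table. Must be at
#'   least that number.
#' @return A list with `records` (data.frame gene/sample) and `total_samples`.
#' @export
read_mutation_table <- function(path, total_samples = NULL) {
  lines <- read_data_lines(path, "#")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("malformed mutation row at line ", which(lengths(fields) < 2L)[1])
  }
  rec <- data.frame(gene = trimws(vapply(fields, `[`, "", 1L)),
                    sample = trimws(vapply(fields, `[`, "", 2L)),
                    stringsAsFactors = FALSE)
  nseen <- length(unique(rec$sample))
  if (is.null(total_samples)) total_samples <- nseen
  if (total_samples < nseen) {
    stop("total_samples (", total_samples, ") is smaller than the number of ",
         "distinct sample ids (", nseen, ")")
  }
  list(records = rec, total_samples = total_samples)
}

#' Largest connected component of a network
#'
#' Returns the induced subgraph on the connected component with the most
#' nodes. Ties are broken deterministically in favor of the component whose
#' sorted node-label vector is lexicographically smallest, so the result does
#' not depend on vertex order in the input.
#'
#' @param net An `igraph` graph.
#' @return The induced subgraph on the node-richest component.
#' @export
largest_connected_component <- function(net) {
  if (!igraph::is_igraph(net) || igraph::vcount(net) == 0L) {
    stop("empty network")
  }
  comp <- igraph::components(net)
  winners <- which(comp$csize == max(comp$csize))
  if (length(winners) > 1L) {
    labs <- lapply(winners, function(k) {
      sort(igraph::V(net)$name[comp$membership == k])
    })
    ord <- order(vapply(labs, paste, "", collapse = "\r"))
    winners <- winners[ord[1]]
  }
  removed <- sum(comp$membership != winners)
  if (removed > 0) {
    message("removed ", removed, " node(s) outside the largest component")
  }
  igraph::induced_subgraph(net, which(comp$membership == winners))
}

#' Restrict a reference network to genes with expression data
#'
#' Genes present in the reference network but absent from (either) expression
#' matrix have uncomputable edge correlations and are removed before analysis.
#'
#' @param net An `igraph` reference network.
#' @param genes Character vector of genes with expression data.
#' @return The induced subgraph on `intersect(V(net), genes)`.
#' @export
restrict_to_expressed <- function(net, genes) {
  keep <- intersect(igraph::V(net)$name, genes)
  removed <- igraph::vcount(net) - length(keep)
  if (removed > 0) {
    message("removed ", removed, " network gene(s) without expression data")
  }
  if (length(keep) == 0L) stop("no network genes have expression data")
  igraph::induced_subgraph(net, keep)
}

#' Write a driver report (TSV plus JSON sidecar)
#'
#' Writes one row per network gene with its weight, differential-network
#' degree and a 0/1 driver-set membership flag, plus a `<path>.json` sidecar
#' recording the objective value, gamma, solver status, seed and package
#' version.
#'
#' @param solution A [driver_solution] as returned by [solve_wmds()].
#' @param network The differential network (a [differential_network] or an
#'   `igraph`) the solution was computed on; supplies degrees. May be `NULL`
#'   for solutions on bare graphs, in which case only selected genes are
#'   written.
#' @param path Output TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @param seed Optional seed to record in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_driver_report <- function(solution, network = NULL, path, seed = NULL) {
  stopifnot(inherits(solution, "driver_solution"))
  g <- if (inherits(network, "differential_network")) network$graph else network
  if (is.null(g)) {
    genes <- sort(solution$genes)
    df <- data.frame(gene = genes,
                     weight = unname(solution$weights[genes]),
                     degree = rep(NA_integer_, length(genes)),
                     driver = rep(1L, length(genes)),
                     stringsAsFactors = FALSE)
  } else {
    genes <- sort(igraph::V(g)$name)
    deg <- igraph::degree(g)[genes]
    w <- solution$weights[genes]
    df <- data.frame(gene = genes, weight = unname(w), degree = unname(deg),
                     driver = as.integer(genes %in% solution$genes),
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(objective = solution$objective,
                  cardinality = solution$cardinality,
                  gamma = solution$gamma,
                  status = solution$status,
                  seed = seed,
                  package_version = as.character(utils::packageVersion("wmds")))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a driver report written by [write_driver_report()]
#'
#' @param path Path to the report TSV.
#' @return A list with `table` (the full data.frame), `genes` (the driver
#'   set) and `meta` (the parsed JSON sidecar, if present).
#' @export
read_driver_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta <- NULL
  if (file.exists(paste0(path, ".json"))) {
    meta <- jsonlite::read_json(paste0(path, ".json"))
  }
  list(table = df, genes = df$gene[df$driver == 1L], meta = meta)
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as a two-column edge list
#'
#' Endpoints within an edge, and edges, are written in sorted order so the
#' output is canonical regardless of the in-memory vertex ordering.
#'
#' @param net An `igraph` graph.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) > 0) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, 2:1]
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a network with attributes to GraphML
#'
#' @param net An `igraph` graph (possibly carrying edge/vertex attributes).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

# Read non-comment lines from a text file; shared input plumbing.
read_data_lines <- function(path, comment = "#", allow_empty = FALSE) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  if (nzchar(comment)) lines <- lines[!startsWith(lines, comment)]
  if (!allow_empty) lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L && !allow_empty) stop("file '", path, "' is empty")
  lines
}
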