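#' Precision and recall of a predicted gene list against a benchmark
#'
#' Duplicates and ordering in either list are ignored. An empty prediction
#' has precision 0 by convention (so cohort sweeps never fail); the recall
#' denominator is the full benchmark list.
#'
#' @param predicted Character vector of predicted genes.
#' @param benchmark Character vector of benchmark genes (non-empty).
#' @param restrict_to Optional gene universe (e.g. the analyzed network's
#'   genes); when given, the benchmark is intersected with it first.
#' @return A list with `tp`, `precision`, `recall`, `n_predicted`,
#'   `n_benchmark`.
#' @export
precision_recall <- function(predicted, benchmark, restrict_to = NULL) {
  benchmark <- unique(benchmark)
  if (!is.null(restrict_to)) benchmark <- intersect(benchmark, restrict_to)
  if (length(benchmark) == 0L) stop("benchmark gene list is empty")
  predicted <- unique(predicted)
  tp <- length(intersect(predicted, benchmark))
  list(tp = tp,
       precision = if (length(predicted) > 0) tp / length(predicted) else 0,
       recall = tp / length(benchmark),
       n_predicted = length(predicted),
       n_benchmark = length(benchmark))
}

#' F-beta measure
#'
#' Weighted harmonic mean of precision and recall,
#' `F = (1 + beta^2) * P * R / (beta^2 * P + R)`, parameterized directly by
#' `beta_squared`; `beta_squared < 1` weights precision above recall
#' (default 0.2), and `beta_squared = 1` is the classical F1. Defined as 0
#' when both precision and recall are 0.
#'
#' @param precision,recall Values in `[0, 1]` (vectorized).
#' @param beta_squared Positive weight parameter (default 0.2).
#' @return The F measure.
#' @export
f_beta <- function(precision, recall, beta_squared = 0.2) {
  if (beta_squared <= 0) stop("beta_squared must be positive")
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1)) {
    stop("precision and recall must be in [0, 1]")
  }
  denom <- beta_squared * precision + recall
  ifelse(denom > 0, (1 + beta_squared) * precision * recall / denom, 0)
}

#' Evaluate a predicted driver list against a benchmark
#'
#' Convenience wrapper combining [precision_recall()] and [f_beta()];
#' reports both the precision-weighted F (default `beta_squared = 0.2`) and
#' the classical F1.
#'
#' @inheritParams precision_recall
#' @param beta_squared Weight parameter for the primary F measure.
#' @return A one-row data.frame with `n_predicted`, `n_benchmark`, `tp`,
#'   `precision`, `recall`, `f_beta`, `f1`.
#' @export
evaluate_drivers <- function(predicted, benchmark, beta_squared = 0.2,
                             restrict_to = NULL) {
  pr <- precision_recall(predicted, benchmark, restrict_to)
  data.frame(n_predicted = pr$n_predicted, n_benchmark = pr$n_benchmark,
             tp = pr$tp, precision = pr$precision, recall = pr$recall,
             f_beta = f_beta(pr$precision, pr$recall, beta_squared),
             f1 = f_beta(pr$precision, pr$recall, 1))
}

#' Equalizing beta-squared for the two worst-case predictions
#'
#' Finds the `beta_squared` at which the F measure of predicting the whole
#' genome (precision `benchmark_size / genome_size`, recall 1) equals the F
#' measure of a minimal all-correct prediction (precision 1, recall
#' `minimal_predictions / benchmark_size`). Setting `F(P1, 1) = F(1, R2)`
#' and solving gives the closed form
#' `beta^2 = R2 * (1 - P1) / (P1 * (1 - R2))`.
#'
#' @param genome_size Number of genes in the genome (e.g. 25000).
#' @param benchmark_size Size of the benchmark driver list (e.g. 616).
#' @param minimal_predictions Size of the minimal all-correct prediction
#'   (e.g. 3); must not exceed `benchmark_size`.
#' @return The equalizing `beta_squared`.
#' @export
equalizing_beta_squared <- function(genome_size, benchmark_size,
                                    minimal_predictions) {
  if (genome_size <= 0 || benchmark_size <= 0 || minimal_predictions <= 0) {
    stop("all arguments must be positive")
  }
  if (minimal_predictions > benchmark_size) {
    stop("minimal_predictions cannot exceed benchmark_size")
  }
  p1 <- benchmark_size / genome_size
  r2 <- minimal_predictions / benchmark_size
  if (p1 >= 1) stop("degenerate case: benchmark covers the whole genome")
  r2 * (1 - p1) / (p1 * (1 - r2))
}

#' Classify predicted drivers by somatic mutation frequency
#'
#' Per-gene mutation frequency is the number of distinct mutated samples
#' divided by the total tumor sample count; genes absent from the table get
#' frequency 0. Genes are classed `low` or `high` around the cutoff
#' (default 0.05); a frequency exactly at the cutoff is classed `low`.
#'
#' @param predicted Character vector of predicted driver genes.
#' @param mutations A mutation table as returned by [read_mutation_table()]
#'   (list with `records` and `total_samples`).
#' @param cutoff Frequency cutoff (default 0.05).
#' @return A data.frame with `gene`, `frequency` and `class`.
#' @export
mutation_frequency_classify <- function(predicted, mutations, cutoff = 0.05) {
  stopifnot(is.list(mutations), !is.null(mutations$records))
  total <- mutations$total_samples
  if (is.null(total) || total < 1) stop("total tumor sample count must be >= 1")
  rec <- unique(mutations$records[, c("gene", "sample")])
  counts <- table(rec$gene)
  predicted <- unique(predicted)
  f <- as.numeric(counts[predicted])
  f[is.na(f)] <- 0
  f <- f / total
  data.frame(gene = predicted, frequency = f,
             class = ifelse(f > cutoff, "high", "low"),
             stringsAsFactors = FALSE)
}
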