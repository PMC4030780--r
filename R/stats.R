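#' Cohort-statistics configuration
#'
#' @param expected_synonymous_fraction Expected fraction of coding/splicing
#'   de novo events that are synonymous under neutrality (default 0.29).
#' @param exome_coding_size Total coding target in bp (default 30 Mb).
#' @param n_genes_for_bonferroni Number of genes tested genome-wide
#'   (default 20,000; alpha / n gives the all-genes threshold).
#' @param alpha Significance level (default 0.05).
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(expected_synonymous_fraction = 0.29,
                         exome_coding_size = 3e7,
                         n_genes_for_bonferroni = 20000,
                         alpha = 0.05) {
  stopifnot(expected_synonymous_fraction >= 0,
            expected_synonymous_fraction <= 1,
            exome_coding_size > 0, n_genes_for_bonferroni > 0,
            alpha > 0, alpha <= 1)
  structure(list(expected_synonymous_fraction = expected_synonymous_fraction,
                 exome_coding_size = exome_coding_size,
                 n_genes_for_bonferroni = n_genes_for_bonferroni,
                 alpha = alpha),
            class = "stats_config")
}

#' Synonymous-depletion test among independent de novo events
#'
#' Under neutrality a fraction `p` of coding/splicing de novo events is
#' synonymous. Observing unexpectedly few synonymous events (equivalently,
#' an excess of functional events) suggests selection of pathogenic events
#' into the cohort. The test is the exact one-sided lower binomial tail:
#' `sum_{i=0..k} C(n,i) p^i (1-p)^(n-i)` with `n` independent events and `k`
#' synonymous — an exact summation, no approximation.
#'
#' @param n_independent Number of independent de novo events.
#' @param n_synonymous Number of them that are synonymous.
#' @param config A [stats_config()] (supplies `p`).
#' @return The lower-tail probability.
#' @export
synonymous_enrichment_test <- function(n_independent, n_synonymous,
                                       config = stats_config()) {
  if (n_independent < 0 || n_synonymous < 0 || n_synonymous > n_independent) {
    stop("need 0 <= n_synonymous <= n_independent")
  }
  sum(dbinom(0:n_synonymous, n_independent,
             config$expected_synonymous_fraction))
}

#' Probability of recurrent functional de novo events in one gene
#'
#' Under a uniform mutation-rate-per-bp model, each of `n` functional de
#' novo events falls in a gene of coding length `L` with probability
#' `L / exome_coding_size`; the number of hits is approximately Poisson with
#' `lambda = n * L / exome_coding_size`, and the probability of two or more
#' hits by chance is `1 - (1 + lambda) * exp(-lambda)`. Returned alongside
#' the Bonferroni threshold `alpha / n_genes_for_bonferroni` for testing all
#' genes.
#'
#' @param gene_coding_length Coding length of the gene in bp.
#' @param n_functional_denovos Number of functional de novo events in the
#'   cohort.
#' @param config A [stats_config()].
#' @return List with `p_recurrent`, `lambda` and `bonferroni_threshold`.
#' @export
recurrent_gene_probability <- function(gene_coding_length,
                                       n_functional_denovos,
                                       config = stats_config()) {
  if (config$exome_coding_size <= 0) stop("exome size must be positive")
  if (gene_coding_length > config$exome_coding_size) {
    stop("gene length exceeds exome size")
  }
  if (n_functional_denovos < 0 || gene_coding_length < 0) {
    stop("counts and lengths must be non-negative")
  }
  lambda <- n_functional_denovos * gene_coding_length / config$exome_coding_size
  list(p_recurrent = 1 - (1 + lambda) * exp(-lambda),
       lambda = lambda,
       bonferroni_threshold = config$alpha / config$n_genes_for_bonferroni)
}

#' Per-proband candidate-count summary
#'
#' @param per_proband_counts Integer vector, one count per analyzed proband.
#' @return List `mean` (arithmetic mean to 2 decimals), `min`, `max`.
#' @export
candidate_count_summary <- function(per_proband_counts) {
  if (length(per_proband_counts) == 0) stop("no probands: summary undefined")
  if (any(per_proband_counts < 0)) stop("counts must be non-negative")
  list(mean = round_half_up(mean(per_proband_counts), 2),
       min = min(per_proband_counts), max = max(per_proband_counts))
}
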