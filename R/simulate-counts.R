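#' Simulate a paired protrusion/cell-body count experiment
#'
#' Generates a gene-by-sample negative-binomial count matrix emulating a
#' fractionation RNA-Seq design: protrusion (Ps) and cell-body (CB)
#' fractions, each with `n_replicates` replicates, in two conditions
#' (control and perturbed). A planted subset of genes is Ps-enriched by
#' `true_log2fc` in both conditions; a planted subset of those
#' ("dependent" genes) has its enrichment attenuated in the perturbed
#' condition, emulating RNAs whose protrusion localization depends on the
#' perturbed factor. Gene baselines are drawn log-normally and library
#' sizes vary log-normally per sample.
#'
#' With `nb_dispersion = 0` counts are Poisson; with
#' `libsize_log2_sd = 0` all samples share a size factor of 1.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per fraction per condition (at least 2
#'   for downstream testing).
#' @param n_enriched Number of planted Ps-enriched genes.
#' @param n_dependent Number of those whose enrichment is attenuated in
#'   the perturbed condition (`n_dependent <= n_enriched`).
#' @param true_log2fc True Ps/CB log2 fold change of enriched genes.
#' @param dependence_attenuation Multiplier in `[0, 1]` applied to the
#'   *loss* of enrichment: dependent genes have
#'   `true_log2fc * (1 - dependence_attenuation)` in the perturbed
#'   condition; `1` removes enrichment entirely.
#' @param baseline_log2_mean,baseline_log2_sd Log2-normal parameters of
#'   gene baseline expected counts (CB fraction, size factor 1).
#' @param nb_dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param libsize_log2_sd Log2 standard deviation of per-sample size
#'   factors.
#' @param conditions Length-2 character: control then perturbed condition
#'   labels.
#' @param seed Integer seed; the generator uses its own RNG stream.
#'
#' @return A list with `counts` (integer matrix, genes x samples, row and
#'   column names set), `sample_info` (tibble: sample, fraction,
#'   condition, replicate), and `truth` (tibble: gene, status in
#'   non_localized / enriched_independent / enriched_dependent, and the
#'   true log2 fold change in each condition).
#' @export
#' @examples
#' sim <- simulate_ps_cb_counts(n_genes = 200, n_enriched = 20,
#'                              n_dependent = 10, seed = 1)
#' table(sim$truth$status)
simulate_ps_cb_counts <- function(n_genes = 2000, n_replicates = 4,
                                  n_enriched = 100, n_dependent = 50,
                                  true_log2fc = 2, dependence_attenuation = 1,
                                  baseline_log2_mean = 6, baseline_log2_sd = 2,
                                  nb_dispersion = 0.05, libsize_log2_sd = 0.2,
                                  conditions = c("control", "perturbed"),
                                  seed = 1L) {
  stopifnot(
    n_genes >= 1, n_replicates >= 1,
    n_enriched >= 0, n_dependent >= 0,
    n_dependent <= n_enriched, n_enriched <= n_genes,
    dependence_attenuation >= 0, dependence_attenuation <= 1,
    baseline_log2_sd > 0, nb_dispersion >= 0, libsize_log2_sd >= 0,
    length(conditions) == 2, !anyDuplicated(conditions)
  )
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  status <- rep("non_localized", n_genes)
  if (n_enriched > 0) {
    status[seq_len(n_enriched)] <- "enriched_independent"
    if (n_dependent > 0) status[seq_len(n_dependent)] <- "enriched_dependent"
  }
  lfc_ctrl <- ifelse(status == "non_localized", 0, true_log2fc)
  lfc_pert <- dplyr::case_when(
    status == "enriched_dependent" ~ true_log2fc * (1 - dependence_attenuation),
    status == "enriched_independent" ~ true_log2fc,
    .default = 0
  )
  info <- tidyr::expand_grid(
    condition = conditions, fraction = c("Ps", "CB"),
    replicate = seq_len(n_replicates)
  )
  info$sample <- sprintf("%s_%s_r%d", info$condition, info$fraction,
                         info$replicate)
  info <- tibble::as_tibble(info[, c("sample", "fraction", "condition",
                                     "replicate")])

  counts <- withr::with_seed(seed, {
    baseline <- 2^rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
    size_factor <- 2^rnorm(nrow(info), 0, libsize_log2_sd)
    mat <- matrix(0L, n_genes, nrow(info),
                  dimnames = list(genes, info$sample))
    for (j in seq_len(nrow(info))) {
      lfc <- if (info$condition[j] == conditions[2]) lfc_pert else lfc_ctrl
      mu <- baseline * size_factor[j] *
        (if (info$fraction[j] == "Ps") 2^lfc else 1)
      mat[, j] <- if (nb_dispersion == 0) {
        rpois(n_genes, mu)
      } else {
        rnbinom(n_genes, mu = mu, size = 1 / nb_dispersion)
      }
    }
    mat
  })

  truth <- tibble::tibble(
    gene = genes, status = status,
    true_log2fc_control = lfc_ctrl, true_log2fc_perturbed = lfc_pert
  )
  list(counts = counts, sample_info = info, truth = truth)
}
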