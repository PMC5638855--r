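#' Coerce counts to a gene-by-sample integer matrix
#'
#' Accepts either a numeric matrix with gene row names or a data frame
#' whose first column holds gene identifiers (the TSV layout used
#' throughout: one gene per row, one sample per column).
#'
#' @param counts Matrix or data frame of nonnegative counts.
#' @return Numeric matrix with gene row names.
#' @export
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    genes <- as.character(counts[[1]])
    mat <- as.matrix(counts[, -1, drop = FALSE])
    rownames(mat) <- genes
    counts <- mat
  }
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix or a data frame with a gene id column",
          class = "periloc_invalid_counts")
  }
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    abort("gene identifiers must be present and unique",
          class = "periloc_invalid_counts")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("sample identifiers must be unique", class = "periloc_invalid_counts")
  }
  if (anyNA(counts) || any(counts < 0) || any(!is.finite(counts))) {
    abort("counts must be finite and nonnegative",
          class = "periloc_invalid_counts")
  }
  counts
}

#' Log counts per million
#'
#' `log2((count + prior_count) / (library_size + 2 * prior_count) * 1e6)`
#' per cell, where the library size is the column total. The half-count
#' offset keeps zeros finite; the matching library-size offset keeps each
#' column of the transformed matrix a proper (shifted) composition.
#'
#' @param counts Counts as accepted by [as_count_matrix()].
#' @param prior_count Offset added to each count (default 0.5, giving the
#'   conventional +1 on the library size).
#' @param lib_size Optional per-sample library sizes (for example
#'   composition-corrected effective sizes from
#'   [effective_lib_sizes()]); defaults to the column totals.
#' @return Numeric matrix of log2-CPM values, genes by samples.
#' @export
#' @examples
#' m <- matrix(c(0L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' log_cpm(m)
log_cpm <- function(counts, prior_count = 0.5, lib_size = NULL) {
  counts <- as_count_matrix(counts)
  lib <- lib_size %||% colSums(counts)
  stopifnot(length(lib) == ncol(counts))
  if (any(lib == 0)) {
    abort("every sample must have a positive total count",
          class = "periloc_zero_library")
  }
  log2(sweep(counts + prior_count, 2, lib + 2 * prior_count, "/") * 1e6)
}

#' Effective library sizes
#'
#' Per-sample library sizes for CPM scaling. `"total"` uses the raw column
#' totals. `"tmm"` (default) multiplies them by trimmed-mean-of-M-values
#' scaling factors, which makes the scaling robust to composition shifts:
#' in a fractionation design the enriched transcripts carry extra count
#' mass in the Ps libraries, and raw totals would push the log-ratios of
#' every unenriched gene away from zero.
#'
#' @inheritParams log_cpm
#' @param method `"tmm"` or `"total"`.
#' @return Numeric vector of effective library sizes, one per sample.
#' @export
effective_lib_sizes <- function(counts, method = c("tmm", "total")) {
  method <- match.arg(method)
  counts <- as_count_matrix(counts)
  lib <- colSums(counts)
  if (method == "total") return(lib)
  lib * edgeR::calcNormFactors(counts, lib.size = lib, method = "TMM")
}

#' Expression filter on log-CPM
#'
#' Keeps genes whose log2-CPM exceeds `threshold` in at least one sample —
#' the expression cutoff applied before any enrichment testing.
#'
#' @param logcpm Matrix from [log_cpm()].
#' @param threshold Log2-CPM cutoff (default 0.5).
#' @return Character vector of retained gene identifiers.
#' @export
filter_expressed <- function(logcpm, threshold = 0.5) {
  stopifnot(is.matrix(logcpm), nrow(logcpm) >= 1)
  rownames(logcpm)[apply(logcpm, 1, max) > threshold]
}

# --- empirical-Bayes variance moderation ------------------------------------

# Newton inversion of the trigamma function (y = trigamma(x), y > 0)
trigamma_inverse <- function(y) {
  out <- y
  hi <- y > 1e7
  lo <- y < 1e-6
  out[hi] <- 1 / sqrt(y[hi])
  out[lo] <- 1 / y[lo]
  mid <- !hi & !lo
  x <- 0.5 + 1 / y[mid]
  for (i in seq_len(50)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(-dif / x) < 1e-8) break
  }
  out[mid] <- x
  out
}

#' Method-of-moments prior for variance moderation
#'
#' Fits the scaled inverse-chi-squared prior `(df_prior, var_prior)` of the
#' hierarchical variance model from the per-gene residual variances, by
#' matching the first two moments of `log(s^2)` (whose sampling
#' distribution about the true variance is a shifted log-chi-squared).
#' Genes with non-finite log variances (for example exact zeros) are
#' excluded from the moment fit. A non-positive excess spread returns an
#' infinite prior df (all genes share one variance).
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar or per gene).
#' @return List with `df_prior` and `var_prior`.
#' @export
fit_var_prior <- function(s2, df) {
  stopifnot(length(s2) >= 2, all(df > 0))
  df <- rep_len(df, length(s2))
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ok <- is.finite(e)
  if (sum(ok) < 2) {
    abort("too few finite residual variances to fit a prior",
          class = "periloc_prior_fit")
  }
  e_mean <- mean(e[ok])
  excess <- var(e[ok]) - mean(trigamma(df[ok] / 2))
  if (excess <= 0) {
    return(list(df_prior = Inf, var_prior = exp(e_mean)))
  }
  df_prior <- 2 * trigamma_inverse(excess)
  list(df_prior = df_prior,
       var_prior = exp(e_mean + digamma(df_prior / 2) - log(df_prior / 2)))
}

# posterior (squeezed) variances
squeeze_var <- function(s2, df, df_prior, var_prior) {
  if (is.infinite(df_prior)) return(rep_len(var_prior, length(s2)))
  (df_prior * var_prior + df * s2) / (df_prior + df)
}

# moderated t and two-sided p for a coefficient with unscaled stdev u
moderated_t_test <- function(coef, u, s2, df, df_prior, var_prior) {
  s2_post <- squeeze_var(s2, df, df_prior, var_prior)
  tstat <- ifelse(coef == 0, 0, coef / (u * sqrt(s2_post)))
  df_total <- df + df_prior
  p <- 2 * pt(-abs(tstat), df = df_total)
  list(t = tstat, p = p, df_total = df_total, s2_post = s2_post)
}

# per-group means and pooled residual variance for one factor
group_fit <- function(x, groups) {
  groups <- droplevels(as.factor(groups))
  n_g <- table(groups)
  ind <- stats::model.matrix(~ 0 + groups)
  means <- x %*% sweep(ind, 2, colSums(ind), "/")
  colnames(means) <- levels(groups)
  fitted <- means[, as.integer(groups), drop = FALSE]
  df <- ncol(x) - nlevels(groups)
  s2 <- rowSums((x - fitted)^2) / df
  list(means = means, s2 = s2, df = df, n = as.numeric(n_g),
       levels = levels(groups))
}

match_samples <- function(counts, sample_info) {
  stopifnot(is.data.frame(sample_info),
            all(c("sample", "fraction", "condition", "replicate") %in%
                  names(sample_info)))
  counts <- as_count_matrix(counts)
  missing <- setdiff(sample_info$sample, colnames(counts))
  if (length(missing)) {
    abort(paste0("samples missing from the count matrix: ",
                 paste(missing, collapse = ", ")),
          class = "periloc_invalid_counts")
  }
  if (!all(sample_info$fraction %in% c("Ps", "CB"))) {
    abort('fraction labels must be "Ps" or "CB"',
          class = "periloc_invalid_counts")
  }
  counts[, sample_info$sample, drop = FALSE]
}

#' Protrusion/cell-body enrichment test
#'
#' Per-gene test of protrusion (Ps) versus cell-body (CB) abundance within
#' one condition. The log2 fold change is the difference of mean log2-CPM
#' between Ps and CB replicates (Ps in the numerator); its per-gene
#' residual variance is moderated by shrinking toward a prior fitted
#' across all genes ([fit_var_prior()]), and the p-value comes from a t
#' distribution with `df_prior + df_residual` degrees of freedom. This
#' stabilizes inference at the small replicate numbers typical of
#' fractionation designs.
#'
#' @param counts Counts as accepted by [as_count_matrix()].
#' @param sample_info Data frame with columns `sample`, `fraction`
#'   (`"Ps"`/`"CB"`), `condition`, `replicate`.
#' @param condition Condition to test within; may be omitted when
#'   `sample_info` contains a single condition.
#' @param prior_df,prior_var Optional fixed prior; when `NULL` (default)
#'   the prior is estimated from the data.
#' @param normalization Library-size scaling passed to
#'   [effective_lib_sizes()]: `"tmm"` (default, composition-robust) or
#'   `"total"` (raw column totals).
#' @return A tibble of class `ps_enrichment`, one row per gene, with
#'   columns `gene`, `log2fc`, `mean_logcpm`, `moderated_t`, `p_value`.
#'   Attributes `prior_df`, `prior_var`, `df_residual`, `condition` record
#'   the fit; see [glance.ps_enrichment()].
#' @export
#' @examples
#' sim <- simulate_ps_cb_counts(n_genes = 300, n_enriched = 30,
#'                              n_dependent = 0, seed = 2)
#' fit <- enrichment_test(sim$counts, sim$sample_info, "control")
#' head(tidy(fit))
enrichment_test <- function(counts, sample_info, condition = NULL,
                            prior_df = NULL, prior_var = NULL,
                            normalization = c("tmm", "total")) {
  if (is.null(condition)) {
    conds <- unique(sample_info$condition)
    if (length(conds) != 1) {
      abort("multiple conditions present: specify `condition`",
            class = "periloc_invalid_design")
    }
    condition <- conds
  }
  info <- dplyr::filter(sample_info, .data$condition == !!condition)
  if (nrow(info) == 0) {
    abort(paste0("no samples in condition ", condition),
          class = "periloc_invalid_design")
  }
  if (any(table(info$fraction) < 2) || length(unique(info$fraction)) < 2) {
    abort("need at least 2 replicates of each fraction within the condition",
          class = "periloc_invalid_design")
  }
  counts <- match_samples(counts, info)
  x <- log_cpm(counts, lib_size = effective_lib_sizes(counts, normalization))
  fit <- group_fit(x, info$fraction)
  coef <- fit$means[, "Ps"] - fit$means[, "CB"]
  u <- sqrt(sum(1 / fit$n))
  if (is.null(prior_df) != is.null(prior_var)) {
    abort("supply both `prior_df` and `prior_var`, or neither",
          class = "periloc_invalid_design")
  }
  if (is.null(prior_df)) {
    prior <- fit_var_prior(fit$s2, fit$df)
  } else {
    prior <- list(df_prior = prior_df, var_prior = prior_var)
  }
  mt <- moderated_t_test(coef, u, fit$s2, fit$df, prior$df_prior,
                         prior$var_prior)
  out <- tibble::tibble(
    gene = rownames(x),
    log2fc = unname(coef),
    mean_logcpm = unname(rowMeans(x)),
    moderated_t = unname(mt$t),
    p_value = unname(mt$p)
  )
  structure(out,
            class = c("ps_enrichment", class(out)),
            prior_df = prior$df_prior, prior_var = prior$var_prior,
            df_residual = fit$df, condition = condition,
            n_ps = sum(info$fraction == "Ps"),
            n_cb = sum(info$fraction == "CB"))
}

#' Call Ps-enriched genes
#'
#' A gene is called `ps_enriched` when its fold change exceeds `fc_cutoff`
#' (on the natural scale, i.e. `2^log2fc > fc_cutoff`) and its p-value is
#' below `p_cutoff`; otherwise `non_localized`.
#'
#' @param result A `ps_enrichment` tibble (or any data frame with `gene`,
#'   `log2fc`, `p_value`).
#' @param fc_cutoff Fold-change cutoff (default 2).
#' @param p_cutoff P-value cutoff (default 0.05).
#' @return A tibble with `gene`, `log2fc`, `p_value`, `localization`.
#' @export
classify_ps_enriched <- function(result, fc_cutoff = 2, p_cutoff = 0.05) {
  stopifnot(all(c("gene", "log2fc", "p_value") %in% names(result)))
  tibble::as_tibble(result) |>
    dplyr::transmute(
      .data$gene, .data$log2fc, .data$p_value,
      localization = dplyr::if_else(
        2^.data$log2fc > fc_cutoff & .data$p_value < p_cutoff,
        "ps_enriched", "non_localized")
    )
}

#' Differential enrichment between conditions
#'
#' Per gene, the change in Ps/CB enrichment between a perturbed and a
#' control condition:
#' `log2(Diff FC) = log2(FC_perturbed) - log2(FC_control)`, estimated as
#' the fraction-by-condition interaction of a per-gene linear model on
#' log2-CPM (four group means). Negative values mean the gene became less
#' Ps-enriched in the perturbed condition. The p-value is a moderated t
#' test on the interaction coefficient, with the variance prior fitted
#' across genes as in [enrichment_test()].
#'
#' @inheritParams enrichment_test
#' @param condition_control,condition_perturbed Condition labels in
#'   `sample_info`.
#' @return A tibble of class `ps_diff` with columns `gene`,
#'   `log2_diff_fc`, `moderated_t`, `p_diff`, and prior attributes as in
#'   [enrichment_test()].
#' @export
diff_fc <- function(counts, sample_info, condition_control = "control",
                    condition_perturbed = "perturbed",
                    prior_df = NULL, prior_var = NULL,
                    normalization = c("tmm", "total")) {
  info <- dplyr::filter(sample_info,
                        .data$condition %in% c(condition_control,
                                               condition_perturbed))
  tab <- table(info$fraction, info$condition)
  if (!identical(sort(rownames(tab)), c("CB", "Ps")) || ncol(tab) != 2 ||
      any(tab < 2)) {
    abort("need >= 2 replicates of both fractions in both conditions",
          class = "periloc_invalid_design")
  }
  counts <- match_samples(counts, info)
  x <- log_cpm(counts, lib_size = effective_lib_sizes(counts, normalization))
  grp <- interaction(info$fraction, info$condition, drop = TRUE)
  fit <- group_fit(x, grp)
  key <- function(f, c) paste(f, c, sep = ".")
  coef <- (fit$means[, key("Ps", condition_perturbed)] -
             fit$means[, key("CB", condition_perturbed)]) -
    (fit$means[, key("Ps", condition_control)] -
       fit$means[, key("CB", condition_control)])
  u <- sqrt(sum(1 / fit$n))
  if (is.null(prior_df) != is.null(prior_var)) {
    abort("supply both `prior_df` and `prior_var`, or neither",
          class = "periloc_invalid_design")
  }
  if (is.null(prior_df)) {
    prior <- fit_var_prior(fit$s2, fit$df)
  } else {
    prior <- list(df_prior = prior_df, var_prior = prior_var)
  }
  mt <- moderated_t_test(coef, u, fit$s2, fit$df, prior$df_prior,
                         prior$var_prior)
  out <- tibble::tibble(
    gene = rownames(x),
    log2_diff_fc = unname(coef),
    moderated_t = unname(mt$t),
    p_diff = unname(mt$p)
  )
  structure(out,
            class = c("ps_diff", class(out)),
            prior_df = prior$df_prior, prior_var = prior$var_prior,
            df_residual = fit$df,
            condition_control = condition_control,
            condition_perturbed = condition_perturbed)
}

#' Classify dependence of localized genes on the perturbed factor
#'
#' Among Ps-enriched genes, a gene is `dependent` when its enrichment
#' dropped significantly in the perturbed condition:
#' `log2_diff_fc <= -diff_cutoff` and `p_diff < p_cutoff` (a one-sided,
#' decreased-enrichment rule, since dependence is defined by loss of
#' enrichment). Other Ps-enriched genes are `independent`; genes that are
#' not Ps-enriched get `not_applicable`.
#'
#' @param classification Output of [classify_ps_enriched()].
#' @param diff Output of [diff_fc()].
#' @param diff_cutoff Cutoff on `-log2_diff_fc` (default 1, i.e. a 2-fold
#'   drop in enrichment).
#' @param p_cutoff P-value cutoff (default 0.05).
#' @return `classification` with added columns `log2_diff_fc`, `p_diff`,
#'   `dependence`.
#' @export
classify_dependence <- function(classification, diff, diff_cutoff = 1,
                                p_cutoff = 0.05) {
  stopifnot(all(c("gene", "localization") %in% names(classification)),
            all(c("gene", "log2_diff_fc", "p_diff") %in% names(diff)))
  tibble::as_tibble(classification) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(diff), "gene", "log2_diff_fc", "p_diff"),
      by = "gene"
    ) |>
    dplyr::mutate(dependence = dplyr::case_when(
      .data$localization != "ps_enriched" ~ "not_applicable",
      .data$log2_diff_fc <= -diff_cutoff & .data$p_diff < p_cutoff ~ "dependent",
      .default = "independent"
    ))
}
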