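#' Direct Ps/CB enrichment ratios
#'
#' The simple normalized-count ratio path used for targeted (probe-based)
#' counting: each sample is scaled to counts per million, then per gene
#' the ratio of the mean normalized Ps count to the mean normalized CB
#' count is reported, with a standard error computed across
#' replicate-matched Ps/CB pairs.
#'
#' @inheritParams enrichment_test
#' @param condition Optional condition to restrict to.
#' @return A tibble with `gene`, `ps_mean`, `cb_mean` (normalized),
#'   `ratio`, `ratio_se` (`NA` when replicates cannot be paired), and
#'   `infinite` (`TRUE` when the CB mean is zero).
#' @export
ps_cb_ratio_direct <- function(counts, sample_info, condition = NULL) {
  info <- tibble::as_tibble(sample_info)
  if (!is.null(condition)) {
    info <- dplyr::filter(info, .data$condition == !!condition)
  }
  if (!all(c("Ps", "CB") %in% info$fraction)) {
    abort("both Ps and CB samples are required",
          class = "periloc_invalid_design")
  }
  counts <- match_samples(counts, info)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort("every sample must have a positive total count",
          class = "periloc_zero_library")
  }
  norm <- sweep(counts, 2, lib, "/") * 1e6
  ps <- norm[, info$fraction == "Ps", drop = FALSE]
  cb <- norm[, info$fraction == "CB", drop = FALSE]
  ps_mean <- rowMeans(ps)
  cb_mean <- rowMeans(cb)
  # replicate-paired per-gene ratios for the standard error
  rep_ps <- info$replicate[info$fraction == "Ps"]
  rep_cb <- info$replicate[info$fraction == "CB"]
  common <- intersect(rep_ps, rep_cb)
  ratio_se <- rep(NA_real_, nrow(norm))
  if (length(common) >= 2) {
    pair <- vapply(common, function(r) {
      ps[, match(r, rep_ps)] / cb[, match(r, rep_cb)]
    }, numeric(nrow(norm)))
    ratio_se <- apply(pair, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_
    })
  }
  tibble::tibble(
    gene = rownames(norm),
    ps_mean = unname(ps_mean),
    cb_mean = unname(cb_mean),
    ratio = unname(ifelse(cb_mean == 0, Inf, ps_mean / cb_mean)),
    ratio_se = unname(ratio_se),
    infinite = unname(cb_mean == 0)
  )
}

#' Cumulative fraction (empirical CDF) table
#'
#' Sorted values with the fraction of observations less than or equal to
#' each value; right-continuous, with tied values sharing a single step.
#' This is the summary behind cumulative-fraction plots of fold-change
#' differences.
#'
#' @param values Nonempty numeric vector (NAs are rejected).
#' @return A tibble with `value` (sorted, unique) and `fraction`.
#' @export
#' @examples
#' cumulative_fraction(c(1, 2, 2, 3))
cumulative_fraction <- function(values) {
  if (length(values) == 0) {
    abort("`values` must be nonempty", class = "periloc_invalid_input")
  }
  if (anyNA(values) || !is.numeric(values)) {
    abort("`values` must be numeric without NAs",
          class = "periloc_invalid_input")
  }
  x <- sort(unique(values))
  n <- length(values)
  tibble::tibble(
    value = x,
    fraction = vapply(x, function(v) sum(values <= v), numeric(1)) / n
  )
}
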