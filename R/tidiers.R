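#' Tidy an enrichment fit
#'
#' @param x A `ps_enrichment` or `ps_diff` object.
#' @param ... Unused.
#' @return The per-gene results as a plain tibble.
#' @method tidy ps_enrichment
#' @export
tidy.ps_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname tidy.ps_enrichment
#' @method tidy ps_diff
#' @export
tidy.ps_diff <- function(x, ...) tidy.ps_enrichment(x, ...)

#' One-row summary of an enrichment fit
#'
#' Reports the empirical-Bayes variance prior and design actually used:
#' `prior_df` and `prior_var` (the fitted scaled inverse-chi-squared
#' prior), `df_residual` (per-gene residual degrees of freedom) and the
#' number of genes tested.
#'
#' @inheritParams tidy.ps_enrichment
#' @return A one-row tibble.
#' @method glance ps_enrichment
#' @export
glance.ps_enrichment <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    prior_df = attr(x, "prior_df"),
    prior_var = attr(x, "prior_var"),
    df_residual = attr(x, "df_residual"),
    condition = attr(x, "condition") %||% NA_character_
  )
}

#' @rdname glance.ps_enrichment
#' @method glance ps_diff
#' @export
glance.ps_diff <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    prior_df = attr(x, "prior_df"),
    prior_var = attr(x, "prior_var"),
    df_residual = attr(x, "df_residual"),
    condition_control = attr(x, "condition_control"),
    condition_perturbed = attr(x, "condition_perturbed")
  )
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("ps_enrichment", "ps_diff"))
  for (a in c("prior_df", "prior_var", "df_residual", "condition",
              "condition_control", "condition_perturbed", "n_ps", "n_cb")) {
    attr(x, a) <- NULL
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
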