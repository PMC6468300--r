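# Broom-style tidiers for the package's result objects.

#' Tidy a signature null model
#'
#' @param x A `signature_null` from [random_signature_null()].
#' @param ... Unused.
#' @return A tibble with one row per null draw (`draw`, `null_r`).
#' @method tidy signature_null
#' @export
tidy.signature_null <- function(x, ...) {
  tibble(draw = seq_along(x$null_r), null_r = x$null_r)
}

#' Glance at a signature null model
#'
#' @param x A `signature_null`.
#' @param ... Unused.
#' @return One-row tibble with the fit and test summary.
#' @method glance signature_null
#' @export
glance.signature_null <- function(x, ...) {
  tibble(k = x$k, n_draws = x$n_draws, seed = x$seed, gene = x$gene,
         gumbel_mu = x$gumbel_mu, gumbel_beta = x$gumbel_beta,
         observed_r = x$observed_r, p_value = x$p_value,
         p_upper = x$p_upper, direction = x$direction)
}

#' Tidy a clustering result
#'
#' @param x A `cluster_result` from [cluster_samples()].
#' @param ... Unused.
#' @return Tibble with `sample_id`, `cluster` and (if supplied)
#'   `reference_label`.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  out <- tibble(sample_id = names(x$labels), cluster = unname(x$labels))
  if (!is.null(x$reference_labels)) out$reference_label <- x$reference_labels
  out
}

#' Glance at a clustering result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return One-row tibble with `n_samples`, `k_groups`, `method`, `ari`.
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_samples = length(x$labels), k_groups = x$k_groups,
         method = x$hclust$method, ari = x$ari)
}

#' Glance at a cohort scoring result
#'
#' @param x A `cohort_scoring` from [score_cohort()].
#' @param ... Unused.
#' @return One-row tibble with correlations, null p-values and the
#'   clustering ARI.
#' @method glance cohort_scoring
#' @export
glance.cohort_scoring <- function(x, ...) {
  tibble(
    target_gene = x$target_gene,
    cor_target = x$cor_target,
    p_target = x$null_target$p_value,
    anti_gene = x$anti_gene %||% NA_character_,
    cor_anti = x$cor_anti %||% NA_real_,
    p_anti = if (is.null(x$null_anti)) NA_real_ else x$null_anti$p_value,
    cluster_ari = x$clustering$ari
  )
}
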