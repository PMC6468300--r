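#' Per-gene differential response between two groups
#'
#' Given log2-scale expression, computes for every gene the linear fold
#' change `2^(mean_b - mean_a)` and a two-sided Welch t-test p-value
#' comparing `group_b` against `group_a`. The Welch test is computed
#' vectorized over genes; it matches `stats::t.test()` exactly.
#'
#' @param expr Gene x sample matrix of log2 expression.
#' @param design Tibble with `sample_id` and `group` columns.
#' @param group_a Reference group label (e.g. `"control"`).
#' @param group_b Test group label (e.g. `"treated"`).
#' @param min_replicates Minimum samples per group (default 2).
#' @return Tibble with `gene_id`, `fold_change` (linear), `log2_fc`,
#'   `p_value`.
#' @export
differential_response <- function(expr, design, group_a, group_b,
                                  min_replicates = 2) {
  design <- as_tibble(design)
  a_ids <- design$sample_id[design$group == group_a]
  b_ids <- design$sample_id[design$group == group_b]
  if (length(a_ids) < min_replicates || length(b_ids) < min_replicates) {
    abort(sprintf(
      "Both groups need >= %d replicates (got %d in '%s', %d in '%s').",
      min_replicates, length(a_ids), group_a, length(b_ids), group_b))
  }
  missing <- setdiff(c(a_ids, b_ids), colnames(expr))
  if (length(missing)) abort(sprintf("Samples not in matrix: %s", id_list(missing)))

  a <- expr[, a_ids, drop = FALSE]
  b <- expr[, b_ids, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate zero-variance genes: identical groups get p = 1 (no evidence)
  p[se2 == 0 & mb == ma] <- 1

  tibble(gene_id = rownames(expr), fold_change = unname(2^(mb - ma)),
         log2_fc = unname(mb - ma), p_value = unname(p))
}

#' Classify treatment-responsive genes by inhibitor dependence
#'
#' Joins the treated-vs-control and treated-plus-inhibitor-vs-control
#' contrasts and assigns each gene one of four classes, evaluated in this
#' fixed order (guaranteeing a partition of the responsive set):
#'
#' 1. `not_responsive` unless `fc_t > fc_min` and `p_t < p_max`;
#' 2. `dependent` ("lost induction") if the inhibitor contrast *fails* the
#'    same criterion (`fc_ti <= fc_min` or `p_ti >= p_max`);
#' 3. `repressed` (potentiated by the inhibitor) if
#'    `fc_ti / fc_t >= potentiation_ratio`;
#' 4. `independent` otherwise (induced equally well either way).
#'
#' @param response_t Tibble from [differential_response()] for treated vs
#'   control.
#' @param response_ti Same for treated + inhibitor vs control. Must cover
#'   exactly the same genes.
#' @param fc_min Linear fold-change threshold for responsiveness (default
#'   1.5, strict `>`).
#' @param p_max p-value threshold (default 0.05, strict `<`).
#' @param potentiation_ratio Fold-ratio (`fc_ti / fc_t`) at or above which a
#'   responsive gene counts as inhibitor-potentiated (default 1.5).
#' @return A `response_table` tibble with `gene_id`, `fc_t`, `p_t`, `fc_ti`,
#'   `p_ti`, `dep_class` (factor with levels not_responsive, independent,
#'   repressed, dependent).
#' @examples
#' t1 <- tibble::tibble(gene_id = c("a", "b"), fold_change = c(3, 2),
#'                      p_value = c(0.01, 0.01))
#' t2 <- tibble::tibble(gene_id = c("a", "b"), fold_change = c(1.2, 4),
#'                      p_value = c(0.3, 0.01))
#' classify_dependence(t1, t2)$dep_class
#' @export
classify_dependence <- function(response_t, response_ti, fc_min = 1.5,
                                p_max = 0.05, potentiation_ratio = 1.5) {
  assert_scalar_number(fc_min, "fc_min", positive = TRUE)
  assert_scalar_number(p_max, "p_max", positive = TRUE)
  assert_scalar_number(potentiation_ratio, "potentiation_ratio", positive = TRUE)
  only_t <- setdiff(response_t$gene_id, response_ti$gene_id)
  only_ti <- setdiff(response_ti$gene_id, response_t$gene_id)
  if (length(only_t) || length(only_ti)) {
    abort(sprintf(
      "Contrasts cover different genes. Only in treated: %s; only in inhibitor: %s",
      id_list(only_t), id_list(only_ti)))
  }
  tab <- dplyr::inner_join(
    dplyr::select(response_t, "gene_id", fc_t = "fold_change", p_t = "p_value"),
    dplyr::select(response_ti, "gene_id", fc_ti = "fold_change", p_ti = "p_value"),
    by = "gene_id")

  responsive <- tab$fc_t > fc_min & tab$p_t < p_max
  fails_ti <- tab$fc_ti <= fc_min | tab$p_ti >= p_max
  potentiated <- tab$fc_ti / tab$fc_t >= potentiation_ratio
  cls <- dplyr::case_when(
    !responsive ~ "not_responsive",
    fails_ti ~ "dependent",
    potentiated ~ "repressed",
    TRUE ~ "independent"
  )
  tab$dep_class <- factor(cls, levels = c("not_responsive", "independent",
                                          "repressed", "dependent"))
  class(tab) <- c("response_table", class(tab))
  attr(tab, "thresholds") <- c(fc_min = fc_min, p_max = p_max,
                               potentiation_ratio = potentiation_ratio)
  tab
}

#' Extract one dependence class as a gene signature
#'
#' @param table A `response_table` from [classify_dependence()].
#' @param which Class to extract (default `"dependent"`, the
#'   inhibitor-dependence signature).
#' @param name Name for the resulting signature.
#' @return A [gene_signature()]; empty signatures are allowed with a
#'   warning.
#' @export
extract_signature <- function(table, which = "dependent",
                              name = paste0(which, "_signature")) {
  stopifnot(inherits(table, "response_table"))
  which <- match.arg(which, levels(table$dep_class))
  genes <- table$gene_id[table$dep_class == which]
  if (!length(genes)) {
    warn(sprintf("No genes in class '%s': returning an empty signature.", which))
    return(structure(list(name = name, description = "", genes = character()),
                     class = "gene_signature"))
  }
  gene_signature(name, genes)
}

#' Derive an inhibitor-dependence signature from a three-condition experiment
#'
#' Convenience pipeline: runs [differential_response()] for treated vs
#' control and treated + inhibitor vs control, classifies dependence, and
#' extracts the dependent class as the signature.
#'
#' @param expr Gene x sample log2 expression matrix.
#' @param design Tibble with `sample_id`, `group`; groups must include
#'   `control`, `treated`, `treated_inhibitor` (names configurable).
#' @param groups Named character vector mapping the three roles to group
#'   labels.
#' @inheritParams classify_dependence
#' @param name Signature name.
#' @return List with `response` (a `response_table`) and `signature`.
#' @examples
#' sim <- generate_three_condition_experiment(n_genes = 200, n_responsive = 60,
#'   n_dependent = 25, n_repressed = 15, seed = 7)
#' res <- derive_signature(sim$expr, sim$design)
#' table(res$response$dep_class)
#' @export
derive_signature <- function(expr, design,
                             groups = c(control = "control",
                                        treated = "treated",
                                        inhibitor = "treated_inhibitor"),
                             fc_min = 1.5, p_max = 0.05,
                             potentiation_ratio = 1.5,
                             name = "dependence_signature") {
  rt <- differential_response(expr, design, groups[["control"]], groups[["treated"]])
  rti <- differential_response(expr, design, groups[["control"]], groups[["inhibitor"]])
  tab <- classify_dependence(rt, rti, fc_min, p_max, potentiation_ratio)
  sig <- extract_signature(tab, "dependent", name)
  list(response = tab, signature = sig)
}
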