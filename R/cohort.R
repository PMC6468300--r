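#' Median-of-ratios size factors
#'
#' Per-sample normalization constants in the DESeq style: each sample's
#' factor is the median, over reference genes, of the ratio of the sample's
#' count to the gene's geometric mean across samples. Reference genes are
#' those with no zero count in any sample. Normalized values are
#' `count / factor`.
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @return Named per-sample vector of positive size factors.
#' @examples
#' m <- cbind(A = c(2, 8), B = c(4, 16))
#' rownames(m) <- c("g1", "g2")
#' size_factors(m) # B twice A
#' @export
size_factors <- function(counts) {
  if (!is.matrix(counts) || any(counts < 0)) {
    abort("`counts` must be a non-negative matrix.")
  }
  ref <- rowSums(counts == 0) == 0L
  if (!any(ref)) {
    abort(paste("No gene has nonzero counts in every sample;",
                "filter all-zero-containing genes or samples first."))
  }
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  f <- apply(logc - loggeo, 2L, function(v) exp(median(v)))
  stats::setNames(f, colnames(counts))
}

#' Normalize a count matrix by its size factors
#'
#' @param counts Gene x sample count matrix.
#' @param factors Optional precomputed [size_factors()].
#' @return Matrix of `count / factor`.
#' @export
normalize_cohort <- function(counts, factors = size_factors(counts)) {
  sweep(counts, 2L, factors, `/`)
}

#' Stratify tumors into first/last expression deciles
#'
#' Ranks tumors by a target gene's (normalized) expression; the lowest
#' `ceiling(n/10)` form the low-decile stratum, the highest form the
#' high-decile stratum, and everything else is mid. Ties are broken by the
#' stable input order, so the result is deterministic; fully degenerate
#' ties trigger a warning.
#'
#' @param target_values Numeric vector of the target gene's expression, one
#'   per tumor (names are sample ids; required if `sample_ids` missing).
#' @param sample_ids Sample ids aligned with `target_values`.
#' @return Tibble with `sample_id`, `target_value`, `stratum` (factor:
#'   `low_decile`, `mid`, `high_decile`).
#' @export
stratify_deciles <- function(target_values, sample_ids = names(target_values)) {
  n <- length(target_values)
  if (n < 10L) abort("Decile stratification needs >= 10 tumors.")
  if (is.null(sample_ids) || length(sample_ids) != n) {
    abort("`sample_ids` must align with `target_values`.")
  }
  k <- ceiling(n / 10)
  ord <- stable_order(target_values)
  stratum <- rep("mid", n)
  stratum[ord[seq_len(k)]] <- "low_decile"
  stratum[ord[seq.int(n - k + 1L, n)]] <- "high_decile"
  sorted <- target_values[ord]
  if (sorted[k] == sorted[k + 1L] || sorted[n - k] == sorted[n - k + 1L]) {
    warn("Ties at a decile boundary: strata fixed by stable sample order.")
  }
  tibble(sample_id = sample_ids, target_value = target_values,
         stratum = factor(stratum, levels = c("low_decile", "mid", "high_decile")))
}

# Per-gene, per-sample fold change relative to the mean of the normal
# samples, on the requested scale. Workhorse for activation scores and the
# resampling null.
fc_vs_normals <- function(values, normal_samples, samples,
                          scale = c("log2", "linear"), pseudocount = 1) {
  scale <- match.arg(scale)
  missing <- setdiff(c(normal_samples, samples), colnames(values))
  if (length(missing)) abort(sprintf("Samples not in matrix: %s", id_list(missing)))
  ref <- rowMeans(values[, normal_samples, drop = FALSE])
  ratio <- (values[, samples, drop = FALSE] + pseudocount) / (ref + pseudocount)
  if (scale == "log2") log2(ratio) else ratio
}

#' Signature activation score per sample
#'
#' The activation score of a sample is the sum, over the signature genes
#' present in the matrix, of that gene's fold change in the sample relative
#' to the mean of the normal samples. By default fold changes are summed on
#' the log2 scale (symmetric in induction/repression and robust to single
#' extreme genes); `scale = "linear"` sums raw ratios instead.
#'
#' @param values Gene x sample matrix of normalized expression.
#' @param signature A [gene_signature()] (or character vector of gene ids).
#' @param normal_samples Ids of the normal reference samples (>= 2).
#' @param samples Samples to score (default: all non-normal columns).
#' @param scale `"log2"` (default) or `"linear"`.
#' @param pseudocount Offset guarding zeros.
#' @return Tibble with `sample_id`, `activation_score`, plus an attribute
#'   `missing_genes` naming signature genes absent from the matrix (also
#'   reported via a message).
#' @examples
#' m <- cbind(n1 = c(10, 10, 10), n2 = c(10, 10, 10), t1 = c(20, 40, 10))
#' rownames(m) <- c("g1", "g2", "g3")
#' activation_score(m, c("g1", "g2", "g3"), c("n1", "n2"), "t1",
#'                  pseudocount = 0) # 1 + 2 + 0 = 3
#' @export
activation_score <- function(values, signature, normal_samples,
                             samples = setdiff(colnames(values), normal_samples),
                             scale = c("log2", "linear"), pseudocount = 1) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  if (length(normal_samples) < 2L) abort("Need >= 2 normal reference samples.")
  present <- intersect(genes, rownames(values))
  if (!length(present)) abort("No signature gene is present in the matrix.")
  missing_genes <- setdiff(genes, present)
  if (length(missing_genes)) {
    inform(sprintf("%d signature gene(s) absent from the matrix, skipped: %s",
                   length(missing_genes), id_list(missing_genes)))
  }
  fc <- fc_vs_normals(values[present, , drop = FALSE], normal_samples,
                      samples, scale, pseudocount)
  out <- tibble(sample_id = samples, activation_score = unname(colSums(fc)))
  attr(out, "missing_genes") <- missing_genes
  out
}

#' Hierarchical clustering of samples on signature genes
#'
#' Agglomerative clustering of samples with Euclidean distance on log2
#' values and Ward's linkage, cut into `k_groups`. The default variant is
#' the squared-distance formulation (`"ward.D2"` in [stats::hclust()]); the
#' classic variant is available as `"ward.D"`. If reference labels are
#' supplied, the adjusted Rand index of the cut against them is reported
#' (via `mclust::adjustedRandIndex`).
#'
#' @param values Gene x sample matrix (already restricted to the genes of
#'   interest, e.g. signature genes), on the normalized scale.
#' @param samples Samples to cluster (default: all columns).
#' @param k_groups Number of clusters to cut; must not exceed the sample
#'   count.
#' @param reference_labels Optional labels, aligned with `samples`.
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @param log2_transform Take `log2(value + pseudocount)` first (default
#'   TRUE).
#' @param pseudocount Offset for the log2 transform.
#' @return A `cluster_result`: list with `hclust`, `labels` (named cut
#'   assignments), `ari` (or `NA`), `reference_labels`, `k_groups`.
#' @export
cluster_samples <- function(values, samples = colnames(values), k_groups,
                            reference_labels = NULL,
                            variant = c("ward.D2", "ward.D"),
                            log2_transform = TRUE, pseudocount = 1) {
  variant <- match.arg(variant)
  k_groups <- assert_count(k_groups, "k_groups", 1L)
  if (length(samples) < 2L) abort("Need >= 2 samples to cluster.")
  if (k_groups > length(samples)) {
    abort(sprintf("k_groups (%d) exceeds the number of samples (%d).",
                  k_groups, length(samples)))
  }
  x <- t(values[, samples, drop = FALSE])
  if (log2_transform) x <- log2(x + pseudocount)
  hc <- hclust(dist(x), method = variant)
  labels <- cutree(hc, k = k_groups)
  ari <- NA_real_
  if (!is.null(reference_labels)) {
    if (length(reference_labels) != length(samples)) {
      abort("`reference_labels` must align with `samples`.")
    }
    ari <- mclust::adjustedRandIndex(labels, reference_labels)
  }
  structure(list(hclust = hc, labels = labels, ari = ari,
                 reference_labels = reference_labels, k_groups = k_groups),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d samples cut into %d groups (%s)\n",
              length(x$labels), x$k_groups, x$hclust$method))
  if (!is.na(x$ari)) cat(sprintf("  adjusted Rand index vs reference: %.3f\n", x$ari))
  invisible(x)
}

#' Export a dendrogram as Newick text
#'
#' @param x A `cluster_result` (or `hclust`).
#' @param path Optional output file; if missing the Newick string is
#'   returned.
#' @return The Newick string, invisibly if written to file.
#' @export
as_newick <- function(x, path = NULL) {
  hc <- if (inherits(x, "cluster_result")) x$hclust else x
  stopifnot(inherits(hc, "hclust"))
  txt <- ape::write.tree(ape::as.phylo(hc))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Correlation between activation scores and one gene's expression
#'
#' Pearson correlation across tumors between the activation score and the
#' gene's log2 normalized expression.
#'
#' @param score_table Tibble with `sample_id`, `activation_score` (e.g. from
#'   [activation_score()]).
#' @param values Gene x sample normalized expression matrix.
#' @param gene Gene id present in `values`.
#' @param pseudocount Offset for the log2 transform.
#' @return The Pearson correlation coefficient (length-1 numeric).
#' @export
score_gene_correlation <- function(score_table, values, gene, pseudocount = 1) {
  if (!gene %in% rownames(values)) abort(sprintf("Gene '%s' not in matrix.", gene))
  if (nrow(score_table) < 3L) abort("Need >= 3 tumors for a correlation.")
  expr <- log2(values[gene, score_table$sample_id] + pseudocount)
  if (sd(expr) == 0 || sd(score_table$activation_score) == 0) {
    abort("Zero variance in scores or expression: correlation undefined.")
  }
  cor(score_table$activation_score, expr)
}

# Method-of-moments Gumbel fit: beta = s * sqrt(6) / pi, mu = m - gamma * beta.
gumbel_fit_moments <- function(x) {
  beta <- sd(x) * sqrt(6) / pi
  mu <- mean(x) - EULER_GAMMA * beta
  c(mu = mu, beta = beta)
}

gumbel_fit_mle <- function(x) {
  start <- gumbel_fit_moments(x)
  nll <- function(p) {
    if (p[2L] <= 0) return(Inf)
    z <- (x - p[1L]) / p[2L]
    length(x) * log(p[2L]) + sum(z) + sum(exp(-z))
  }
  fit <- stats::optim(start, nll)
  c(mu = unname(fit$par[1L]), beta = unname(fit$par[2L]))
}

# Upper tail 1 - exp(-exp(-z)) of the fitted Gumbel, computed stably so that
# extreme observations give a tiny positive p rather than 0.
gumbel_upper_tail <- function(x, mu, beta) {
  z <- (x - mu) / beta
  p <- -expm1(-exp(-z))
  pmax(p, .Machine$double.xmin)
}

#' Random-signature resampling null for a score-gene correlation
#'
#' Assesses whether the correlation between a signature's activation score
#' and a gene's expression could arise from an arbitrary gene set of the
#' same size: draws `n_draws` random signatures of `k` genes uniformly
#' without replacement from the matrix genes (excluding `gene` itself and
#' any `exclude` set), recomputes the activation score for each, records its
#' Pearson correlation with the gene, and fits a Gumbel extreme-value
#' distribution to the null correlations by the method of moments
#' (`beta = s * sqrt(6) / pi`, `mu = m - 0.5772 * beta`).
#'
#' Two tail probabilities are reported. `p_value` follows the directional
#' convention: for a positive observed correlation it is the upper Gumbel
#' tail `1 - exp(-exp(-(r - mu)/beta))`; for a negative one, fit and tail
#' are applied to the negated values. `p_upper` is always the plain upper
#' tail of the observed correlation against the as-is fit; it is the
#' calibrated quantity under the null and the one to use for uniformity
#' checks.
#'
#' @param values Gene x sample normalized expression matrix.
#' @param signature The signature whose observed correlation is being
#'   tested.
#' @param gene Correlate gene (excluded from the null universe).
#' @param normal_samples,tumor_samples Reference and scored samples.
#' @param n_draws Number of random signatures (default 1000).
#' @param seed Integer seed for the draws.
#' @param exclude Extra genes to exclude from the null universe (default
#'   none; at desk scale, excluding the true signature genes avoids
#'   signal leakage into the null — see the methods vignette).
#' @param k Signature size for the draws; defaults to the number of
#'   signature genes present in the matrix.
#' @param scale,pseudocount Passed to the activation score.
#' @param fit `"moments"` (default, closed form) or `"mle"`.
#' @return A `signature_null` object: list with `k`, `n_draws`, `seed`,
#'   `null_r`, `gumbel_mu`, `gumbel_beta`, `observed_r`, `p_value`,
#'   `p_upper`, `direction`, `gene`.
#' @export
random_signature_null <- function(values, signature, gene,
                                  normal_samples, tumor_samples,
                                  n_draws = 1000, seed,
                                  exclude = character(), k = NULL,
                                  scale = c("log2", "linear"),
                                  pseudocount = 1,
                                  fit = c("moments", "mle")) {
  scale <- match.arg(scale)
  fit <- match.arg(fit)
  n_draws <- assert_count(n_draws, "n_draws", 2L)
  seed <- assert_count(seed, "seed")
  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  present <- intersect(genes, rownames(values))
  if (!length(present)) abort("No signature gene is present in the matrix.")
  if (is.null(k)) k <- length(present)
  k <- assert_count(k, "k", 1L)
  universe <- setdiff(rownames(values), c(gene, exclude))
  if (k > length(universe)) {
    abort(sprintf("k = %d exceeds the %d available genes in the null universe.",
                  k, length(universe)))
  }

  target <- log2(values[gene, tumor_samples] + pseudocount)
  fc_all <- fc_vs_normals(values, normal_samples, tumor_samples,
                          scale, pseudocount)
  observed_r <- cor(colSums(fc_all[present, , drop = FALSE]), target)

  uni_idx <- match(universe, rownames(fc_all))
  null_r <- withr::with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      idx <- uni_idx[sample.int(length(uni_idx), k)]
      cor(colSums(fc_all[idx, , drop = FALSE]), target)
    }, numeric(1))
  })

  fit_fun <- if (fit == "moments") gumbel_fit_moments else gumbel_fit_mle
  par_up <- fit_fun(null_r)
  p_upper <- gumbel_upper_tail(observed_r, par_up[["mu"]], par_up[["beta"]])
  if (observed_r >= 0) {
    direction <- "positive"
    par_dir <- par_up
    p_value <- p_upper
  } else {
    direction <- "negative"
    par_dir <- fit_fun(-null_r)
    p_value <- gumbel_upper_tail(-observed_r, par_dir[["mu"]], par_dir[["beta"]])
  }

  structure(
    list(k = k, n_draws = n_draws, seed = seed, null_r = null_r,
         gumbel_mu = unname(par_dir[["mu"]]),
         gumbel_beta = unname(par_dir[["beta"]]),
         observed_r = observed_r, p_value = unname(p_value),
         p_upper = unname(p_upper), direction = direction, gene = gene,
         fit = fit),
    class = "signature_null"
  )
}

#' @export
print.signature_null <- function(x, ...) {
  cat(sprintf("<signature_null> %d draws of %d genes vs '%s' (seed %d)\n",
              x$n_draws, x$k, x$gene, x$seed))
  cat(sprintf("  observed r = %.3f (%s); Gumbel(mu = %.4f, beta = %.4f)\n",
              x$observed_r, x$direction, x$gumbel_mu, x$gumbel_beta))
  cat(sprintf("  p = %.3g (directional), p_upper = %.3g\n", x$p_value, x$p_upper))
  invisible(x)
}

#' Score a tumor/normal cohort against a signature
#'
#' Full cohort pipeline: median-of-ratios normalization, per-tumor
#' activation score, decile stratification on a target gene, score-vs-gene
#' correlations, Ward clustering of normals plus the extreme strata on the
#' signature genes, and the random-signature Gumbel null for the target
#' correlation.
#'
#' @param x A [count_experiment()] whose design `group` column labels
#'   samples `normal` / `tumor` (or a bare gene x sample count matrix plus
#'   `design`).
#' @param signature A [gene_signature()].
#' @param target_gene Gene used for stratification and the primary
#'   correlation.
#' @param anti_gene Optional negatively-coupled gene for a second
#'   correlation/null.
#' @param design Required if `x` is a bare matrix.
#' @param n_draws,seed,exclude Passed to [random_signature_null()].
#' @param scale,pseudocount Score options.
#' @return A `cohort_scoring` list: `score_table` (tibble `sample_id`,
#'   `activation_score`, `target_log2`, `stratum` with normals labelled
#'   `normal`), `size_factors`, `clustering` (a `cluster_result`),
#'   `cor_target`, `cor_anti`, `null_target`, `null_anti`.
#' @examples
#' \donttest{
#' sim <- generate_cohort(n_genes = 300, n_signature = 40, n_normal = 20,
#'                        n_tumor = 60, seed = 5)
#' res <- score_cohort(sim$experiment, sim$signature, sim$target_gene,
#'                     anti_gene = sim$anti_gene, n_draws = 200, seed = 1)
#' res$cor_target
#' }
#' @export
score_cohort <- function(x, signature, target_gene, anti_gene = NULL,
                         design = NULL, n_draws = 1000, seed,
                         exclude = character(),
                         scale = c("log2", "linear"), pseudocount = 1) {
  scale <- match.arg(scale)
  if (inherits(x, "count_experiment")) {
    counts <- x$counts
    design <- x$design
  } else {
    counts <- x
    if (is.null(design)) abort("`design` is required with a bare matrix.")
  }
  normal_samples <- design$sample_id[design$group == "normal"]
  tumor_samples <- design$sample_id[design$group == "tumor"]
  if (length(normal_samples) < 2L) abort("Need >= 2 normal samples.")
  if (!target_gene %in% rownames(counts)) {
    abort(sprintf("Target gene '%s' not in matrix.", target_gene))
  }

  sf <- size_factors(counts)
  values <- normalize_cohort(counts, sf)

  scores <- activation_score(values, signature, normal_samples,
                             tumor_samples, scale, pseudocount)
  target_log2 <- log2(values[target_gene, ] + pseudocount)
  strata <- stratify_deciles(target_log2[tumor_samples], tumor_samples)

  score_table <- dplyr::left_join(
    scores,
    dplyr::select(strata, "sample_id", "stratum"),
    by = "sample_id")
  score_table$target_log2 <- target_log2[score_table$sample_id]
  normal_scores <- activation_score(values, signature, normal_samples,
                                    normal_samples, scale, pseudocount)
  normal_scores$stratum <- "normal"
  normal_scores$target_log2 <- target_log2[normal_scores$sample_id]
  score_table <- dplyr::bind_rows(
    dplyr::mutate(score_table, stratum = as.character(.data$stratum)),
    normal_scores)
  score_table$stratum <- factor(score_table$stratum,
                                levels = c("low_decile", "mid", "high_decile",
                                           "normal"))
  class(score_table) <- c("score_table", class(score_table))

  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  present <- intersect(genes, rownames(values))
  extreme <- score_table$sample_id[score_table$stratum %in%
                                     c("low_decile", "high_decile", "normal")]
  ref_labels <- as.character(score_table$stratum[match(extreme, score_table$sample_id)])
  clustering <- cluster_samples(values[present, , drop = FALSE], extreme,
                                k_groups = 3L, reference_labels = ref_labels,
                                pseudocount = pseudocount)

  tumor_scores <- scores
  cor_target <- score_gene_correlation(tumor_scores, values, target_gene,
                                       pseudocount)
  null_target <- random_signature_null(values, signature, target_gene,
                                       normal_samples, tumor_samples,
                                       n_draws = n_draws, seed = seed,
                                       exclude = exclude, scale = scale,
                                       pseudocount = pseudocount)
  cor_anti <- NULL
  null_anti <- NULL
  if (!is.null(anti_gene)) {
    cor_anti <- score_gene_correlation(tumor_scores, values, anti_gene,
                                       pseudocount)
    null_anti <- random_signature_null(values, signature, anti_gene,
                                       normal_samples, tumor_samples,
                                       n_draws = n_draws, seed = seed + 1L,
                                       exclude = exclude, scale = scale,
                                       pseudocount = pseudocount)
  }

  structure(
    list(score_table = score_table, size_factors = sf,
         clustering = clustering, cor_target = cor_target,
         cor_anti = cor_anti, null_target = null_target,
         null_anti = null_anti, target_gene = target_gene,
         anti_gene = anti_gene),
    class = "cohort_scoring"
  )
}

#' @export
print.cohort_scoring <- function(x, ...) {
  cat(sprintf("<cohort_scoring> %d scored samples; target '%s'\n",
              nrow(x$score_table), x$target_gene))
  cat(sprintf("  r(score, %s) = %.3f (null p = %.3g)\n",
              x$target_gene, x$cor_target, x$null_target$p_value))
  if (!is.null(x$cor_anti)) {
    cat(sprintf("  r(score, %s) = %.3f (null p = %.3g)\n",
                x$anti_gene, x$cor_anti, x$null_anti$p_value))
  }
  cat(sprintf("  clustering ARI vs strata: %.3f\n", x$clustering$ari))
  invisible(x)
}
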