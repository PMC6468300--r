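#' Normalize probe counts with positive spike-ins and housekeeping genes
#'
#' Two-step content normalization in the conventional nCounter style. For
#' each step the per-sample summary is the geometric mean of the relevant
#' control probes (positive spike-ins first, then housekeeping genes on the
#' spike-normalized values); each sample's factor is the across-sample
#' arithmetic mean of those summaries divided by the sample's own summary,
#' rescaled so the factors average exactly 1. Both factors are applied
#' multiplicatively to every probe.
#'
#' The per-sample background (mean + 2 SD of the normalized negative-control
#' probes) is recorded for QC; it is never subtracted.
#'
#' @param x A [count_experiment()] with at least two positive-spike probes
#'   and one housekeeping probe, all with strictly positive counts in every
#'   sample.
#' @return An object of class `normalized_matrix`: list with `values`
#'   (probe x sample positive reals), `pos_factors`, `hk_factors`,
#'   `background` (per-sample), plus the `annotation` and `design` tibbles
#'   carried over.
#' @examples
#' sim <- generate_screen(n_endogenous = 5, n_perturbations = 8, seed = 1)
#' norm <- normalize_counts(sim$experiment)
#' round(norm$pos_factors[1:3], 3)
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "count_experiment"))
  ann <- x$annotation
  counts <- x$counts
  pos_ids <- ann$probe_id[ann$probe_class == "positive_spike"]
  hk_ids <- ann$probe_id[ann$probe_class == "housekeeping"]
  neg_ids <- ann$probe_id[ann$probe_class == "negative_spike"]
  if (length(pos_ids) < 2L || length(hk_ids) < 1L) {
    abort("Normalization needs >= 2 positive_spike probes and >= 1 housekeeping probe.")
  }

  check_positive <- function(ids, what) {
    sub <- counts[ids, , drop = FALSE]
    zero <- which(sub <= 0, arr.ind = TRUE)
    if (nrow(zero)) {
      offenders <- sprintf("%s/%s", ids[zero[, 1L]], colnames(sub)[zero[, 2L]])
      abort(sprintf("Zero count in %s probe(s) (probe/sample): %s",
                    what, id_list(offenders)))
    }
  }
  check_positive(pos_ids, "positive_spike")
  check_positive(hk_ids, "housekeeping")

  factor_for <- function(mat, ids) {
    g <- apply(mat[ids, , drop = FALSE], 2L, geom_mean)
    f <- mean(g) / g
    f / mean(f) # factors average exactly 1
  }

  pos_factors <- factor_for(counts, pos_ids)
  v1 <- sweep(counts, 2L, pos_factors, `*`)
  hk_factors <- factor_for(v1, hk_ids)
  values <- sweep(v1, 2L, hk_factors, `*`)

  background <- if (length(neg_ids)) {
    neg <- values[neg_ids, , drop = FALSE]
    apply(neg, 2L, function(v) mean(v) + 2 * sd(v))
  } else {
    stats::setNames(rep(0, ncol(values)), colnames(values))
  }

  structure(
    list(values = values, pos_factors = pos_factors, hk_factors = hk_factors,
         background = background, annotation = ann, design = x$design),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  pos_factors in [%.3f, %.3f]; hk_factors in [%.3f, %.3f]\n",
              min(x$pos_factors), max(x$pos_factors),
              min(x$hk_factors), max(x$hk_factors)))
  invisible(x)
}

#' Log2 expression levels with a pseudocount
#'
#' @param norm A `normalized_matrix` (or a bare numeric matrix).
#' @param pseudocount Positive offset added before taking log2; guards zeros.
#' @return A probe x sample matrix of `log2(value + pseudocount)`.
#' @export
log2_levels <- function(norm, pseudocount = 1) {
  assert_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  values <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  log2(values + pseudocount)
}

#' Per-probe Z-scores across the samples of a screen arm
#'
#' For each probe, the mean and sample standard deviation (n - 1) of its
#' log2 normalized level are computed over *all* samples of the arm,
#' controls and perturbations alike, and each sample's level is standardized
#' against them. Probes with zero spread get `NA` Z-scores and a QC flag
#' rather than an error.
#'
#' @param log2_matrix Probe x sample matrix of log2 levels.
#' @param arm_samples Sample ids defining the arm (>= 3); defaults to all
#'   columns.
#' @return A list with `mean` and `sd` (per probe), `z` (probe x sample
#'   matrix over `arm_samples`) and `sd_zero` (logical per probe).
#' @examples
#' m <- matrix(c(1, 1, 1, 1, 6), nrow = 1,
#'             dimnames = list("P", paste0("s", 1:5)))
#' z <- probe_zscores(m)
#' round(z$z[1, "s5"], 4) # 4 / sqrt(5)
#' @export
probe_zscores <- function(log2_matrix, arm_samples = colnames(log2_matrix)) {
  if (length(arm_samples) < 3L) {
    abort("An arm needs >= 3 samples to estimate a per-probe spread.")
  }
  missing <- setdiff(arm_samples, colnames(log2_matrix))
  if (length(missing)) {
    abort(sprintf("Samples not in matrix: %s", id_list(missing)))
  }
  m <- log2_matrix[, arm_samples, drop = FALSE]
  mu <- rowMeans(m)
  s <- row_sds(m)
  sd_zero <- s == 0
  z <- (m - mu) / ifelse(sd_zero, NA_real_, s)
  list(mean = mu, sd = s, z = z, sd_zero = sd_zero)
}

#' Convert a Z-score to a standard-normal tail p-value
#'
#' One-tailed gives the upper tail `P(Z > z)`; two-tailed gives twice the
#' upper tail of `|z|`. At the conventional screen thresholds this yields
#' the familiar figures: one-tailed 9.0e-4 at z = 3.12 and 5.7e-3 at
#' z = 2.53; two-tailed 4.65e-4 (0.05%) at z = 3.5.
#'
#' @param z Numeric vector of finite Z-scores.
#' @param tails `"one"` (default) or `"two"`.
#' @return p-values in (0, 1).
#' @export
z_to_pvalue <- function(z, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (any(!is.finite(z))) abort("`z` must be finite.")
  if (tails == "one") {
    pnorm(z, lower.tail = FALSE)
  } else {
    2 * pnorm(abs(z), lower.tail = FALSE)
  }
}

#' Call induction hits from per-probe Z-scores
#'
#' Flags probe/perturbation pairs whose log2 normalized level exceeds the
#' probe's arm-wide mean by more than `thresholds[1]` and `thresholds[2]`
#' sample standard deviations (strict inequality, one-sided upward: the
#' screens look for induction of silent genes). Control samples are scored
#' but never flagged as hits. A per-probe Shapiro-Wilk normality flag
#' (alpha = 0.05) and a below-background flag accompany every row; both are
#' QC annotations, neither gates the calls.
#'
#' @param zres Result of [probe_zscores()].
#' @param log2_matrix The matrix passed to [probe_zscores()].
#' @param design Sample design tibble (`sample_id`, `perturbation_id`, ...).
#' @param thresholds Two strictly increasing sigma thresholds.
#' @param background Optional per-sample background level (on the normalized
#'   scale) for the `below_background` flag; the flag compares the
#'   *normalized* (not log2) value, so supply `norm_values` too.
#' @param norm_values Optional probe x sample normalized values matrix.
#' @param shapiro_alpha Significance level for the per-probe normality flag.
#' @return A `hit_table` tibble with columns `probe_id`, `sample_id`,
#'   `perturbation_id`, `log2_value`, `z`, `hit_2p5`, `hit_3p5`
#'   (flags at the lower and upper threshold, named for the defaults),
#'   `probe_normal`, `below_background`.
#' @export
call_hits <- function(zres, log2_matrix, design, thresholds = c(2.5, 3.5),
                      background = NULL, norm_values = NULL,
                      shapiro_alpha = 0.05) {
  if (length(thresholds) != 2L || !all(is.finite(thresholds)) ||
      diff(thresholds) <= 0) {
    abort("`thresholds` must be two strictly increasing finite numbers.")
  }
  z <- zres$z
  arm_samples <- colnames(z)
  m <- log2_matrix[rownames(z), arm_samples, drop = FALSE]

  shapiro_p <- purrr::map_dbl(seq_len(nrow(m)), function(i) {
    if (zres$sd_zero[i]) return(NA_real_)
    x <- m[i, ]
    if (length(x) > 5000L) x <- x[seq_len(5000L)]
    tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  })
  probe_normal <- shapiro_p > shapiro_alpha

  tab <- tibble(
    probe_id = rep(rownames(z), times = ncol(z)),
    sample_id = rep(arm_samples, each = nrow(z)),
    log2_value = as.vector(m),
    z = as.vector(z)
  )
  tab <- dplyr::left_join(
    tab, dplyr::select(design, "sample_id", "perturbation_id"),
    by = "sample_id")
  is_control <- tab$perturbation_id == "control"
  tab$hit_2p5 <- !is_control & !is.na(tab$z) & tab$z > thresholds[1L]
  tab$hit_3p5 <- !is_control & !is.na(tab$z) & tab$z > thresholds[2L]
  tab$probe_normal <- probe_normal[match(tab$probe_id, rownames(z))]
  tab$below_background <- if (!is.null(background) && !is.null(norm_values)) {
    as.vector(norm_values[rownames(z), arm_samples, drop = FALSE]) <
      background[tab$sample_id]
  } else {
    NA
  }
  tab <- tab[, c("probe_id", "sample_id", "perturbation_id", "log2_value",
                 "z", "hit_2p5", "hit_3p5", "probe_normal", "below_background")]
  class(tab) <- c("hit_table", class(tab))
  attr(tab, "thresholds") <- thresholds
  tab
}

#' Screen hit-calling pipeline
#'
#' Chains [normalize_counts()], [log2_levels()], [probe_zscores()] (within
#' each screen arm, over all of its samples including controls) and
#' [call_hits()], restricted to endogenous probes.
#'
#' @param x A [count_experiment()].
#' @param thresholds Two sigma thresholds (see [call_hits()]).
#' @param pseudocount Offset for [log2_levels()].
#' @return A `hit_table` tibble covering every endogenous probe and every
#'   sample, with an `arm` column.
#' @examples
#' sim <- generate_screen(n_endogenous = 8, n_perturbations = 20,
#'                        n_hits = 1, seed = 42)
#' hits <- screen_hits(sim$experiment)
#' dplyr::filter(hits, hit_2p5)
#' @export
screen_hits <- function(x, thresholds = c(2.5, 3.5), pseudocount = 1) {
  stopifnot(inherits(x, "count_experiment"))
  norm <- normalize_counts(x)
  lv <- log2_levels(norm, pseudocount)
  endo <- norm$annotation$probe_id[norm$annotation$probe_class == "endogenous"]
  lv_endo <- lv[endo, , drop = FALSE]
  arms <- split(norm$design$sample_id, norm$design$arm)
  out <- purrr::imap(arms, function(samples, arm) {
    zres <- probe_zscores(lv_endo, samples)
    tab <- call_hits(zres, lv_endo, norm$design, thresholds,
                     background = norm$background,
                     norm_values = norm$values)
    tab$arm <- arm
    tab
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("hit_table", class(res))
  attr(res, "thresholds") <- thresholds
  res
}

#' Linear fold change of each sample against the control group
#'
#' Computes, per probe and sample, `(value + pseudocount) /
#' (control-group mean value + pseudocount)` on the normalized scale, with a
#' two-fold-or-more flag (`>= 2`).
#'
#' @param norm A `normalized_matrix`.
#' @param reference_group Value of the design `group` column defining the
#'   reference samples; must be non-empty.
#' @param pseudocount Offset guarding zeros.
#' @return Tibble with `probe_id`, `sample_id`, `fold_change`, `fc_ge2`.
#' @export
fold_change_vs_controls <- function(norm, reference_group = "control",
                                    pseudocount = 1) {
  stopifnot(inherits(norm, "normalized_matrix"))
  assert_scalar_number(pseudocount, "pseudocount")
  ref_samples <- norm$design$sample_id[norm$design$group == reference_group]
  if (!length(ref_samples)) {
    abort(sprintf("Reference group '%s' is empty.", reference_group))
  }
  ref_mean <- rowMeans(norm$values[, ref_samples, drop = FALSE])
  fc <- (norm$values + pseudocount) / (ref_mean + pseudocount)
  tibble(
    probe_id = rep(rownames(fc), times = ncol(fc)),
    sample_id = rep(colnames(fc), each = nrow(fc)),
    fold_change = as.vector(fc),
    fc_ge2 = as.vector(fc) >= 2
  )
}
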