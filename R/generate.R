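#' Simulate an arrayed perturbation screen read out by molecular counting
#'
#' Generates a probe-by-sample count matrix that mimics a NanoString-style
#' arrayed screen of tissue-restricted genes: low-baseline endogenous probes,
#' three high-count housekeeping probes, a six-step geometric positive
#' spike-in ladder, negative-control probes near zero, per-sample (lane)
#' technical factors, and a handful of planted multiplicative inductions
#' ("hits") with known location and effect size.
#'
#' Counts are negative-binomial with mean
#' `lane_factor * probe_baseline * effect` and size `dispersion`, the
#' standard overdispersed model for digital counting data. Lane factors are
#' log-normal with `sdlog = 0.2`. Endogenous baselines are scattered
#' two-fold around `baseline_low`; housekeeping baselines sit near 5000,
#' negative controls near 2, and the spike ladder uses relative levels
#' 128, 32, 8, 2, 0.5, 0.125.
#'
#' @param n_endogenous Number of endogenous (tissue-restricted) probes.
#' @param n_perturbations Number of perturbation samples (one per well).
#' @param n_controls Number of control wells.
#' @param n_hits Number of planted probe/perturbation inductions.
#' @param hit_effect Multiplicative induction of a planted hit (> 1).
#' @param baseline_low Center of the endogenous baseline means (counts).
#' @param dispersion Negative-binomial size parameter (> 0).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list with `experiment` (a [count_experiment()]) and `truth`, a
#'   list holding `planted_hits` (tibble of probe_id, perturbation_id,
#'   sample_id, effect), `lane_factors`, `dispersion` and `baseline_means`.
#' @examples
#' sim <- generate_screen(n_endogenous = 6, n_perturbations = 10, seed = 1)
#' sim$truth$planted_hits
#' @export
generate_screen <- function(n_endogenous = 42, n_perturbations = 160,
                            n_controls = 12, n_hits = 3, hit_effect = 8,
                            baseline_low = 20, dispersion = 10, seed) {
  n_endogenous <- assert_count(n_endogenous, "n_endogenous", 1L)
  n_perturbations <- assert_count(n_perturbations, "n_perturbations", 1L)
  n_controls <- assert_count(n_controls, "n_controls", 1L)
  n_hits <- assert_count(n_hits, "n_hits", 0L)
  assert_scalar_number(hit_effect, "hit_effect")
  if (hit_effect <= 1) abort("`hit_effect` must be > 1 (multiplicative induction).")
  assert_scalar_number(dispersion, "dispersion", positive = TRUE)
  assert_scalar_number(baseline_low, "baseline_low", positive = TRUE)
  if (n_hits > n_endogenous * n_perturbations) {
    abort("`n_hits` cannot exceed n_endogenous * n_perturbations.")
  }
  seed <- assert_count(seed, "seed")
  withr::local_seed(seed)

  endo_ids <- sprintf("ENDO_%03d", seq_len(n_endogenous))
  hk_ids <- c("PGK1", "TBP", "TUBB2A")
  spike_levels <- c(128, 32, 8, 2, 0.5, 0.125)
  pos_ids <- sprintf("POS_%s", LETTERS[seq_along(spike_levels)])
  neg_ids <- sprintf("NEG_%s", LETTERS[1:8])
  probe_ids <- c(endo_ids, hk_ids, pos_ids, neg_ids)

  annotation <- tibble(
    probe_id = probe_ids,
    target_gene = c(sprintf("GENE_%03d", seq_len(n_endogenous)), hk_ids,
                    pos_ids, neg_ids),
    probe_class = c(rep("endogenous", n_endogenous),
                    rep("housekeeping", 3L),
                    rep("positive_spike", length(spike_levels)),
                    rep("negative_spike", 8L)),
    spike_level = c(rep(NA_real_, n_endogenous + 3L), spike_levels,
                    rep(NA_real_, 8L))
  )

  ctrl_ids <- sprintf("CTRL_%02d", seq_len(n_controls))
  pert_ids <- sprintf("PERT_%03d", seq_len(n_perturbations))
  sample_ids <- c(ctrl_ids, pert_ids)
  design <- tibble(
    sample_id = sample_ids,
    perturbation_id = c(rep("control", n_controls), pert_ids),
    arm = "sirna",
    group = c(rep("control", n_controls), rep("perturbed", n_perturbations))
  )

  baselines <- c(
    baseline_low * 2^runif(n_endogenous, -1, 1), # scattered low baselines
    rep(5000, 3L),
    spike_levels * 400,                          # ladder well clear of zero
    rep(2, 8L)
  )
  names(baselines) <- probe_ids
  lane <- exp(rnorm(length(sample_ids), 0, 0.2))
  names(lane) <- sample_ids

  mu <- outer(baselines, lane)
  planted <- tibble(probe_id = character(), perturbation_id = character(),
                    sample_id = character(), effect = numeric())
  if (n_hits > 0L) {
    pair_idx <- sample.int(n_endogenous * n_perturbations, n_hits)
    p_row <- ((pair_idx - 1L) %% n_endogenous) + 1L
    s_col <- ((pair_idx - 1L) %/% n_endogenous) + 1L
    planted <- tibble(probe_id = endo_ids[p_row],
                      perturbation_id = pert_ids[s_col],
                      sample_id = pert_ids[s_col],
                      effect = hit_effect)
    mu[cbind(match(planted$probe_id, probe_ids),
             match(planted$sample_id, sample_ids))] <-
      mu[cbind(match(planted$probe_id, probe_ids),
               match(planted$sample_id, sample_ids))] * hit_effect
  }

  # Endogenous probes carry the negative-binomial overdispersion; control
  # probes (housekeeping, spikes) are near-Poisson at their count scale, as
  # technical replicates of counting controls are in practice -- this is what
  # lets control-based normalization remove lane factors rather than add
  # control-probe noise.
  counts <- matrix(0L, nrow = nrow(mu), ncol = ncol(mu),
                   dimnames = list(probe_ids, sample_ids))
  endo <- seq_len(n_endogenous)
  counts[endo, ] <- rnbinom(length(endo) * ncol(mu),
                            mu = mu[endo, ], size = dispersion)
  counts[-endo, ] <- rpois(length(mu[-endo, ]), mu[-endo, ])

  list(
    experiment = count_experiment(counts, annotation, design),
    truth = list(planted_hits = planted, lane_factors = lane,
                 dispersion = dispersion, baseline_means = baselines)
  )
}

#' Simulate a three-condition expression experiment for signature derivation
#'
#' Generates log2-scale expression for a control / treated /
#' treated-plus-inhibitor design with known response classes: among
#' `n_responsive` treatment-induced genes, `n_dependent` lose their
#' induction under the inhibitor, `n_repressed` are induced more strongly
#' under the inhibitor, and the remainder respond equally in both
#' conditions. The default class sizes (190 dependent, 155 repressed, and
#' hence 171 independent of 516 responsive) reproduce the canonical
#' three-way split of a TGF-beta response partitioned by kinase-inhibitor
#' dependence.
#'
#' Expression is `baseline + condition effect + Normal(0, noise_sd)` on the
#' log2 scale. Treatment effects are drawn uniformly from `effect_range`
#' (log2 units; the lower end, 2, corresponds to four-fold induction, typical
#' of strongly responsive genes). Dependent genes have inhibitor-condition
#' effect 0; repressed genes have it amplified by +1.2 log2 units
#' (~2.3-fold potentiation); independent genes keep the same effect.
#'
#' @param n_genes Total genes.
#' @param n_responsive,n_dependent,n_repressed Truth class sizes; must
#'   satisfy `n_dependent + n_repressed <= n_responsive <= n_genes`.
#' @param n_reps Replicates per condition.
#' @param noise_sd Residual log2 standard deviation.
#' @param effect_range Range (log2) of treatment effects for responsive genes.
#' @param seed Integer seed.
#' @return A list with `expr` (gene x sample log2 matrix), `design` (tibble
#'   `sample_id`, `group` in control / treated / treated_inhibitor) and
#'   `truth` (tibble `gene_id`, `class`, `effect_t`, `effect_ti`).
#' @export
generate_three_condition_experiment <- function(n_genes = 2000,
                                                n_responsive = 516,
                                                n_dependent = 190,
                                                n_repressed = 155,
                                                n_reps = 3,
                                                noise_sd = 0.25,
                                                effect_range = c(2, 4),
                                                seed) {
  n_genes <- assert_count(n_genes, "n_genes", 1L)
  n_responsive <- assert_count(n_responsive, "n_responsive", 0L)
  n_dependent <- assert_count(n_dependent, "n_dependent", 0L)
  n_repressed <- assert_count(n_repressed, "n_repressed", 0L)
  n_reps <- assert_count(n_reps, "n_reps", 2L)
  if (n_dependent + n_repressed > n_responsive || n_responsive > n_genes) {
    abort("Need n_dependent + n_repressed <= n_responsive <= n_genes.")
  }
  seed <- assert_count(seed, "seed")
  withr::local_seed(seed)

  gene_ids <- sprintf("GENE_%04d", seq_len(n_genes))
  n_independent <- n_responsive - n_dependent - n_repressed
  class <- rep("not_responsive", n_genes)
  resp_idx <- if (n_responsive > 0) sample.int(n_genes, n_responsive) else integer()
  class[resp_idx] <- rep(c("dependent", "repressed", "independent"),
                         c(n_dependent, n_repressed, n_independent))

  effect_t <- numeric(n_genes)
  effect_t[resp_idx] <- runif(n_responsive, effect_range[1L], effect_range[2L])
  effect_ti <- effect_t
  effect_ti[class == "dependent"] <- 0
  effect_ti[class == "repressed"] <- effect_t[class == "repressed"] + 1.2

  groups <- rep(c("control", "treated", "treated_inhibitor"), each = n_reps)
  sample_ids <- paste0(rep(c("ctl", "trt", "ti"), each = n_reps),
                       "_", rep(seq_len(n_reps), 3L))
  baseline <- runif(n_genes, 5, 10)
  shift <- cbind(0, effect_t, effect_ti)[, rep(1:3, each = n_reps), drop = FALSE]
  expr <- baseline + shift +
    matrix(rnorm(n_genes * length(sample_ids), 0, noise_sd), nrow = n_genes)
  dimnames(expr) <- list(gene_ids, sample_ids)

  list(
    expr = expr,
    design = tibble(sample_id = sample_ids, group = groups),
    truth = tibble(gene_id = gene_ids, class = class,
                   effect_t = effect_t, effect_ti = effect_ti)
  )
}

#' Simulate a tumor/normal expression cohort with a latent activation factor
#'
#' Generates a gene-by-sample count cohort in which each tumor carries a
#' latent pathway-activation level `a_t ~ Normal(0, 1)` loading on a set of
#' signature genes, one positively coupled marker gene (the stratification
#' target, an ADAM12-like readout) and one negatively coupled marker (a
#' KAT2A-like repressor readout). Normal samples have activation 0. Counts
#' are Poisson around `2^(log2 mean) * library_factor`, with log-normal
#' library size factors (`sdlog = 0.3`) and per-entry log-normal biological
#' noise (`noise_sd` on the log2 scale), so overdispersion enters through
#' the latent mean.
#'
#' @param n_genes Genes in the matrix, including the two marker genes.
#' @param n_signature Signature genes (loadings drawn Uniform(0.5, 1.5)).
#' @param n_normal,n_tumor Cohort sizes.
#' @param coupling Strength of the marker coupling to `a_t` (log2 units per
#'   activation SD). Non-positive values are legitimate (a warning notes the
#'   sign convention).
#' @param noise_sd Per-entry log2 biological noise SD.
#' @param seed Integer seed.
#' @return A list with `experiment` (a [count_experiment()] with a cohort
#'   arm and groups normal/tumor), `signature` (a [gene_signature()]),
#'   `target_gene`, `anti_gene`, and `truth` (list with `activation` per
#'   tumor, `loadings`, `target_coupling`, `anti_coupling`,
#'   `library_factors`).
#' @export
generate_cohort <- function(n_genes = 3000, n_signature = 190,
                            n_normal = 112, n_tumor = 500,
                            coupling = 1.0, noise_sd = 0.5, seed) {
  n_genes <- assert_count(n_genes, "n_genes", 3L)
  n_signature <- assert_count(n_signature, "n_signature", 1L)
  n_normal <- assert_count(n_normal, "n_normal", 2L)
  n_tumor <- assert_count(n_tumor, "n_tumor", 1L)
  assert_scalar_number(coupling, "coupling")
  assert_scalar_number(noise_sd, "noise_sd")
  if (n_signature >= n_genes - 1L) {
    abort("`n_signature` must leave room for the two marker genes.")
  }
  if (coupling <= 0) {
    warn("`coupling` <= 0: markers will not be positively/negatively coupled as usual.")
  }
  seed <- assert_count(seed, "seed")
  withr::local_seed(seed)

  gene_ids <- sprintf("GENE_%04d", seq_len(n_genes - 2L))
  target_gene <- "TARGET_MARKER"
  anti_gene <- "ANTI_MARKER"
  all_ids <- c(gene_ids, target_gene, anti_gene)
  sig_ids <- sample(gene_ids, n_signature)

  normal_ids <- sprintf("NORM_%03d", seq_len(n_normal))
  tumor_ids <- sprintf("TUM_%03d", seq_len(n_tumor))
  sample_ids <- c(normal_ids, tumor_ids)

  activation <- c(rep(0, n_normal), rnorm(n_tumor))
  names(activation) <- sample_ids
  loadings <- runif(n_signature, 0.5, 1.5)
  names(loadings) <- sig_ids

  baseline <- c(runif(n_genes - 2L, 4, 9), 7, 7)
  names(baseline) <- all_ids

  log2_mean <- matrix(baseline, nrow = n_genes, ncol = length(sample_ids),
                      dimnames = list(all_ids, sample_ids))
  log2_mean[sig_ids, ] <- log2_mean[sig_ids, ] + outer(loadings, activation)
  log2_mean[target_gene, ] <- log2_mean[target_gene, ] + coupling * activation
  log2_mean[anti_gene, ] <- log2_mean[anti_gene, ] - coupling * activation
  log2_mean <- log2_mean + matrix(rnorm(length(log2_mean), 0, noise_sd),
                                  nrow = n_genes)

  lib <- exp(rnorm(length(sample_ids), 0, 0.3))
  names(lib) <- sample_ids
  mu <- sweep(2^log2_mean, 2, lib, `*`)
  counts <- matrix(rpois(length(mu), mu), nrow = n_genes,
                   dimnames = list(all_ids, sample_ids))

  annotation <- tibble(probe_id = all_ids, target_gene = all_ids,
                       probe_class = "endogenous", spike_level = NA_real_)
  design <- tibble(
    sample_id = sample_ids,
    perturbation_id = "none",
    arm = "cohort",
    group = c(rep("normal", n_normal), rep("tumor", n_tumor))
  )

  list(
    experiment = count_experiment(counts, annotation, design),
    signature = gene_signature("SYN_ACTIVATION_SIG", sig_ids),
    target_gene = target_gene,
    anti_gene = anti_gene,
    truth = list(activation = activation[tumor_ids], loadings = loadings,
                 target_coupling = coupling, anti_coupling = -coupling,
                 library_factors = lib)
  )
}
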