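# Small hand-buildable fixtures used across test files.

# A minimal valid screen experiment: `endo` is an endogenous probe x sample
# integer matrix; control probes are filled in deterministically so that
# normalization factors are exactly 1 unless `pos`/`hk` columns are given.
toy_experiment <- function(endo,
                           pos = NULL, hk = NULL, neg = NULL,
                           perturbation_id = NULL, group = NULL,
                           arm = "sirna") {
  n_s <- ncol(endo)
  samples <- colnames(endo)
  if (is.null(pos)) pos <- matrix(rep(c(800L, 200L), n_s), nrow = 2,
                                  dimnames = list(NULL, samples))
  if (is.null(hk)) hk <- matrix(rep(5000L, n_s), nrow = 1,
                                dimnames = list(NULL, samples))
  if (is.null(neg)) neg <- matrix(rep(c(1L, 2L, 3L), n_s), nrow = 3,
                                  dimnames = list(NULL, samples))
  rownames(pos) <- sprintf("POS_%d", seq_len(nrow(pos)))
  rownames(hk) <- sprintf("HK_%d", seq_len(nrow(hk)))
  rownames(neg) <- sprintf("NEG_%d", seq_len(nrow(neg)))
  counts <- rbind(endo, pos, hk, neg)
  storage.mode(counts) <- "integer"
  annotation <- tibble::tibble(
    probe_id = rownames(counts),
    target_gene = rownames(counts),
    probe_class = rep(c("endogenous", "positive_spike", "housekeeping",
                        "negative_spike"),
                      c(nrow(endo), nrow(pos), nrow(hk), nrow(neg))),
    spike_level = c(rep(NA_real_, nrow(endo)), 2^seq_len(nrow(pos)),
                    rep(NA_real_, nrow(hk) + nrow(neg)))
  )
  if (is.null(perturbation_id)) {
    perturbation_id <- c("control", samples[-1])
  }
  if (is.null(group)) {
    group <- ifelse(perturbation_id == "control", "control", "perturbed")
  }
  design <- tibble::tibble(sample_id = samples,
                           perturbation_id = perturbation_id,
                           arm = arm, group = group)
  count_experiment(counts, annotation, design)
}

# Independent Welch t oracle, straight from the textbook formulas.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(b) - mean(a)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# Standard Gumbel sampler by inverse CDF.
rgumbel <- function(n, mu = 0, beta = 1) mu - beta * log(-log(runif(n)))
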