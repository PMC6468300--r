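test_that("identical control summaries give unit factors and untouched values", {
  endo <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
                 dimnames = list(c("E1", "E2", "E3"), c("s1", "s2", "s3")[1:2]))
  x <- toy_experiment(endo)
  norm <- normalize_counts(x)
  expect_equal(unname(norm$pos_factors), c(1, 1))
  expect_equal(unname(norm$hk_factors), c(1, 1))
  expect_equal(norm$values, x$counts + 0)
})

test_that("a sample scaled two-fold is normalized back onto the others", {
  # sample B doubles every probe of sample A
  endo <- matrix(c(10L, 40L, 20L, 80L), ncol = 2,
                 dimnames = list(c("E1", "E2"), c("A", "B")))
  pos <- matrix(c(800L, 200L, 1600L, 400L), ncol = 2)
  hk <- matrix(c(5000L, 10000L), ncol = 2)
  neg <- matrix(c(1L, 2L, 2L, 4L), ncol = 2)
  x <- toy_experiment(endo, pos = pos, hk = hk, neg = neg)
  norm <- normalize_counts(x)
  # factors average exactly one and undo the 2x: A gets 4/3, B gets 2/3
  f <- norm$pos_factors * norm$hk_factors
  expect_equal(mean(norm$pos_factors), 1)
  expect_equal(mean(norm$hk_factors), 1)
  expect_equal(unname(f[["A"]] / f[["B"]]), 2)
  expect_equal(norm$values[c("E1", "E2"), "A"],
               norm$values[c("E1", "E2"), "B"])
})

test_that("normalization is scale-equivariant per sample", {
  sim <- generate_screen(n_endogenous = 8, n_perturbations = 10, seed = 21)
  x <- sim$experiment
  norm0 <- normalize_counts(x)
  counts2 <- x$counts
  counts2[, 3] <- counts2[, 3] * 3L
  x2 <- count_experiment(counts2, x$annotation, x$design)
  norm2 <- normalize_counts(x2)
  endo <- x$annotation$probe_id[x$annotation$probe_class == "endogenous"]
  # a per-sample technical scaling is absorbed entirely by that sample'"'"'s
  # factors: normalized values agree across the whole matrix up to the
  # single global rescaling constant of the factor normalization
  ratio <- norm2$values[endo, ] / norm0$values[endo, ]
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
  # so z-scores, which are location/scale-free per probe on the log2 scale,
  # are exactly invariant once the pseudocount is scaled along
  lr <- log2(ratio[1, 1])
  expect_equal(probe_zscores(log2(norm2$values + 2^lr))$z[endo, ],
               probe_zscores(log2(norm0$values + 1))$z[endo, ],
               tolerance = 1e-9)
})

test_that("normalization reduces housekeeping variability below half of raw", {
  sim <- generate_screen(seed = 31)
  x <- sim$experiment
  norm <- normalize_counts(x)
  hk <- x$annotation$probe_id[x$annotation$probe_class == "housekeeping"]
  cv <- function(v) sd(v) / mean(v)
  raw_cv <- apply(x$counts[hk, ], 1, cv)
  norm_cv <- apply(norm$values[hk, ], 1, cv)
  expect_true(all(norm_cv < raw_cv / 2))
})

test_that("zero counts in control probes fail with probe and sample named", {
  endo <- matrix(c(5L, 5L), ncol = 2,
                 dimnames = list("E1", c("sA", "sB")))
  pos <- matrix(c(800L, 0L, 820L, 210L), ncol = 2)
  x <- toy_experiment(endo, pos = pos)
  err <- expect_error(normalize_counts(x), "positive_spike")
  expect_match(conditionMessage(err), "POS_2/sA")
})

test_that("log2 levels apply the pseudocount elementwise", {
  m <- matrix(c(0, 7, 1, 3, 15, 31), nrow = 2)
  expect_equal(log2_levels(m, pseudocount = 1),
               log2(m + 1))
  expect_equal(log2_levels(matrix(c(1, 3, 15), 1), 1)[1, ], c(1, 2, 4))
  expect_error(log2_levels(m, pseudocount = 0), "pseudocount")
})

test_that("probe z-scores match the hand-computed example", {
  m <- matrix(c(1, 1, 1, 1, 6), nrow = 1,
              dimnames = list("P", paste0("s", 1:5)))
  z <- probe_zscores(m)
  expect_equal(unname(z$mean), 2)
  expect_equal(unname(z$sd), sqrt(5))
  expect_equal(unname(z$z[1, "s5"]), 4 / sqrt(5), tolerance = 1e-12)
  expect_equal(unname(z$z[1, "s1"]), -1 / sqrt(5), tolerance = 1e-12)
})

test_that("z-scores standardize each probe to mean 0, sd 1", {
  sim <- generate_screen(n_endogenous = 12, n_perturbations = 30, seed = 41)
  lv <- log2_levels(normalize_counts(sim$experiment))
  z <- probe_zscores(lv)
  ok <- !z$sd_zero
  expect_true(all(abs(rowMeans(z$z[ok, ])) < 1e-9))
  expect_true(all(abs(apply(z$z[ok, ], 1, sd) - 1) < 1e-9))
})

test_that("constant probes are flagged, small arms are an error", {
  m <- rbind(P1 = c(2, 2, 2, 2), P2 = c(1, 2, 3, 4))
  colnames(m) <- paste0("s", 1:4)
  z <- probe_zscores(m)
  expect_true(z$sd_zero[["P1"]])
  expect_true(all(is.na(z$z["P1", ])))
  expect_false(any(is.na(z$z["P2", ])))
  expect_error(probe_zscores(m[, 1:2]), ">= 3 samples")
})

test_that("z-to-p reproduces the standard normal tails", {
  expect_equal(z_to_pvalue(0), 0.5)
  expect_equal(signif(z_to_pvalue(3.12), 2), 9.0e-4)
  expect_equal(signif(z_to_pvalue(2.53), 2), 5.7e-3)
  expect_lt(z_to_pvalue(8.47), 1e-5)
  # 3.5 sigma two-tailed is 0.05% to two decimals in percent
  expect_equal(round(100 * z_to_pvalue(3.5, tails = "two"), 2), 0.05)
  expect_equal(z_to_pvalue(1.3, "two"), 2 * z_to_pvalue(1.3))
  expect_error(z_to_pvalue(Inf), "finite")
})

test_that("hit calls bracket the thresholds and respect controls", {
  endo <- matrix(0L, nrow = 2, ncol = 12,
                 dimnames = list(c("E1", "E2"), sprintf("s%02d", 1:12)))
  endo[] <- 20L
  x <- toy_experiment(endo,
                      perturbation_id = c("control", "control",
                                          sprintf("pert%02d", 3:12)))
  lv <- log2_levels(normalize_counts(x))
  # construct z directly: single pair at exactly 3.0
  zres <- probe_zscores(rbind(lv, FAKE = c(rep(0, 11), 1)))
  tab <- call_hits(zres, rbind(lv, FAKE = c(rep(0, 11), 1)), x$design)
  expect_s3_class(tab, "hit_table")
  expect_true(all(tab$hit_2p5[tab$hit_3p5]))

  # all-zero z table yields no hits at either threshold
  expect_identical(sum(tab$hit_3p5), 0L)

  # a z just above 2.5 but below 3.5 is a 2.5-only hit
  z2 <- list(z = matrix(c(rep(-0.5, 11), 3.0), nrow = 1,
                        dimnames = list("E1", colnames(endo))),
             sd_zero = c(E1 = FALSE))
  tab2 <- call_hits(z2, lv["E1", , drop = FALSE], x$design)
  expect_identical(sum(tab2$hit_2p5), 1L)
  expect_identical(sum(tab2$hit_3p5), 0L)
  expect_identical(tab2$sample_id[tab2$hit_2p5], "s12")

  # control samples are scored but never called
  z3 <- list(z = matrix(c(5, rep(-0.4, 11)), nrow = 1,
                        dimnames = list("E1", colnames(endo))),
             sd_zero = c(E1 = FALSE))
  tab3 <- call_hits(z3, lv["E1", , drop = FALSE], x$design)
  expect_identical(sum(tab3$hit_2p5), 0L)
  expect_equal(tab3$z[tab3$sample_id == "s01"], 5)

  expect_error(call_hits(z3, lv, x$design, thresholds = c(3, 2)),
               "increasing")
})

test_that("planted screen hits are recovered at the lower threshold", {
  recovered <- vapply(1:5, function(s) {
    sim <- generate_screen(seed = 200 + s)
    hits <- screen_hits(sim$experiment)
    called <- paste(hits$probe_id, hits$sample_id)[hits$hit_2p5]
    truth <- paste(sim$truth$planted_hits$probe_id,
                   sim$truth$planted_hits$sample_id)
    all(truth %in% called)
  }, logical(1))
  expect_true(all(recovered))
})

test_that("normality flags come from a per-probe Shapiro test", {
  sim <- generate_screen(n_endogenous = 6, n_perturbations = 40, seed = 51)
  hits <- screen_hits(sim$experiment)
  lv <- log2_levels(normalize_counts(sim$experiment))
  p1 <- shapiro.test(lv["ENDO_001", ])$p.value
  flag <- unique(hits$probe_normal[hits$probe_id == "ENDO_001"])
  expect_identical(flag, p1 > 0.05)
})

test_that("fold changes against controls match hand computation", {
  endo <- matrix(c(10L, 10L, 10L, 25L), ncol = 2,
                 dimnames = list(c("E1", "E2"), c("ctl", "trt")))
  x <- toy_experiment(endo)
  norm <- normalize_counts(x)
  fc <- fold_change_vs_controls(norm)
  # control sample equals the control mean: fold change 1, flag off
  expect_equal(fc$fold_change[fc$probe_id == "E1" & fc$sample_id == "ctl"], 1)
  expect_false(fc$fc_ge2[fc$probe_id == "E1" & fc$sample_id == "ctl"])
  # control mean 10, sample 25, pseudocount 1 -> 26/11
  expect_equal(fc$fold_change[fc$probe_id == "E2" & fc$sample_id == "trt"],
               26 / 11)
  expect_true(fc$fc_ge2[fc$probe_id == "E2" & fc$sample_id == "trt"])
  expect_error(fold_change_vs_controls(norm, reference_group = "nope"),
               "empty")
})

test_that("a constructed positive control trips exactly the built flags", {
  # 42 endogenous probes, 38 of them at 4x baseline in the test sample
  base <- rep(40L, 42)
  endo <- cbind(ctl1 = base, ctl2 = base,
                pos = c(base[1:38] * 4L, base[39:42]))
  rownames(endo) <- sprintf("E%02d", 1:42)
  x <- toy_experiment(endo, perturbation_id = c("control", "control", "mix"))
  fc <- fold_change_vs_controls(normalize_counts(x))
  flags <- fc$fc_ge2[fc$sample_id == "pos"]
  expect_identical(sum(flags), 38L)
})
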