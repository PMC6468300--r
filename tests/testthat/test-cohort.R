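test_that("size factors match the two-sample median-of-ratios oracle", {
  m <- cbind(A = c(2, 8), B = c(4, 16))
  rownames(m) <- c("g1", "g2")
  f <- size_factors(m)
  # geometric means (2.828, 11.314); all ratios 1/sqrt(2) for A, sqrt(2) for B
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(f[["B"]] / f[["A"]]), 2, tolerance = 1e-12)
  norm <- normalize_cohort(m, f)
  expect_equal(norm[, "A"], norm[, "B"])

  # identical samples: all factors 1
  m2 <- cbind(s1 = c(5, 9, 2), s2 = c(5, 9, 2), s3 = c(5, 9, 2))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
})

test_that("size factors agree with DESeq2's implementation", {
  skip_if_not_installed("DESeq2")
  sim <- generate_cohort(n_genes = 300, n_signature = 40, n_normal = 10,
                         n_tumor = 40, seed = 77)
  counts <- sim$experiment$counts
  ours <- size_factors(counts)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("size factors are exactly equivariant to per-sample scaling", {
  sim <- generate_cohort(n_genes = 120, n_signature = 15, n_normal = 6,
                         n_tumor = 20, seed = 78)
  counts <- sim$experiment$counts
  # keep the reference-gene set unchanged: scaling up a sample keeps nonzeros
  f0 <- size_factors(counts)
  counts2 <- counts
  counts2[, 4] <- counts2[, 4] * 5L
  f2 <- size_factors(counts2)
  # factors are defined up to a common constant (the geometric means absorb
  # 5^(1/n)); relative to any other sample the scaled sample moves by exactly 5
  expect_equal(unname((f2[4] / f2[1]) / (f0[4] / f0[1])), 5,
               tolerance = 1e-12)
  expect_equal(unname(f2[-4] / f0[-4]),
               rep(unname(f2[1] / f0[1]), ncol(counts) - 1),
               tolerance = 1e-12)

  zero_mat <- matrix(c(0L, 1L, 2L, 0L), 2,
                     dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(size_factors(zero_mat), "filter")
})

test_that("size factors recover the generating library factors", {
  r <- vapply(1:3, function(s) {
    sim <- generate_cohort(n_genes = 500, n_signature = 50, n_normal = 20,
                           n_tumor = 60, seed = 500 + s)
    cor(size_factors(sim$experiment$counts), sim$truth$library_factors)
  }, numeric(1))
  expect_true(all(r >= 0.99))
})

test_that("decile strata have the documented sizes and tie behaviour", {
  v <- setNames(rnorm(100), sprintf("t%03d", 1:100))
  s <- stratify_deciles(v)
  expect_identical(sum(s$stratum == "low_decile"), 10L)
  expect_identical(sum(s$stratum == "high_decile"), 10L)
  expect_identical(sum(s$stratum == "mid"), 80L)
  # the extremes really are the extremes
  expect_true(max(s$target_value[s$stratum == "low_decile"]) <=
                min(s$target_value[s$stratum == "mid"]))

  s10 <- stratify_deciles(setNames(1:10, letters[1:10]))
  expect_identical(sum(s10$stratum == "low_decile"), 1L)
  expect_identical(sum(s10$stratum == "high_decile"), 1L)

  expect_error(stratify_deciles(setNames(1:9, letters[1:9])), ">= 10")

  # fully tied values: deterministic strata by stable order, with a warning
  tied <- setNames(rep(1, 20), sprintf("s%02d", 1:20))
  expect_warning(st <- stratify_deciles(tied), "Ties")
  expect_identical(st$sample_id[st$stratum == "low_decile"],
                   sprintf("s%02d", 1:2))
  expect_identical(st$sample_id[st$stratum == "high_decile"],
                   sprintf("s%02d", 19:20))
})

test_that("decile stratification is permutation-invariant on distinct values", {
  v <- setNames(sample(rnorm(40)), sprintf("t%02d", 1:40))
  s1 <- stratify_deciles(v)
  perm <- sample(length(v))
  s2 <- stratify_deciles(v[perm])
  merged <- merge(as.data.frame(s1), as.data.frame(s2), by = "sample_id")
  expect_identical(as.character(merged$stratum.x),
                   as.character(merged$stratum.y))
})

test_that("activation scores match hand computation and are additive", {
  m <- cbind(n1 = c(10, 10, 10), n2 = c(10, 10, 10),
             t1 = c(20, 40, 10), t2 = c(10, 10, 10))
  rownames(m) <- c("g1", "g2", "g3")
  sc <- activation_score(m, c("g1", "g2", "g3"), c("n1", "n2"),
                         c("t1", "t2"), pseudocount = 0)
  expect_equal(sc$activation_score[sc$sample_id == "t1"], 1 + 2 + 0)
  # a tumor at the normal mean scores zero
  expect_equal(sc$activation_score[sc$sample_id == "t2"], 0)

  # additivity over a disjoint signature partition (log2 scale)
  s12 <- activation_score(m, c("g1", "g2"), c("n1", "n2"), "t1",
                          pseudocount = 0)
  s3 <- activation_score(m, "g3", c("n1", "n2"), "t1", pseudocount = 0)
  expect_equal(s12$activation_score + s3$activation_score,
               sc$activation_score[sc$sample_id == "t1"])

  # linear scale sums raw ratios
  lin <- activation_score(m, c("g1", "g2", "g3"), c("n1", "n2"), "t1",
                          scale = "linear", pseudocount = 0)
  expect_equal(lin$activation_score, 2 + 4 + 1)

  # absent genes are skipped and reported; all-absent is an error
  expect_message(
    sk <- activation_score(m, c("g1", "nope"), c("n1", "n2"), "t1",
                           pseudocount = 0),
    "nope")
  expect_equal(sk$activation_score, 1)
  expect_error(activation_score(m, "nope", c("n1", "n2"), "t1"), "signature")
})

test_that("activation scores recover the latent activation factor", {
  sim <- generate_cohort(n_genes = 800, n_signature = 80, n_normal = 20,
                         n_tumor = 100, seed = 91)
  v <- normalize_cohort(sim$experiment$counts)
  d <- sim$experiment$design
  sc <- activation_score(v, sim$signature,
                         d$sample_id[d$group == "normal"],
                         d$sample_id[d$group == "tumor"])
  expect_gte(cor(sc$activation_score, sim$truth$activation), 0.9)
})

test_that("Ward clustering matches the closed-form small-case oracle", {
  m <- matrix(c(0, 0.1, 10, 10.1), nrow = 1,
              dimnames = list("g", c("a", "b", "c", "d")))
  res <- cluster_samples(m, k_groups = 2, log2_transform = FALSE,
                         reference_labels = c(1, 1, 2, 2))
  # first two merges join the tight pairs at their Euclidean distances
  expect_equal(res$hclust$height[1:2], c(0.1, 0.1))
  # final Ward.D2 merge: sqrt(2 * 2 * 2 / 4) * centroid distance
  expect_equal(res$hclust$height[3], sqrt(2) * 10, tolerance = 1e-10)
  expect_identical(unname(res$labels), c(1L, 1L, 2L, 2L))
  expect_equal(res$ari, 1)

  # two samples: a single merge at their distance
  m2 <- matrix(c(0, 3, 4, 0), nrow = 2,
               dimnames = list(c("g1", "g2"), c("x", "y")))
  res2 <- cluster_samples(m2, k_groups = 2, log2_transform = FALSE)
  expect_equal(res2$hclust$height, 5)

  expect_error(cluster_samples(m, k_groups = 9, log2_transform = FALSE),
               "exceeds")
})

test_that("Ward merge heights never decrease", {
  sim <- generate_cohort(n_genes = 200, n_signature = 30, n_normal = 10,
                         n_tumor = 30, seed = 17)
  v <- normalize_cohort(sim$experiment$counts)
  res <- cluster_samples(v[sim$signature$genes, ], k_groups = 3)
  expect_true(all(diff(res$hclust$height) >= -1e-12))
  res_d <- cluster_samples(v[sim$signature$genes, ], k_groups = 3,
                           variant = "ward.D")
  expect_true(all(diff(res_d$hclust$height) >= -1e-12))
})

test_that("dendrograms export as Newick text", {
  m <- matrix(c(0, 1, 5, 5.5), nrow = 1,
              dimnames = list("g", c("a", "b", "c", "d")))
  res <- cluster_samples(m, k_groups = 2, log2_transform = FALSE)
  nwk <- as_newick(res)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "a")
  path <- withr::local_tempfile(fileext = ".nwk")
  as_newick(res, path)
  expect_identical(readLines(path), nwk)
  expect_identical(ape::read.tree(path)$tip.label %in% c("a", "b", "c", "d"),
                   rep(TRUE, 4))
})

test_that("score-gene correlation handles exact and degenerate cases", {
  st <- tibble::tibble(sample_id = c("t1", "t2", "t3"),
                       activation_score = c(1, 2, 3))
  m <- rbind(same = 2^c(1, 2, 3) - 1, anti = 2^c(3, 2, 1) - 1,
             flat = c(4, 4, 4))
  colnames(m) <- c("t1", "t2", "t3")
  expect_equal(score_gene_correlation(st, m, "same"), 1)
  expect_equal(score_gene_correlation(st, m, "anti"), -1)
  expect_error(score_gene_correlation(st, m, "flat"), "variance")
  expect_error(score_gene_correlation(st, m, "missing"), "not in matrix")
  expect_error(score_gene_correlation(st[1:2, ], m, "same"), ">= 3")
})

test_that("clustering separates normals from extreme strata on cohort data", {
  sim <- generate_cohort(n_genes = 600, n_signature = 60, n_normal = 20,
                         n_tumor = 80, seed = 23)
  res <- score_cohort(sim$experiment, sim$signature, sim$target_gene,
                      n_draws = 50, seed = 1,
                      exclude = sim$signature$genes)
  # a reduced cohort still segregates strata cleanly (the full-scale bar of
  # 0.9 is exercised on default-size cohorts in the acceptance suite)
  expect_gte(res$clustering$ari, 0.7)
  st <- res$score_table
  expect_identical(sum(st$stratum == "low_decile"), 8L)
  expect_identical(sum(st$stratum == "high_decile"), 8L)
  expect_identical(sum(st$stratum == "normal"), 20L)
  # high-decile tumors activate the signature more than low-decile tumors
  expect_gt(mean(st$activation_score[st$stratum == "high_decile"]),
            mean(st$activation_score[st$stratum == "low_decile"]))
})
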