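test_that("size factors: symmetry, scale equivariance, and brute force", {
  m <- tiny_counts(20, 5, seed = 2)
  same <- m; for (j in 2:5) same[, j] <- same[, 1]
  expect_equal(unname(estimate_size_factors(same)), rep(1, 5))

  dbl <- m; dbl[, 3] <- 2L * dbl[, 3]
  sf <- estimate_size_factors(dbl)
  expect_equal(unname(sf[3] / sf[1]),
               unname(estimate_size_factors(m)[3] / estimate_size_factors(m)[1]) * 2,
               tolerance = 1e-12)

  # brute-force median-of-ratios on a 50 x 6 seeded matrix
  m2 <- tiny_counts(50, 6, seed = 9)
  keep <- rowSums(m2 > 0) == 6
  geo <- exp(rowMeans(log(m2[keep, ])))
  raw <- apply(m2[keep, ], 2, function(cl) median(cl / geo))
  expect_equal(unname(estimate_size_factors(m2)),
               unname(raw / exp(mean(log(raw)))), tolerance = 1e-12)

  # gene-permutation invariance
  perm <- sample(nrow(m2))
  expect_equal(estimate_size_factors(m2), estimate_size_factors(m2[perm, ]))

  none <- m; none[1, ] <- 0L; none[cbind(2:20, rep(1, 19))] <- 0L
  expect_error(estimate_size_factors(none), "pseudo-reference")
})

test_that("vst closed-form values, monotonicity, and stabilization", {
  m <- matrix(c(0L, 7L), 1, 2, dimnames = list("g1", c("a", "b")))
  v <- vst(m, size_factors = c(a = 1, b = 1))
  expect_equal(unname(v["g1", ]), c(0, 3))
  expect_match(attr(v, "transform_tag"), "log2")

  m2 <- tiny_counts(30, 6, seed = 4)
  v2 <- vst(m2, size_factors = rep(1, 6))
  for (g in 1:5) expect_equal(order(m2[g, ]), order(v2[g, ]))
  expect_error(vst(m2, size_factors = c(1, 2)), "one size factor")

  # variance-stabilization property: SD-vs-mean slope shrinks after VST
  set.seed(10)
  mu <- 10^runif(400, 1, 4)
  nb <- t(vapply(mu, function(m) rnbinom(40, mu = m, size = 1 / 0.05),
                 numeric(40)))
  dimnames(nb) <- list(sprintf("g%d", 1:400), sprintf("s%d", 1:40))
  storage.mode(nb) <- "integer"
  slope_raw <- coef(lm(log(apply(nb, 1, sd)) ~ log(rowMeans(nb))))[2]
  vv <- vst(nb, size_factors = rep(1, 40))
  slope_vst <- coef(lm(log(apply(vv, 1, sd)) ~ log(rowMeans(nb))))[2]
  expect_lt(slope_vst, slope_raw)
})

test_that("top-variance filter keeps ceiling(fraction*G), stably", {
  m <- tiny_counts(10, 6, seed = 5)
  v <- vst(m, size_factors = rep(1, 6))
  expect_equal(nrow(filter_top_variable(v, 0.9)), 9)
  expect_identical(filter_top_variable(v, 1.0), v)
  expect_error(filter_top_variable(v, 0), "fraction")

  v100 <- vst(tiny_counts(100, 8, seed = 6), size_factors = rep(1, 8))
  kept <- rownames(filter_top_variable(v100, 0.3))
  vars <- apply(v100, 1, var)
  oracle <- rownames(v100)[order(-vars, rownames(v100))][1:30]
  expect_setequal(kept, oracle)
  # order preserved + idempotent
  expect_identical(kept, rownames(v100)[rownames(v100) %in% oracle])
  expect_identical(filter_top_variable(filter_top_variable(v100, 0.3), 1.0),
                   filter_top_variable(v100, 0.3))
})

test_that("sample PCA: duplicates, completeness, reconstruction, signs", {
  v <- vst(tiny_counts(40, 6, seed = 7), size_factors = rep(1, 6))
  v[, 2] <- v[, 1]
  p <- pca_samples(v)
  expect_equal(p$scores[1, 1], p$scores[2, 1])
  expect_equal(sum(p$variance_explained), 1)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  # reconstruction at full rank
  cent <- t(v) - colMeans(t(v))[col(t(v))]
  cent <- scale(t(v), center = TRUE, scale = FALSE)
  expect_lt(max(abs(p$scores %*% t(p$loadings) - cent)), 1e-8)
  # deterministic sign: largest-|.| loading entry positive
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_error(pca_samples(v, n_components = 50), "n_components")
})

test_that("PC1 separates a strongly divergent population", {
  ds <- fast_sim(seed = 21, n_genes = 400, module_sizes = c(50),
                 pop_effect_sd = 1)
  v <- filter_top_variable(vst(ds$counts), 0.9)
  p <- pca_samples(v, 3)
  pops <- ds$samples$population
  # silhouette of the best-separated population on PC1
  sil <- vapply(levels(pops), function(pp) {
    a <- p$scores[pops == pp, 1]; b <- p$scores[pops != pp, 1]
    (abs(mean(a) - mean(b)) - sd(a)) / max(sd(a), sd(b))
  }, numeric(1))
  expect_gt(max(sil), 0)
})

test_that("QC flags: planted swap, low-mapping ties, and disabled case", {
  ds <- fast_sim(seed = 2, n_genes = 500, module_sizes = c(50, 50),
                 pop_effect_sd = 0.5)
  v <- filter_top_variable(vst(ds$counts), 0.9)
  v[, 40] <- v[, 1]                       # plant a cross-population copy
  fl <- flag_qc_samples(pca_samples(v), ds$samples)
  expect_match(fl$qc_flags[40], "suspected_swap")
  expect_lte(sum(grepl("suspected_swap", fl$qc_flags)), 2)
  expect_equal(sum(grepl("low_mapping", fl$qc_flags)), 2)
  expect_false(40 %in% match(qc_pass(fl), fl$sample_id))

  # all-equal mapping: stable tie-break by sample id
  s2 <- ds$samples; s2$read_mapping_pct <- 0.9
  fl2 <- flag_qc_samples(pca_samples(v), s2)
  expect_identical(which(grepl("low_mapping", fl2$qc_flags)), c(1L, 2L))

  # manual exclude-list overrides
  fl3 <- flag_qc_samples(pca_samples(v), ds$samples, exclude = "S010")
  expect_match(fl3$qc_flags[fl3$sample_id == "S010"], "manual_exclude")

  s3 <- ds$samples[c(1:2, 19:36, 37:54), ]
  expect_warning(
    flag_qc_samples(pca_samples(v[, c(1:2, 19:36, 37:54)]), s3),
    "fewer than 3")
})

test_that("swap detector false-positive rate is low on null data", {
  flagged <- vapply(1:100, function(s) {
    ds <- simulate_null_dataset(sim_config(n_genes = 120,
                                           module_sizes = integer(0),
                                           n_per_cell = 3, seed = 2000 + s))
    v <- filter_top_variable(vst(ds$counts), 0.9)
    fl <- flag_qc_samples(pca_samples(v), ds$samples, k_low_mapping = 0)
    any(grepl("suspected_swap", fl$qc_flags))
  }, logical(1))
  expect_gte(mean(!flagged), 0.95)
})
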