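test_that("trait PCA: perfect block, SVD oracle, missing male blocks", {
  ds <- fast_sim(seed = 13)
  tp <- trait_pca(ds$traits)
  expect_setequal(setdiff(names(tp), "sample_id"),
                  c(t(outer(c("Fbehav", "Mbehav", "Mmorph"),
                            c("_PC1", "_PC2"), paste0))))
  ctrl <- ds$samples$treatment == "female-control"
  expect_true(all(is.na(tp$Mmorph_PC1[ctrl])))
  expect_true(all(is.na(tp$Mbehav_PC2[ctrl])))
  expect_equal(mean(tp$Fbehav_PC1), 0, tolerance = 1e-10)
  expect_equal(mean(tp$Mmorph_PC1, na.rm = TRUE), 0, tolerance = 1e-10)

  # independent SVD oracle on the complete-case standardized Mmorph block
  x <- as.matrix(ds$traits[!ctrl, grep("Mmorph", names(ds$traits))])
  sv <- svd(scale(x))
  for (j in 1:2) {
    o <- sv$u[, j] * sv$d[j]
    expect_equal(abs(cor(tp[[paste0("Mmorph_PC", j)]][!ctrl], o)), 1,
                 tolerance = 1e-10)
  }

  # two perfectly correlated traits: PC1 carries all block variance
  tr <- data.frame(sample_id = sprintf("s%d", 1:10),
                   A_1 = rnorm(10))
  tr$A_2 <- 2 * tr$A_1 + 1
  tp2 <- trait_pca(tr)
  expect_equal(attr(tp2, "variance_explained")$A[1], 1)

  tr$A_2 <- 3
  expect_error(trait_pca(tr), "non-constant")
})

test_that("Welch t-test matches the hand-computed closed form", {
  # x = 1:4, y = 3:6: mean diff -2, each var 5/3, se = sqrt(5/6),
  # t = -2 / sqrt(5/6) = -2.190890, Satterthwaite df = 6 exactly
  w <- welch_ttest(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(w$t, -2 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(w$df, 6, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(-abs(w$t), 6), tolerance = 1e-12)

  set.seed(3); x <- rnorm(9); y <- rnorm(7, 1)
  a <- welch_ttest(x, y); b <- welch_ttest(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)

  same <- welch_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_ttest(rep(1, 4), rep(2, 4)), "zero variance")
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})

test_that("module contrasts: counting, planted shift, skipped cells", {
  ds <- fast_sim(seed = 17, n_genes = 240, module_sizes = c(60, 60),
                 pop_effect_sd = 0)
  # plant a population shift on module 1's genes
  counts <- ds$counts
  g1 <- names(ds$truth$module_of_gene)[ds$truth$module_of_gene == "M1"]
  pop1 <- ds$samples$population == levels(ds$samples$population)[1]
  counts[g1, pop1] <- counts[g1, pop1] + 400L
  eg <- module_eigengenes(vst(counts), ds$truth$module_of_gene)
  ct <- module_contrasts(eg, ds$samples)
  # 2 population contrasts + 3 treatment pairs x 3 populations, per module
  expect_equal(nrow(ct), 2 * (2 + 3 * 3))
  planted <- ct[ct$module == "M1" & ct$type == "population", ]
  expect_true(all(planted$p < 0.01))
  other <- ct[ct$module == "M2", ]
  expect_gt(min(other$p), 1e-4)

  # undersized cell: contrast skipped with a message
  keep <- !(ds$samples$population == levels(ds$samples$population)[2] &
              ds$samples$treatment == "conspecific" &
              duplicated(ds$samples$treatment) == FALSE)
  sub <- ds$samples[c(1:24, 31:54), ]
  expect_message(
    ct2 <- module_contrasts(eg[c(1:24, 31:54), , drop = FALSE], sub),
    "undersized")
  expect_lt(nrow(ct2), nrow(ct))
})

test_that("interaction model: zero-interaction, oracle coefficients, errors", {
  s <- model_samples(8)
  set.seed(21)
  trait <- rnorm(24)
  y <- 2 + 0.7 * trait                  # exact: every slope equal
  fit <- fit_interaction_model(y, s, trait)
  a <- anova_type2(fit)
  # interaction (and population) SS are exactly zero; degenerate 0/0 F maps
  # to the (0, p = 1) convention
  expect_equal(a$F[a$term == "population:trait"], 0)
  expect_equal(a$p_param[a$term == "population:trait"], 1)

  y2 <- rnorm(24) + ifelse(s$population == "B", 2, 0) + 0.5 * trait
  fit2 <- fit_interaction_model(y2, s, trait)
  X <- model.matrix(~ pop * trait,
                    data.frame(pop = factor(s$population), trait = trait))
  beta <- solve(t(X) %*% X, t(X) %*% y2)[, 1]
  expect_equal(unname(fit2$coefficients), unname(beta), tolerance = 1e-10)
  expect_equal(fit2$df_resid, 24 - 6)

  s_bad <- s; s_bad$population[s_bad$population == "C"][2:8] <- "A"
  s_bad$population <- factor(as.character(s_bad$population))
  expect_error(fit_interaction_model(y, s_bad, trait), "'C'")

  tr_na <- trait; tr_na[1:4] <- NA
  fit3 <- fit_interaction_model(y, s, tr_na)
  expect_length(fit3$sample_ids, 20)
})

test_that("type-II SS equals the lm oracle and sequential SS when balanced", {
  s <- model_samples(6)
  set.seed(31)
  trait <- rnorm(18)
  y <- rnorm(18) + 0.4 * trait + ifelse(s$population == "C", 1, 0)
  a <- anova_type2(fit_interaction_model(y, s, trait))
  o <- oracle_type2(y, s$population, trait)
  expect_equal(a$F, unname(o$F), tolerance = 1e-10)
  expect_equal(a$p_param, unname(o$p), tolerance = 1e-10)
  expect_equal(unique(a$df2), o$df2)

  # balanced design, covariate orthogonalized within populations:
  # type-II equals sequential SS from base anova()
  tr_o <- ave(trait, s$population, FUN = function(z) z - mean(z))
  a2 <- anova_type2(fit_interaction_model(y, s, tr_o))
  seq_tab <- anova(lm(y ~ pop * trait,
                      data.frame(pop = factor(s$population), trait = tr_o)))
  expect_equal(a2$F, seq_tab$`F value`[1:3], tolerance = 1e-9)
})

test_that("type-II ANOVA invariances: relabelling and trait centring", {
  s <- model_samples(5)
  set.seed(41)
  trait <- rnorm(15); y <- rnorm(15)
  a <- anova_type2(fit_interaction_model(y, s, trait))
  s2 <- s
  s2$population <- factor(s2$population,
                          levels = c("C", "A", "B"))    # relabel/reorder
  a2 <- anova_type2(fit_interaction_model(y, s2, trait))
  expect_equal(a$p_param, a2$p_param, tolerance = 1e-9)
  a3 <- anova_type2(fit_interaction_model(y, s, trait - 17.3))
  expect_equal(a$F[3], a3$F[3], tolerance = 1e-9)
})

test_that("type-II p-values are uniform under the null", {
  s <- model_samples(8)
  set.seed(51)
  trait <- rnorm(24)
  ps <- replicate(500, anova_type2(fit_interaction_model(rnorm(24), s,
                                                         trait))$p_param)
  for (i in 1:3) expect_gt(ks.test(ps[i, ], "punif")$p.value, 0.01)
})

test_that("candidate gene set and models behave per contract", {
  cg <- candidate_gene_set()
  expect_equal(nrow(cg), 24)
  expect_equal(length(unique(cg$pathway)), 5)
  expect_false(anyDuplicated(cg$symbol) > 0)

  ds <- fast_sim(seed = 19, n_genes = 200, module_sizes = c(40))
  v <- vst(ds$counts)
  # alias two rows to candidate symbols; one of them tracks the planted
  # interaction module's latent factor
  rownames(v)[150] <- "gnrh3"            # a background gene
  g_m1 <- which(ds$truth$module_of_gene == "M1")[1]
  rownames(v)[g_m1] <- "oxtr"            # tracks the interaction module
  tp <- trait_pca(ds$traits)
  res <- candidate_gene_models(v, ds$samples, tp, modules = NULL)
  expect_setequal(unique(res$gene), c("gnrh3", "oxtr"))
  expect_equal(nrow(res), 2 * 6 * 3)        # gene x traitPC x term
  expect_length(attr(res, "unmapped"), 22)
  oxtr_int <- res[res$gene == "oxtr" & res$trait == "Mmorph_PC1" &
                    res$term == "population:trait", ]
  expect_lt(oxtr_int$p_param, 0.05)
})

test_that("DE emulator: null log2FC, BH property, exclusions", {
  ds <- simulate_null_dataset(sim_config(n_genes = 150,
                                         module_sizes = integer(0), seed = 23))
  counts <- ds$counts
  counts[1, ] <- 0L
  de <- de_test(counts, ds$samples)
  expect_identical(attr(de, "excluded_genes"), rownames(counts)[1])
  sub <- de[de$contrast_type == "treatment" &
              de$contrast == de$contrast[1], ]
  expect_lt(abs(median(sub$log2FC, na.rm = TRUE)), 0.1)
  ok <- !is.na(sub$p)
  expect_true(all(sub$padj[ok] >= sub$p[ok]))
  ord <- order(sub$p[ok])
  cummax_adj <- cummax((sub$p[ok] * sum(ok) / rank(sub$p[ok]))[ord])
  expect_true(all(diff(pmin(cummax_adj, 1)) >= -1e-12))
})
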