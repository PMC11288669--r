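# Trait principal components, Welch t-test contrasts, population-by-trait
# linear models on module eigengenes (and candidate genes) with type-II
# sums-of-squares ANOVA, and a simplified negative-binomial differential
# expression test.

#' Per-block trait principal components
#'
#' Derives two PCs each for the female-behaviour (Fbehav), male-behaviour
#' (Mbehav) and male-morphology (Mmorph) measurement blocks. Within a block,
#' columns are standardized and PCs extracted by SVD on the block's
#' complete-case rows; rows with missing measurements (female-control trials
#' have no male) get `NA` scores. Signs follow the [pca_samples()]
#' convention.
#'
#' @param traits data.frame with `sample_id` and numeric columns named
#'   `<block>_<k>`.
#' @param blocks Optional named list mapping block name to column names;
#'   by default inferred from the prefix before the last underscore.
#' @param n_components PCs per block (default 2).
#' @return data.frame `sample_id` + `<block>_PC<j>` columns; per-block
#'   loadings and variance explained in attributes.
#' @export
trait_pca <- function(traits, blocks = NULL, n_components = 2) {
  stopifnot("sample_id" %in% names(traits))
  meas <- setdiff(names(traits), "sample_id")
  if (is.null(blocks)) {
    pref <- sub("_[^_]*$", "", meas)
    blocks <- split(meas, pref)
  }
  out <- data.frame(sample_id = traits$sample_id)
  loadings <- list(); varexp <- list()
  for (bl in names(blocks)) {
    cols <- blocks[[bl]]
    x <- as.matrix(traits[, cols, drop = FALSE])
    cc <- stats::complete.cases(x)
    if (sum(cc) < 3)
      stop("block '", bl, "' has fewer than 3 complete rows", call. = FALSE)
    xs <- x[cc, , drop = FALSE]
    sds <- apply(xs, 2, stats::sd)
    if (sum(sds > 0) < 2)
      stop("block '", bl, "' has fewer than 2 non-constant columns",
           call. = FALSE)
    xs <- scale(xs[, sds > 0, drop = FALSE])
    k <- min(n_components, ncol(xs), nrow(xs) - 1L)
    sv <- svd(xs)
    for (j in seq_len(k)) {
      v <- sv$v[, j]
      fl <- sign(v[which.max(abs(v))]); if (fl == 0) fl <- 1
      sc <- rep(NA_real_, nrow(traits))
      sc[cc] <- fl * sv$u[, j] * sv$d[j]
      out[[sprintf("%s_PC%d", bl, j)]] <- sc
      sv$v[, j] <- fl * v
    }
    loadings[[bl]] <- sv$v[, seq_len(k), drop = FALSE]
    rownames(loadings[[bl]]) <- colnames(xs)
    varexp[[bl]] <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  }
  attr(out, "loadings") <- loadings
  attr(out, "variance_explained") <- varexp
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value.
#'
#' @param x,y Numeric vectors, each of length >= 2; at least one group must
#'   have non-zero variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_ttest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("both groups have zero variance", call. = FALSE)
  }
  sx <- vx / length(x); sy <- vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Eigengene group contrasts
#'
#' The first-pass univariate screens: Welch t-tests comparing the reference
#' population against each other population (sympatric species pair, and
#' limnetics from different lakes), plus all pairwise treatment contrasts
#' within each population, for every module eigengene. Contrasts with an
#' undersized cell are skipped with a message.
#'
#' @param eigengenes Sample x module matrix.
#' @param samples Sample metadata aligned with the eigengene rows.
#' @return data.frame: module, type, group1, group2, population, n1, n2,
#'   t, df, p.
#' @export
module_contrasts <- function(eigengenes, samples) {
  check_samples(samples)
  stopifnot(nrow(eigengenes) == nrow(samples))
  pops <- levels(factor(samples$population))
  trts <- levels(factor(samples$treatment))
  rows <- list()
  add <- function(module, type, g1, g2, pop, sel1, sel2) {
    e <- eigengenes[, module]
    if (sum(sel1) < 2 || sum(sel2) < 2) {
      message("skipping contrast ", g1, " vs ", g2, " (", module,
              "): undersized cell")
      return()
    }
    tt <- welch_ttest(e[sel1], e[sel2])
    rows[[length(rows) + 1]] <<- data.frame(
      module = module, type = type, group1 = g1, group2 = g2,
      population = pop %||% NA_character_, n1 = sum(sel1), n2 = sum(sel2),
      t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  }
  for (m in colnames(eigengenes)) {
    for (p2 in pops[-1])
      add(m, "population", pops[1], p2, NULL,
          samples$population == pops[1], samples$population == p2)
    for (pop in pops)
      for (i in seq_along(trts)) for (j in seq_along(trts))
        if (i < j)
          add(m, "treatment", trts[i], trts[j], pop,
              samples$population == pop & samples$treatment == trts[i],
              samples$population == pop & samples$treatment == trts[j])
  }
  do.call(rbind, rows)
}

# Orthonormal column bases for the four nested models used by the type-II
# decomposition: full (pop * trait), additive, population-only, trait-only.
.term_engine <- function(pop, trait) {
  pop <- droplevels(factor(pop))
  if (nlevels(pop) < 2) stop("need >= 2 populations in the analysis set",
                             call. = FALSE)
  small <- names(which(table(pop) < 2))
  if (length(small))
    stop("population level '", small[1],
         "' has a single sample: interaction slope inestimable", call. = FALSE)
  base <- function(X) {
    q <- qr(X)
    list(Q = qr.Q(q)[, seq_len(q$rank), drop = FALSE], rank = q$rank)
  }
  list(full = base(stats::model.matrix(~ pop * trait)),
       add = base(stats::model.matrix(~ pop + trait)),
       pop = base(stats::model.matrix(~ pop)),
       trait = base(stats::model.matrix(~ trait)),
       n = length(trait), pop_f = pop, trait_v = trait)
}

# F statistics and parametric p for population / trait / interaction over the
# columns of Y (one response per column). Degenerate fits map to p = 1.
.term_pvalues <- function(eng, Y) {
  tot <- colSums(Y^2)
  rss <- lapply(eng[c("full", "add", "pop", "trait")], function(m)
    pmax(tot - colSums(crossprod(m$Q, Y)^2), 0))
  df2 <- eng$n - eng$full$rank
  denom <- rss$full / df2
  mk <- function(rss_red, rank_red) {
    df1 <- eng$add$rank - rank_red
    f <- pmax(rss_red - rss$add, 0) / df1 / denom
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    p[!is.finite(p)] <- 1
    f[!is.finite(f)] <- 0
    list(F = f, df1 = df1, p = p)
  }
  int_df1 <- eng$full$rank - eng$add$rank
  f_int <- pmax(rss$add - rss$full, 0) / int_df1 / denom
  p_int <- stats::pf(f_int, int_df1, df2, lower.tail = FALSE)
  p_int[!is.finite(p_int)] <- 1
  f_int[!is.finite(f_int)] <- 0
  list(population = mk(rss$trait, eng$trait$rank),
       trait = mk(rss$pop, eng$pop$rank),
       interaction = list(F = f_int, df1 = int_df1, p = p_int),
       df2 = df2)
}

#' Fit the population-by-trait linear model
#'
#' Ordinary least squares for `y ~ population + trait + population:trait`
#' with treatment-contrast (reference level) coding. The analysis set is the
#' samples with a non-missing trait value and response; female-control
#' trials, which have no male-trait measurements, drop out of male-trait
#' models by construction.
#'
#' @param y Per-sample response (module eigengene or gene expression).
#' @param samples Sample metadata aligned with `y`.
#' @param trait Per-sample covariate (NA excluded).
#' @return Object of class `model_fit`: coefficients, residuals, `rss`,
#'   `df_resid`, the analysis-set `sample_ids`, and the inputs needed to
#'   derive nested-model sums of squares.
#' @export
fit_interaction_model <- function(y, samples, trait) {
  check_samples(samples)
  stopifnot(length(y) == nrow(samples), length(trait) == nrow(samples))
  keep <- !is.na(y) & !is.na(trait)
  if (sum(keep) < 4) stop("analysis set too small", call. = FALSE)
  pop <- droplevels(factor(samples$population[keep]))
  eng <- .term_engine(pop, trait[keep])
  X <- stats::model.matrix(~ pop * trait, data = data.frame(pop = pop,
                                                            trait = trait[keep]))
  fit <- stats::lm.fit(X, y[keep])
  df_resid <- sum(keep) - eng$full$rank
  if (df_resid < 1) stop("no residual degrees of freedom", call. = FALSE)
  structure(list(coefficients = fit$coefficients,
                 residuals = fit$residuals,
                 rss = sum(fit$residuals^2),
                 df_resid = df_resid,
                 y = y[keep], pop = pop, trait = trait[keep],
                 sample_ids = as.character(samples$sample_id[keep]),
                 engine = eng),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("population-by-trait fit:", length(x$y), "samples,",
      nlevels(x$pop), "populations; residual df", x$df_resid, "\n")
  invisible(x)
}

#' Type-II sums-of-squares ANOVA
#'
#' Marginality-respecting decomposition: population is tested against the
#' model with trait only, trait against the model with population only
#' (each Delta-RSS taken to the additive model), and the interaction against
#' the additive model; every F uses the full-model residual mean square.
#' In a balanced design with an orthogonal covariate this equals the
#' sequential decomposition.
#'
#' @param fit A [fit_interaction_model()] result.
#' @return data.frame with one row per term: `term`, `F`, `df1`, `df2`,
#'   `p_param`, and an `efdr` column (NA until filled by [efdr()]).
#' @export
anova_type2 <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  pv <- .term_pvalues(fit$engine, matrix(fit$y, ncol = 1))
  data.frame(
    term = c("population", "trait", "population:trait"),
    F = c(pv$population$F, pv$trait$F, pv$interaction$F),
    df1 = c(pv$population$df1, pv$trait$df1, pv$interaction$df1),
    df2 = pv$df2,
    p_param = c(pv$population$p, pv$trait$p, pv$interaction$p),
    efdr = NA_real_, stringsAsFactors = FALSE)
}

#' The candidate neuroendocrine/neuromodulatory gene set
#'
#' Twenty-four genes from five pathways repeatedly implicated in female mate
#' choice and social decision-making: GnRH signalling, nonapeptide
#' signalling, dopamine signalling, prostaglandin F2-alpha signalling, and
#' synaptic plasticity.
#'
#' @return data.frame with columns `symbol` and `pathway` (24 rows,
#'   5 pathways).
#' @export
candidate_gene_set <- function() {
  data.frame(
    symbol = c("gnrh2", "gnrh3", "gnrhr1", "gnrhr4",
               "avp", "avpr1ab", "avpr2", "avpr2aa", "avpr2l", "oxt", "oxtr",
               "th", "th2", "drd1", "drd1b", "drd2a", "drd2l",
               "ptgfr",
               "nlgn1", "nlgn2a", "nlgn2b", "nlgn3a", "nlgn3b", "serpini1"),
    pathway = rep(c("GnRH", "nonapeptide", "dopamine", "PGF2a",
                    "synaptic_plasticity"), c(4, 7, 6, 1, 6)),
    stringsAsFactors = FALSE)
}

#' Candidate-gene population-by-trait models
#'
#' Runs [fit_interaction_model()] + [anova_type2()] for each mapped
#' candidate gene crossed with each trait PC, and reports each candidate's
#' module membership when an assignment is supplied. Symbols absent from the
#' expression matrix are listed in the `unmapped` attribute, not an error.
#'
#' @param expr Gene x sample matrix whose rownames carry gene symbols.
#' @param samples Sample metadata aligned with columns of `expr`.
#' @param trait_pcs data.frame from [trait_pca()] (or any `sample_id` +
#'   numeric columns).
#' @param genes data.frame like [candidate_gene_set()].
#' @param modules Optional `module_assignment` for membership annotation.
#' @return Long data.frame: gene, pathway, module, trait, term, F, df1, df2,
#'   p_param, efdr.
#' @export
candidate_gene_models <- function(expr, samples, trait_pcs,
                                  genes = candidate_gene_set(),
                                  modules = NULL) {
  check_samples(samples)
  mapped <- genes[genes$symbol %in% rownames(expr), , drop = FALSE]
  unmapped <- setdiff(genes$symbol, mapped$symbol)
  pc_cols <- setdiff(names(trait_pcs), "sample_id")
  idx <- match(samples$sample_id, trait_pcs$sample_id)
  rows <- list()
  for (g in mapped$symbol) {
    y <- expr[g, ]
    for (pc in pc_cols) {
      fit <- fit_interaction_model(y, samples, trait_pcs[[pc]][idx])
      tab <- anova_type2(fit)
      tab <- cbind(gene = g,
                   pathway = mapped$pathway[mapped$symbol == g],
                   module = if (is.null(modules)) NA_character_
                            else unname(modules[g]),
                   trait = pc, tab, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- tab
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' Simplified negative-binomial differential expression
#'
#' A deliberately lightweight emulator of the count-model stage: per-gene NB
#' dispersion by method of moments (floored at 1e-8) — a first pass on
#' normalized counts within design cells, then re-matched to the Pearson
#' chi-square of the fitted model — an NB log-linear model
#' `counts ~ population + treatment` fit by iteratively reweighted least
#' squares with a log size-factor offset, Wald tests (t reference with
#' residual degrees of freedom) for all pairwise treatment and population
#' contrasts, and Benjamini-Hochberg adjustment within each contrast
#' (significance convention: adjusted p < 0.1). Genes with an influential
#' outlying count (maximum Cook's distance above the F(0.99) cutoff) get
#' `NA` p-values rather than a call, mirroring standard count-model
#' practice. No shrinkage of fold changes is applied.
#'
#' @param counts Gene x sample integer matrix.
#' @param samples Sample metadata.
#' @param size_factors Optional per-sample factors.
#' @param cooks_filter Mask p-values of genes whose maximum Cook's distance
#'   exceeds `qf(0.99, n_coef, df_resid)` (default TRUE).
#' @return Long data.frame: gene, contrast_type, contrast, log2FC, se, stat,
#'   p, padj; all-zero genes are excluded and listed in the
#'   `excluded_genes` attribute.
#' @export
de_test <- function(counts, samples, size_factors = NULL,
                    cooks_filter = TRUE) {
  check_counts(counts); check_samples(samples, counts)
  sf <- size_factors %||% estimate_size_factors(counts)
  zero <- rowSums(counts) == 0
  excluded <- rownames(counts)[zero]
  counts <- counts[!zero, , drop = FALSE]
  norm <- sweep(counts, 2, sf, "/")

  cell <- interaction(samples$population, samples$treatment, drop = TRUE)
  ncell <- table(cell)
  use_cells <- names(ncell)[ncell >= 2]
  disp <- apply(norm, 1, function(x) {
    num <- 0; den <- 0
    for (cl in use_cells) {
      xi <- x[cell == cl]
      w <- length(xi) - 1
      num <- num + w * (stats::var(xi) - mean(xi))
      den <- den + w * mean(xi)^2
    }
    if (den <= 0) return(1e-8)
    max(num / den, 1e-8)
  })

  pop <- droplevels(factor(samples$population))
  trt <- droplevels(factor(samples$treatment))
  X <- stats::model.matrix(~ pop + trt)
  off <- log(sf)
  p_coef <- ncol(X)

  contrast_list <- list()
  lv <- levels(trt)
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    cv <- numeric(p_coef); names(cv) <- colnames(X)
    if (i > 1) cv[paste0("trt", lv[i])] <- -1
    cv[paste0("trt", lv[j])] <- 1
    contrast_list[[paste0(lv[j], "_vs_", lv[i])]] <-
      list(type = "treatment", v = cv)
  }
  lp <- levels(pop)
  for (i in seq_along(lp)) for (j in seq_along(lp)) if (i < j) {
    cv <- numeric(p_coef); names(cv) <- colnames(X)
    if (i > 1) cv[paste0("pop", lp[i])] <- -1
    cv[paste0("pop", lp[j])] <- 1
    contrast_list[[paste0(lp[j], "_vs_", lp[i])]] <-
      list(type = "population", v = cv)
  }

  df_resid <- nrow(X) - p_coef

  irls <- function(y, alpha, b) {
    for (it in 1:25) {
      eta <- pmin(pmax(drop(X %*% b) + off, -30), 30)
      mu <- exp(eta)
      w <- mu / (1 + alpha * mu)
      z <- (eta - off) + (y - mu) / mu
      XtW <- t(X * w)
      b_new <- tryCatch(solve(XtW %*% X, XtW %*% z)[, 1],
                        error = function(e) NULL)
      if (is.null(b_new)) return(NULL)
      delta <- max(abs(b_new - b)); b <- b_new
      if (delta < 1e-8) break
    }
    b
  }

  fit_one <- function(y, alpha) {
    b0 <- stats::lm.fit(X, log((y + 0.5) / exp(off)))$coefficients
    b0[is.na(b0)] <- 0
    b <- irls(y, alpha, b0)
    if (is.null(b)) return(NULL)
    # second-pass dispersion: match the Pearson chi-square of the fit to its
    # residual df, so noisy first-pass cell moments do not deflate alpha
    mu <- exp(pmin(pmax(drop(X %*% b) + off, -30), 30))
    pearson <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - df_resid
    if (pearson(1e-8) > 0) {
      up <- max(alpha, 1)
      while (pearson(up) > 0 && up < 1e6) up <- up * 10
      alpha <- tryCatch(stats::uniroot(pearson, c(1e-8, up))$root,
                        error = function(e) alpha)
      alpha <- max(alpha, 1e-8)
      b <- irls(y, alpha, b)
      if (is.null(b)) return(NULL)
    } else alpha <- 1e-8
    mu <- exp(pmin(pmax(drop(X %*% b) + off, -30), 30))
    w <- mu / (1 + alpha * mu)
    V <- tryCatch(solve(t(X * w) %*% X), error = function(e) NULL)
    if (is.null(V)) return(NULL)
    hat <- rowSums((X %*% V) * X) * w
    pearson2 <- (y - mu)^2 / (mu + alpha * mu^2)
    cooks <- (pearson2 / p_coef) * hat / (1 - hat)^2
    list(b = b, V = V, max_cooks = max(cooks))
  }

  res <- vector("list", length(contrast_list))
  names(res) <- names(contrast_list)
  for (nm in names(contrast_list)) {
    res[[nm]] <- matrix(NA_real_, nrow(counts), 3,
                        dimnames = list(rownames(counts),
                                        c("log2FC", "se", "stat")))
  }
  max_cooks <- rep(NA_real_, nrow(counts))
  for (g in seq_len(nrow(counts))) {
    f <- fit_one(counts[g, ], disp[g])
    if (is.null(f)) next
    max_cooks[g] <- f$max_cooks
    for (nm in names(contrast_list)) {
      cv <- contrast_list[[nm]]$v
      est <- sum(cv * f$b)
      se <- sqrt(drop(cv %*% f$V %*% cv))
      res[[nm]][g, ] <- c(est / log(2), se / log(2), est / se)
    }
  }
  outlier <- cooks_filter &
    !is.na(max_cooks) & max_cooks > stats::qf(0.99, p_coef, df_resid)

  out <- do.call(rbind, lapply(names(contrast_list), function(nm) {
    m <- res[[nm]]
    p <- 2 * stats::pt(-abs(m[, "stat"]), df = nrow(X) - p_coef)
    p[outlier] <- NA_real_
    data.frame(gene = rownames(m), contrast_type = contrast_list[[nm]]$type,
               contrast = nm, log2FC = m[, "log2FC"], se = m[, "se"],
               stat = m[, "stat"], p = p,
               padj = stats::p.adjust(p, "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(out, "excluded_genes") <- excluded
  out
}
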