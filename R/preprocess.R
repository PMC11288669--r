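# Normalization, variance stabilization, variable-gene filtering, sample PCA
# and quality-control flagging for bulk count matrices.

#' Median-of-ratios size factors
#'
#' Per-sample median of `count / geometric mean` over genes expressed in all
#' samples, rescaled so the factors have geometric mean 1. This is the
#' standard library-composition estimator used upstream of variance
#' stabilization.
#'
#' @param counts Gene x sample integer matrix.
#' @return Named positive numeric vector, one factor per sample, geometric
#'   mean 1.
#' @export
estimate_size_factors <- function(counts) {
  check_counts(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop(paste("no gene has positive counts in every sample;",
               "filter samples or supply a pseudo-reference fallback"),
         call. = FALSE)
  sub <- counts[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))        # geometric mean 1
  names(sf) <- colnames(counts)
  sf
}

#' Variance-stabilizing transform of counts
#'
#' `log2(count / size_factor + pseudocount)`. A shifted-log transform is used
#' in place of the regularized-log transform of the original analysis; the
#' transform and its pseudocount are recorded in the matrix's
#' `transform_tag` attribute, and downstream contracts are written against
#' variance-stabilization properties rather than any particular transform.
#'
#' @param counts Gene x sample integer matrix.
#' @param size_factors Positive per-sample factors
#'   (default [estimate_size_factors()]).
#' @param pseudocount Added before the log (default 1, so a zero count maps
#'   to 0).
#' @return Numeric matrix of the same shape with attribute `transform_tag`.
#' @export
vst <- function(counts, size_factors = estimate_size_factors(counts),
                pseudocount = 1) {
  check_counts(counts)
  if (length(size_factors) != ncol(counts))
    stop("need one size factor per sample", call. = FALSE)
  if (any(size_factors <= 0)) stop("size factors must be positive", call. = FALSE)
  v <- log2(sweep(counts, 2, size_factors, "/") + pseudocount)
  attr(v, "transform_tag") <- sprintf("log2(count/sf + %g)", pseudocount)
  v
}

#' Keep the most variable genes
#'
#' Retains the `ceiling(fraction * n_genes)` genes with largest variance on
#' the transformed scale (the analysis used the 90% most variable genes).
#' Ties break stably by (variance descending, gene id ascending); the
#' original row order of retained genes is preserved, so the operation is
#' idempotent at a fixed fraction.
#'
#' @param expr Gene x sample numeric matrix (VST scale).
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @return The row-subset matrix (attributes preserved).
#' @export
filter_top_variable <- function(expr, fraction = 0.9) {
  if (length(fraction) != 1 || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  g <- nrow(expr)
  keep_n <- ceiling(fraction * g)
  v <- apply(expr, 1, stats::var)
  ord <- order(-v, rownames(expr))
  keep <- sort(ord[seq_len(keep_n)])
  out <- expr[keep, , drop = FALSE]
  attr(out, "transform_tag") <- attr(expr, "transform_tag")
  out
}

#' Principal components of samples
#'
#' SVD-based PCA of samples in gene space. Genes are centred but not
#' unit-scaled (expression variance is the signal being visualized). Signs
#' are fixed deterministically: each loading vector's largest-magnitude
#' element is positive.
#'
#' @param expr Gene x sample numeric matrix.
#' @param n_components Number of components to retain (default full rank).
#' @return List of class `pca_result`: `scores` (sample x component),
#'   `loadings` (gene x component), `variance_explained` (fraction per
#'   retained component).
#' @export
pca_samples <- function(expr, n_components = NULL) {
  x <- t(expr)                               # samples x genes
  if (nrow(x) < 2) stop("need at least two samples", call. = FALSE)
  x <- scale(x, center = TRUE, scale = FALSE)
  full_rank <- min(nrow(x) - 1L, ncol(x))
  n_components <- n_components %||% full_rank
  if (n_components > min(dim(x)))
    stop("n_components exceeds matrix rank bound", call. = FALSE)
  sv <- svd(x)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u[, seq_len(n_components), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_components)], n_components), 2, flip, "*")
  loadings <- sweep(sv$v[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  dimnames(scores) <- list(colnames(expr), paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(rownames(expr), paste0("PC", seq_len(n_components)))
  ve <- sv$d[seq_len(n_components)]^2 / sum(sv$d^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", ncol(x$scores), "components;",
      "variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_explained, 5)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Flag quality-control failures
#'
#' Two codified QC rules emulating by-eye sample curation:
#' `"suspected_swap"` — in PC space, a sample is an outlier with respect to
#' its own population (squared Mahalanobis distance under the pooled
#' within-population covariance above the chi-square 0.999 quantile) *and*
#' lies `margin` times closer to another population's centroid; and
#' `"low_mapping"` — the `k_low_mapping` samples with the lowest
#' read-mapping percentage, when that column exists (ties break stably by
#' mapping percentage then sample id). Flagged samples are excluded
#' downstream by default but never deleted from the table.
#'
#' @param pca A [pca_samples()] result.
#' @param samples Sample metadata (data.frame with `population`; optional
#'   `read_mapping_pct`).
#' @param n_pcs Number of leading PCs used for swap detection; the default
#'   (one per population level, minimum 2) spans the population centroids.
#' @param margin Distance ratio own/other that triggers a swap flag
#'   (default 2).
#' @param k_low_mapping How many lowest-mapping samples to flag (default 2).
#' @param exclude Explicit sample ids to flag as `"manual_exclude"`,
#'   overriding/augmenting the codified rules.
#' @return `samples` with a `qc_flags` character column (`;`-separated, ""
#'   when clean).
#' @export
flag_qc_samples <- function(pca, samples, n_pcs = NULL, margin = 2,
                            k_low_mapping = 2, exclude = character()) {
  check_samples(samples)
  n_pcs <- n_pcs %||% max(2L, nlevels(factor(samples$population)))
  n_pcs <- min(n_pcs, ncol(pca$scores))
  sc <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  pops <- levels(factor(samples$population))
  flags <- rep("", nrow(samples))

  counts_per_pop <- table(factor(samples$population, levels = pops))
  if (any(counts_per_pop < 3)) {
    warning("swap detection disabled: a population has fewer than 3 samples")
  } else {
    centroids <- do.call(rbind, lapply(pops, function(p)
      colMeans(sc[samples$population == p, , drop = FALSE])))
    rownames(centroids) <- pops
    # pooled within-population covariance, ridge-regularized for stability
    dev <- sc - centroids[as.character(samples$population), , drop = FALSE]
    S <- crossprod(dev) / (nrow(sc) - length(pops))
    S <- S + diag(1e-8 * mean(diag(S)) + 1e-12, ncol(S))
    Sinv <- solve(S)
    for (i in seq_len(nrow(samples))) {
      d <- sqrt(vapply(pops, function(p) {
        z <- sc[i, ] - centroids[p, ]
        drop(z %*% Sinv %*% z)
      }, numeric(1)))
      own <- as.character(samples$population[i])
      if (d[own]^2 > stats::qchisq(0.999, df = n_pcs) &&
          d[own] > margin * min(d[setdiff(pops, own)]))
        flags[i] <- paste(c(strsplit(flags[i], ";")[[1]], "suspected_swap"),
                          collapse = ";")
    }
  }

  if ("read_mapping_pct" %in% names(samples) && k_low_mapping > 0) {
    ord <- order(samples$read_mapping_pct, samples$sample_id)
    low <- ord[seq_len(min(k_low_mapping, nrow(samples)))]
    for (i in low)
      flags[i] <- paste(c(setdiff(strsplit(flags[i], ";")[[1]], ""),
                          "low_mapping"), collapse = ";")
  }
  for (i in which(samples$sample_id %in% exclude))
    flags[i] <- paste(c(setdiff(strsplit(flags[i], ";")[[1]], ""),
                        "manual_exclude"), collapse = ";")
  samples$qc_flags <- sub("^;", "", flags)
  samples
}

#' Samples passing QC
#'
#' @param samples A table from [flag_qc_samples()].
#' @return Character vector of unflagged sample ids.
#' @export
qc_pass <- function(samples) {
  if (is.null(samples$qc_flags)) return(as.character(samples$sample_id))
  as.character(samples$sample_id[samples$qc_flags == ""])
}
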