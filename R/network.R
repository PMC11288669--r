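# Signed weighted co-expression network: soft-thresholded signed adjacency,
# topological overlap, dynamic branch cutting of the average-linkage
# dendrogram, module eigengenes, and eigengene-based module merging.

#' Network construction parameters
#'
#' Defaults are the optimized settings of the original analysis: soft power
#' 9 on a signed network, biweight midcorrelation with at most 5% of points
#' weighted to zero per side, minimum module size 30, eigengene merge height
#' 0.25, branch-split sensitivity 2, branch detection height 0.995, and gene
#' blocks of at most 30 000.
#'
#' @param power Soft-threshold exponent (> 0).
#' @param network_type Only `"signed"` is supported: correlation is mapped
#'   `(1 + cor)/2` so negatively correlated genes are unconnected.
#' @param cor_type `"bicor"` (default) or `"pearson"`.
#' @param max_p_outliers Per-side outlier cap for bicor, in (0, 0.5].
#' @param min_module_size Minimum genes per detected module.
#' @param merge_cut_height Eigengene dissimilarity below which modules merge.
#' @param deep_split Integer 0-4; higher splits branches more aggressively
#'   into smaller modules.
#' @param detect_cut_height Dendrogram height above which branches are never
#'   modules.
#' @param max_block_size Gene block size for memory layout (result
#'   invariant).
#' @return A validated list of class `network_params`.
#' @export
network_params <- function(power = 9, network_type = "signed",
                           cor_type = c("bicor", "pearson"),
                           max_p_outliers = 0.05, min_module_size = 30,
                           merge_cut_height = 0.25, deep_split = 2,
                           detect_cut_height = 0.995, max_block_size = 30000) {
  cor_type <- match.arg(cor_type)
  if (power <= 0) config_error("power", "must be > 0")
  if (network_type != "signed")
    config_error("network_type", "must be 'signed'")
  if (max_p_outliers <= 0 || max_p_outliers > 0.5)
    config_error("max_p_outliers", "must lie in (0, 0.5]")
  if (min_module_size < 1) config_error("min_module_size", "must be >= 1")
  if (merge_cut_height < 0 || merge_cut_height > 1)
    config_error("merge_cut_height", "must lie in [0, 1]")
  if (!deep_split %in% 0:4) config_error("deep_split", "must be in 0..4")
  if (detect_cut_height <= 0 || detect_cut_height > 1)
    config_error("detect_cut_height", "must lie in (0, 1]")
  if (max_block_size < 1) config_error("max_block_size", "must be >= 1")
  structure(list(power = power, network_type = network_type,
                 cor_type = cor_type, max_p_outliers = max_p_outliers,
                 min_module_size = as.integer(min_module_size),
                 merge_cut_height = merge_cut_height,
                 deep_split = as.integer(deep_split),
                 detect_cut_height = detect_cut_height,
                 max_block_size = as.integer(max_block_size)),
            class = "network_params")
}

#' Signed adjacency from correlations
#'
#' `a_ij = ((1 + cor_ij) / 2)^power`, so cor -1 maps to 0 (unconnected),
#' +1 to 1, and 0 to `2^-power`. The diagonal is set to 1.
#'
#' @param cors Symmetric correlation matrix with entries in `[-1, 1]`.
#' @param power Soft-threshold exponent.
#' @return Adjacency matrix with entries in `[0, 1]`.
#' @export
signed_adjacency <- function(cors, power = 9) {
  if (any(cors < -1 - 1e-12) || any(cors > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  a <- ((1 + cors) / 2)^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_{k != i,j} a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k_i = sum_{k != i} a_ik`; `TOM_ii = 1`. Two genes are
#' similar when they are connected and share neighbours.
#'
#' @param adj Symmetric adjacency in `[0, 1]` with unit diagonal.
#' @param tol Symmetry tolerance (error beyond it).
#' @return Symmetric matrix in `[0, 1]`; dissimilarity for clustering is
#'   `1 - TOM`.
#' @export
tom_similarity <- function(adj, tol = 1e-8) {
  if (max(abs(adj - t(adj))) > tol)
    stop("adjacency is not symmetric within tolerance", call. = FALSE)
  if (any(adj < -tol) || any(adj > 1 + tol))
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  k <- rowSums(adj) - diag(adj)
  aa <- tcrossprod(adj)                      # (A^2)_ij, A symmetric
  numer <- aa - adj                          # sum_{k != i,j} a_ik a_kj + a_ij
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- numer / denom
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  (tom + t(tom)) / 2
}

# Dynamic branch cut of an average-linkage dendrogram of 1 - TOM.
# A branch is a module core when it has >= min_module_size leaves, its merge
# height is below detect_cut_height, and it is separated from the
# surrounding tree: climbing from the branch until it has grown by at least
# 20% more leaves (so single straggler genes chaining onto a branch cannot
# mask its isolation), the height reached must exceed the branch's own
# height by gap * (1 - height) — a separation judged relative to the
# branch's own tightness, which keeps the rule meaningful after the
# soft-threshold power compresses the TOM scale. deep_split relaxes the gap
# factor, so higher values admit more, smaller branches. The deepest
# qualifying branches win; genes outside every core are left for the
# PAM-like sweep.
.cut_branches <- function(h, params) {
  n <- length(h$order)
  merge <- h$merge
  height <- h$height
  gap <- c(0.70, 0.60, 0.50, 0.35, 0.20)[params$deep_split + 1]

  size <- numeric(n - 1)
  parent_of <- integer(n - 1)          # 0 = root
  sib_size <- numeric(n - 1)           # leaves on the other side of parent
  for (i in seq_len(n - 1)) {
    kid_size <- function(k) if (k < 0) 1 else size[k]
    s1 <- kid_size(merge[i, 1]); s2 <- kid_size(merge[i, 2])
    size[i] <- s1 + s2
    if (merge[i, 1] > 0) { parent_of[merge[i, 1]] <- i
                           sib_size[merge[i, 1]] <- s2 }
    if (merge[i, 2] > 0) { parent_of[merge[i, 2]] <- i
                           sib_size[merge[i, 2]] <- s1 }
  }

  join_height <- function(i) {
    need <- 0.2 * size[i]
    acc <- 0; j <- i
    repeat {
      p <- parent_of[j]
      if (p == 0L) return(Inf)
      acc <- acc + sib_size[j]
      if (acc >= need) return(height[p])
      j <- p
    }
  }
  qualifies <- function(i) {
    size[i] >= params$min_module_size &&
      height[i] <= params$detect_cut_height &&
      (join_height(i) - height[i]) >= gap * (1 - height[i])
  }

  # bottom-up: children of merge i always have index < i; the deepest
  # qualifying branch in a lineage is kept.
  mods <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    kids <- c(if (merge[i, 1] > 0) mods[[merge[i, 1]]],
              if (merge[i, 2] > 0) mods[[merge[i, 2]]])
    val <- if (length(kids)) kids
           else if (qualifies(i)) i
           else integer(0)
    mods[i] <- list(val)
  }
  chosen <- mods[[n - 1]]

  leaves_of <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      k <- stack[[1]]; stack <- stack[-1]
      if (k < 0) out <- c(out, -k) else stack <- c(merge[k, ], stack)
    }
    out
  }
  lapply(chosen, leaves_of)
}

#' Detect co-expression modules from topological overlap
#'
#' Average-linkage hierarchical clustering of `1 - TOM` followed by a
#' dynamic branch cut (see [network_params()] for the knobs). Genes on no
#' qualifying branch are `"unassigned"`; optionally a PAM-like sweep then
#' adds each unassigned gene to its nearest module when its mean TOM to the
#' module's members reaches half that module's median internal TOM. Module
#' labels `"M1", "M2", ...` are assigned by decreasing size.
#'
#' @param tom Topological overlap matrix from [tom_similarity()].
#' @param params [network_params()].
#' @param pam_stage Run the nearest-module reassignment sweep (default TRUE).
#' @return Named character vector (gene -> label) of class
#'   `module_assignment`, with a `labels` attribute ordered by size.
#' @export
detect_modules <- function(tom, params = network_params(), pam_stage = TRUE) {
  genes <- rownames(tom) %||% sprintf("g%d", seq_len(nrow(tom)))
  n <- nrow(tom)
  assign <- rep("unassigned", n)
  names(assign) <- genes
  if (n < params$min_module_size) {
    warning("fewer genes than min_module_size: all genes unassigned")
    return(structure(assign, labels = "unassigned",
                     class = "module_assignment"))
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  branches <- .cut_branches(h, params)
  if (length(branches)) {
    for (b in seq_along(branches)) assign[branches[[b]]] <- paste0("B", b)
    if (pam_stage) {
      meds <- vapply(seq_along(branches), function(b) {
        sub <- tom[branches[[b]], branches[[b]], drop = FALSE]
        stats::median(sub[upper.tri(sub)])
      }, numeric(1))
      un <- which(assign == "unassigned")
      for (i in un) {
        sims <- vapply(branches, function(lv) mean(tom[i, lv]), numeric(1))
        b <- which.max(sims)
        if (sims[b] >= 0.5 * meds[b]) assign[i] <- paste0("B", b)
      }
    }
  }
  relabel_by_size(assign)
}

# Re-rank module labels by decreasing size (ties: first-seen order);
# "unassigned" is reserved and always last.
relabel_by_size <- function(assign) {
  tab <- table(assign[assign != "unassigned"])
  if (length(tab)) {
    ord <- names(sort(tab, decreasing = TRUE))
    new <- stats::setNames(sprintf("M%d", seq_along(ord)), ord)
    assign[assign != "unassigned"] <- new[assign[assign != "unassigned"]]
    labels <- c(sprintf("M%d", seq_along(ord)), "unassigned")
  } else labels <- "unassigned"
  structure(assign, labels = labels, class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(factor(x, levels = attr(x, "labels")))
  cat("module assignment:", length(x), "genes\n")
  print(tab)
  invisible(x)
}

#' Module eigengenes
#'
#' Per module, the first principal component of the sample x gene submatrix
#' of standardized expression (each gene centred and scaled across samples).
#' The eigengene is the PC-score vector (sample mean 0), with sign oriented
#' so that its mean correlation with the module's genes is positive;
#' `variance_explained` is the first-eigenvalue share. A single-gene module's
#' eigengene is that gene standardized.
#'
#' @param expr Gene x sample numeric matrix covering all module genes.
#' @param modules A `module_assignment`.
#' @return Sample x module matrix with attribute `variance_explained`.
#' @export
module_eigengenes <- function(expr, modules) {
  labels <- setdiff(attr(modules, "labels") %||% unique(modules), "unassigned")
  if (!length(labels)) stop("no modules to summarize", call. = FALSE)
  if (ncol(expr) < 2) stop("need at least 2 samples", call. = FALSE)
  me <- matrix(NA_real_, ncol(expr), length(labels),
               dimnames = list(colnames(expr), labels))
  ve <- stats::setNames(numeric(length(labels)), labels)
  for (lab in labels) {
    g <- names(modules)[modules == lab]
    g <- intersect(g, rownames(expr))
    if (!length(g)) stop("module ", lab, " has no genes in expr", call. = FALSE)
    sub <- expr[g, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (all(sds == 0)) stop("module ", lab, " is all-constant", call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
    z <- t((sub - rowMeans(sub)) / apply(sub, 1, stats::sd))  # samples x genes
    if (ncol(z) == 1) {
      message("module ", lab, " has a single usable gene; eigengene = that gene")
      me[, lab] <- z[, 1]
      ve[lab] <- 1
      next
    }
    sv <- svd(z)
    e <- sv$u[, 1] * sv$d[1]
    if (mean(stats::cor(e, z)) < 0) e <- -e
    me[, lab] <- e
    ve[lab] <- sv$d[1]^2 / sum(sv$d^2)
  }
  attr(me, "variance_explained") <- ve
  me
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - cor(E_a, E_b)` is below `merge_cut_height`,
#' recomputing the merged eigengene each time, until no pair qualifies.
#' `"unassigned"` never merges. Labels are re-ranked by size afterwards.
#'
#' @param expr Gene x sample matrix.
#' @param modules `module_assignment`.
#' @param merge_cut_height Dissimilarity threshold (0 disables merging).
#' @return List with elements `modules` and `eigengenes`.
#' @export
merge_close_modules <- function(expr, modules, merge_cut_height = 0.25) {
  assign <- as.character(modules)
  names(assign) <- names(modules)
  repeat {
    labs <- setdiff(unique(assign), "unassigned")
    if (length(labs) < 2) break
    cur <- structure(assign, labels = c(labs, "unassigned"),
                     class = "module_assignment")
    me <- module_eigengenes(expr, cur)
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    ij <- arrayInd(which.min(d), dim(d))
    if (d[ij] >= merge_cut_height) break
    a <- colnames(me)[ij[1]]; b <- colnames(me)[ij[2]]
    assign[assign == b] <- a
  }
  out <- relabel_by_size(assign)
  list(modules = out, eigengenes = module_eigengenes(expr, out))
}
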