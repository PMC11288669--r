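# Biweight midcorrelation: a median/MAD-based robust correlation. Each
# vector is median-centred and downweighted by the Tukey biweight
# w_i = (1 - u_i^2)^2 for |u_i| < 1 with u_i = (x_i - med) / (9 MAD); the
# correlation is the cosine of the two weighted vectors. `max_p_outliers`
# caps, side by side, the proportion of points that can receive zero weight
# by rescaling u so that the outer quantile maps to +-1.

# Returns the weighted, centred vector; attr "fallback" = TRUE when MAD = 0
# and a mean-centred (Pearson-style) vector is returned instead.
.bicor_transform <- function(x, max_p_outliers = 0.05) {
  med <- stats::median(x)
  madx <- stats::median(abs(x - med))
  if (madx == 0) {
    out <- x - mean(x)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  u <- (x - med) / (9 * madx)
  if (max_p_outliers < 0.5) {
    ql <- stats::quantile(u, max_p_outliers, names = FALSE)
    qh <- stats::quantile(u, 1 - max_p_outliers, names = FALSE)
    if (ql < -1) u[u < 0] <- u[u < 0] / abs(ql)
    if (qh > 1) u[u > 0] <- u[u > 0] / qh
  }
  w <- (1 - u^2)^2 * (abs(u) < 1)
  out <- (x - med) * w
  if (sum(out^2) == 0) {       # pathological weighting; fall back
    out <- x - mean(x)
    attr(out, "fallback") <- TRUE
  }
  attr(out, "fallback") <- isTRUE(attr(out, "fallback"))
  out
}

#' Biweight midcorrelation of two vectors
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @param max_p_outliers Maximum proportion of points per side allowed to
#'   receive zero weight (default 0.05). When the MAD of a vector is zero the
#'   function falls back to Pearson centring for that vector, with a warning.
#' @return A correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y, max_p_outliers = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  for (nm in c("x", "y")) {
    v <- get(nm)
    if (stats::var(v) == 0)
      stop(sprintf("vector '%s' is constant", nm), call. = FALSE)
  }
  xt <- .bicor_transform(x, max_p_outliers)
  yt <- .bicor_transform(y, max_p_outliers)
  if (attr(xt, "fallback") || attr(yt, "fallback"))
    warning("zero MAD: Pearson fallback used for one or both vectors")
  r <- sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
  min(1, max(-1, r))
}

#' Gene-gene correlation matrix
#'
#' Pairwise biweight midcorrelation (or Pearson) of gene expression profiles
#' across samples, computed in gene blocks of at most `max_block_size` rows.
#' Blocking affects memory layout only; the result is block-size invariant.
#' Constant genes are dropped with a warning and listed in the
#' `dropped_genes` attribute; genes with zero MAD but positive variance use
#' the Pearson fallback (counted in attribute `n_fallback`).
#'
#' @param expr Gene x sample numeric matrix (>= 3 samples).
#' @param params A [network_params()] object.
#' @return Symmetric gene x gene matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr, params = network_params()) {
  if (ncol(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  v <- apply(expr, 1, stats::var)
  dropped <- rownames(expr)[v == 0]
  if (length(dropped)) {
    warning(length(dropped), " constant gene(s) dropped from the network")
    expr <- expr[v > 0, , drop = FALSE]
  }
  n_fallback <- 0L
  if (params$cor_type == "bicor") {
    xt <- t(apply(expr, 1, function(row) {
      tr <- .bicor_transform(row, params$max_p_outliers)
      if (attr(tr, "fallback")) n_fallback <<- n_fallback + 1L
      as.numeric(tr)
    }))
  } else {
    xt <- expr - rowMeans(expr)
  }
  xt <- xt / sqrt(rowSums(xt^2))
  n <- nrow(xt)
  cors <- matrix(NA_real_, n, n, dimnames = list(rownames(expr), rownames(expr)))
  starts <- seq(1L, n, by = params$max_block_size)
  for (s in starts) {
    idx <- s:min(s + params$max_block_size - 1L, n)
    cors[idx, ] <- xt[idx, , drop = FALSE] %*% t(xt)
  }
  cors[cors > 1] <- 1
  cors[cors < -1] <- -1
  diag(cors) <- 1
  attr(cors, "dropped_genes") <- dropped
  attr(cors, "n_fallback") <- n_fallback
  cors
}
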