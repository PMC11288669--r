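#' @keywords internal
"_PACKAGE"

# Run `expr` with the global RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed and a label
#'
#' A fixed labelled-hash scheme so that pipeline stages are independently
#' reproducible from one global seed. The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Integer global seed.
#' @param label Character scalar naming the stage or purpose.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(label) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  s <- (as.numeric(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483646 + 1)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items,
#' used to score recovery of planted co-expression modules.
#'
#' @param a,b Vectors of cluster labels (any atomic type), equal length.
#' @return A number <= 1; 1 means identical partitions, ~0 chance agreement.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# stop() with a consistent prefix naming the offending field/argument.
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# Validate a counts matrix contract: non-negative integers, unique dimnames.
check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix", call. = FALSE)
  if (any(counts < 0)) stop("counts contain negative entries", call. = FALSE)
  if (any(counts != round(counts))) stop("counts must be integers", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids", call. = FALSE)
  invisible(counts)
}

# Validate sample metadata against a counts matrix.
check_samples <- function(samples, counts = NULL) {
  stopifnot(is.data.frame(samples))
  need <- c("sample_id", "population", "treatment")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(counts) && !identical(as.character(samples$sample_id),
                                     colnames(counts)))
    stop("sample_id does not match counts columns (order matters)", call. = FALSE)
  invisible(samples)
}

# Standard WGCNA-style colour aliases for size-ranked module labels.
#' Map size-ranked module labels to conventional colour aliases
#'
#' Cosmetic helper giving modules "turquoise"/"blue"/... names in the
#' convention of weighted co-expression network analysis; `"unassigned"`
#' maps to `"grey"`.
#'
#' @param labels Character vector of module labels (`"M1"`, `"M2"`, ...,
#'   `"unassigned"`).
#' @return Character vector of colour names, same length.
#' @export
module_colour_alias <- function(labels) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
           "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
           "darkgrey", "orange", "darkorange", "white", "skyblue")
  out <- rep(NA_character_, length(labels))
  out[labels == "unassigned"] <- "grey"
  idx <- suppressWarnings(as.integer(sub("^M", "", labels)))
  ok <- !is.na(idx) & idx >= 1 & idx <= length(pal) & labels != "unassigned"
  out[ok] <- pal[idx[ok]]
  out[is.na(out)] <- labels[is.na(out)]
  out
}
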