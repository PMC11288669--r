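# Shared fixtures and independent oracles. Oracles deliberately use plain
# base-R implementations (lm(), loops) so they cannot share code paths with
# the package internals they check.

tiny_counts <- function(n_genes = 8, n_samples = 4, seed = 1, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("g%d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

fast_sim <- function(seed = 1, n_genes = 300, module_sizes = c(50, 50), ...) {
  simulate_dataset(sim_config(n_genes = n_genes, module_sizes = module_sizes,
                              seed = seed, ...))
}

# a sample table for direct model fitting (no counts involved)
model_samples <- function(n_per_pop = 8, pops = c("A", "B", "C")) {
  data.frame(sample_id = sprintf("s%02d", seq_len(n_per_pop * length(pops))),
             population = factor(rep(pops, each = n_per_pop), levels = pops),
             treatment = "t1", stringsAsFactors = FALSE)
}

# independent type-II SS oracle built on lm()
oracle_type2 <- function(y, pop, trait) {
  d <- data.frame(y = y, pop = droplevels(factor(pop)), trait = trait)
  rss <- function(f) sum(resid(lm(f, d))^2)
  r_full <- rss(y ~ pop * trait); r_add <- rss(y ~ pop + trait)
  r_pop <- rss(y ~ pop); r_trait <- rss(y ~ trait)
  npop <- nlevels(d$pop); n <- length(y)
  df2 <- n - 2 * npop
  Fs <- c(population = ((r_trait - r_add) / (npop - 1)) / (r_full / df2),
          trait = (r_pop - r_add) / (r_full / df2),
          interaction = ((r_add - r_full) / (npop - 1)) / (r_full / df2))
  ps <- pf(Fs, c(npop - 1, 1, npop - 1), df2, lower.tail = FALSE)
  list(F = Fs, p = ps, df2 = df2)
}

# brute-force TOM by its defining triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    s <- 0
    for (l in seq_len(n)) if (l != i && l != j) s <- s + a[i, l] * a[l, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# block-structured adjacency for planted-partition tests
block_adjacency <- function(sizes, within = 0.9, between = 0.01, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  a <- matrix(between, n, n)
  for (b in seq_along(sizes)) a[lab == b, lab == b] <- within
  a <- a + matrix(runif(n * n, 0, 0.005), n, n)
  a <- (a + t(a)) / 2
  a[a > 1] <- 1
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
  a
}
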