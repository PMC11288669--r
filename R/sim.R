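#' Configuration for the bulk RNA-seq simulator
#'
#' Describes a simulated study of female brain gene expression across
#' populations (sympatric limnetic/benthic ecotypes plus an allopatric
#' limnetic population) and social treatments (conspecific courtship,
#' heterospecific courtship, female social control), with planted
#' co-expression modules, constitutive population effects, module-by-treatment
#' shifts, and module-trait covariation whose slope may differ between
#' populations (the planted population-by-trait interaction).
#'
#' The gene-level model is log-linear: for gene g in module m and sample s,
#' `log2 mu_gs = base_g + sqrt(r) f_ms + sqrt(1-r) e_gs + pop_gp + trt_gt`,
#' where `f_ms` is the module's standard-normal latent activity (possibly
#' regressed on the male-trait covariate), `r = within_module_cor`, and
#' counts are drawn NB with `Var = mu + nb_dispersion * mu^2` after a
#' multiplicative library-size factor. Background genes carry independent
#' noise only. Expected within-module correlation of the latent log signal
#' is exactly `r`; the realized count-scale correlation is attenuated by
#' sampling noise.
#'
#' @param n_genes Total number of genes.
#' @param module_sizes Integer vector of planted module sizes; genes beyond
#'   `sum(module_sizes)` are unassigned background.
#' @param n_per_cell Samples per population x treatment cell (study design:
#'   5-6 brains per cell; default 6).
#' @param populations,treatments Factor level labels. Defaults mirror the
#'   three-population, three-treatment design; the first population is the
#'   reference for contrasts.
#' @param within_module_cor Target latent correlation r in (0,1) among genes
#'   of one module (log scale).
#' @param pop_effect_sd SD (log2 scale) of per-gene constitutive population
#'   shifts; 0.3 gives the strong population separation seen on sample PC1.
#' @param trait_slope Module x population matrix of slopes of latent module
#'   activity on the simulated male-trait covariate (standard-normal units).
#'   A vector is recycled across populations. The default plants the
#'   opposing-slope interaction on module 1: +1.5 in population 1, -1.5 in
#'   population 2, 0 elsewhere.
#' @param treatment_effect Module x treatment matrix of log2 shifts applied
#'   to every gene of a module under a treatment. A scalar `x` is expanded to
#'   "module 2 (if present) shifted by `x` under the first treatment". The
#'   default plants a 1 log2-fold shift of module 2 under conspecific
#'   courtship; its genes form the true differential-expression set.
#' @param nb_dispersion Per-gene NB dispersion alpha in `Var = mu + alpha mu^2`
#'   (scalar or length `n_genes`); 0 gives the Poisson limit.
#' @param lib_size_range Range of multiplicative library-size factors,
#'   drawn log-uniform.
#' @param seed Integer seed governing all randomness of one dataset.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       module_sizes = c(100, 100, 100),
                       n_per_cell = 6,
                       populations = c("Paxton_limnetic", "Paxton_benthic",
                                       "Priest_limnetic"),
                       treatments = c("conspecific", "heterospecific",
                                      "female-control"),
                       within_module_cor = 0.7,
                       pop_effect_sd = 0.3,
                       trait_slope = NULL,
                       treatment_effect = NULL,
                       nb_dispersion = 0.05,
                       lib_size_range = c(0.7, 1.4),
                       seed = 1) {
  n_mod <- length(module_sizes)
  n_pop <- length(populations)
  n_trt <- length(treatments)

  if (length(n_genes) != 1 || n_genes < 1 || n_genes != round(n_genes))
    config_error("n_genes", "must be a positive integer")
  if (n_mod > 0 && (any(module_sizes < 1) || any(module_sizes != round(module_sizes))))
    config_error("module_sizes", "must be positive integers")
  if (sum(module_sizes) > n_genes)
    config_error("module_sizes", "sum exceeds n_genes")
  if (length(n_per_cell) != 1 || n_per_cell < 1)
    config_error("n_per_cell", "must be a positive integer")
  if (!is.numeric(within_module_cor) || within_module_cor <= 0 ||
      within_module_cor >= 1)
    config_error("within_module_cor", "must lie in (0, 1)")
  if (pop_effect_sd < 0) config_error("pop_effect_sd", "must be >= 0")
  if (any(nb_dispersion < 0)) config_error("nb_dispersion", "must be >= 0")
  if (!length(nb_dispersion) %in% c(1L, n_genes))
    config_error("nb_dispersion", "must be scalar or length n_genes")
  if (length(lib_size_range) != 2 || any(lib_size_range <= 0) ||
      diff(lib_size_range) < 0)
    config_error("lib_size_range", "must be an increasing positive pair")
  if (anyDuplicated(populations)) config_error("populations", "has duplicates")
  if (anyDuplicated(treatments)) config_error("treatments", "has duplicates")

  if (is.null(trait_slope)) {
    trait_slope <- matrix(0, n_mod, n_pop)
    if (n_mod >= 1 && n_pop >= 2) {
      trait_slope[1, 1] <- 1.5
      trait_slope[1, 2] <- -1.5
    }
  } else if (!is.matrix(trait_slope)) {
    if (length(trait_slope) == 1) trait_slope <- rep(trait_slope, n_mod)
    if (length(trait_slope) != n_mod)
      config_error("trait_slope", "must have one entry (or row) per module")
    trait_slope <- matrix(trait_slope, n_mod, n_pop)
  }
  if (!all(dim(trait_slope) == c(n_mod, n_pop)))
    config_error("trait_slope", "must be a module x population matrix")

  if (is.null(treatment_effect)) treatment_effect <- 1
  if (!is.matrix(treatment_effect)) {
    if (length(treatment_effect) != 1)
      config_error("treatment_effect", "must be a scalar or module x treatment matrix")
    eff <- matrix(0, n_mod, n_trt)
    if (treatment_effect != 0 && n_mod >= 2) eff[2, 1] <- treatment_effect
    treatment_effect <- eff
  }
  if (!all(dim(treatment_effect) == c(n_mod, n_trt)))
    config_error("treatment_effect", "must be a module x treatment matrix")

  structure(list(
    n_genes = as.integer(n_genes), module_sizes = as.integer(module_sizes),
    n_per_cell = as.integer(n_per_cell), populations = populations,
    treatments = treatments, within_module_cor = within_module_cor,
    pop_effect_sd = pop_effect_sd, trait_slope = trait_slope,
    treatment_effect = treatment_effect, nb_dispersion = nb_dispersion,
    lib_size_range = lib_size_range, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      length(x$module_sizes), "planted modules (",
      paste(x$module_sizes, collapse = ", "), "genes ),",
      length(x$populations), "populations x", length(x$treatments),
      "treatments x", x$n_per_cell, "per cell; seed", x$seed, "\n")
  invisible(x)
}

# Trait loading patterns: five male-morphology and five male-behaviour
# measurements load on two latent male factors each; four female-behaviour
# measurements load on two female factors. Factor 1 of the male-morphology
# block is the covariate that planted module slopes act on.
.trait_blocks <- list(
  Fbehav = list(n = 4, l1 = c(0.9, 0.8, 0.7, -0.6), l2 = c(0.1, -0.2, 0.4, 0.6)),
  Mbehav = list(n = 5, l1 = c(0.9, 0.85, 0.8, 0.6, -0.5), l2 = c(-0.2, 0.2, -0.1, 0.6, 0.6)),
  Mmorph = list(n = 5, l1 = c(0.9, 0.85, 0.8, 0.7, 0.6), l2 = c(-0.2, 0.2, -0.3, 0.4, 0.5))
)

#' Simulate a study dataset with planted structure
#'
#' Draws counts, sample metadata and per-trial trait measurements from the
#' generative model described in [sim_config()], returning the ground truth
#' needed to score every downstream stage.
#'
#' Male-trait measurements (and the covariate driving planted slopes) exist
#' only for courtship treatments; female-control samples carry `NA` in the
#' male blocks, which forces downstream models to define their analysis set.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_dataset` with elements `counts` (gene x
#'   sample integer matrix), `samples` (data.frame: sample_id, population,
#'   treatment, read_mapping_pct), `traits` (data.frame of per-trial
#'   measurements in three named blocks), and `truth` (list: module_of_gene,
#'   latent_activity, true_interaction_modules, true_de_genes, trait_latent).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cf <- config
  n_mod <- length(cf$module_sizes)
  n_pop <- length(cf$populations)
  n_trt <- length(cf$treatments)
  n_samp <- n_pop * n_trt * cf$n_per_cell

  with_seed(cf$seed, {
    samples <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n_samp)),
      population = factor(rep(cf$populations, each = n_trt * cf$n_per_cell),
                          levels = cf$populations),
      treatment = factor(rep(rep(cf$treatments, each = cf$n_per_cell), n_pop),
                         levels = cf$treatments),
      stringsAsFactors = FALSE
    )
    samples$read_mapping_pct <- runif(n_samp, 0.80, 0.98)
    is_courtship <- samples$treatment != "female-control"

    # Latent trait factors; male factors only exist where a male was present.
    male1 <- ifelse(is_courtship, rnorm(n_samp), NA_real_)   # the covariate
    male2 <- ifelse(is_courtship, rnorm(n_samp), NA_real_)
    fem1 <- rnorm(n_samp)
    fem2 <- rnorm(n_samp)

    mk_block <- function(bl, f1, f2) {
      sapply(seq_len(bl$n), function(j)
        bl$l1[j] * f1 + bl$l2[j] * f2 + 0.3 * rnorm(n_samp))
    }
    traits <- data.frame(sample_id = samples$sample_id)
    for (nm in names(.trait_blocks)) {
      f1 <- if (nm == "Fbehav") fem1 else male1
      f2 <- if (nm == "Fbehav") fem2 else male2
      blk <- mk_block(.trait_blocks[[nm]], f1, f2)
      colnames(blk) <- sprintf("%s_%d", nm, seq_len(.trait_blocks[[nm]]$n))
      traits <- cbind(traits, as.data.frame(blk))
    }

    # Module latent activity: slope on the male-trait covariate (0 where no
    # male was present) plus unit noise.
    x_eff <- ifelse(is_courtship, male1, 0)
    pop_idx <- as.integer(samples$population)
    latent <- matrix(rnorm(n_samp * max(n_mod, 1L)), n_samp, max(n_mod, 1L))
    if (n_mod > 0) {
      for (m in seq_len(n_mod))
        latent[, m] <- latent[, m] + cf$trait_slope[m, pop_idx] * x_eff
      colnames(latent) <- sprintf("M%d", seq_len(n_mod))
    }

    gene_ids <- sprintf("G%05d", seq_len(cf$n_genes))
    module_of_gene <- rep("unassigned", cf$n_genes)
    if (n_mod > 0)
      module_of_gene[seq_len(sum(cf$module_sizes))] <-
        rep(sprintf("M%d", seq_len(n_mod)), cf$module_sizes)
    names(module_of_gene) <- gene_ids

    # log2 baseline spans ~32-4096 expected counts: deep bulk libraries
    # (tens of millions of reads over ~2e4 genes) put most genes here, and
    # it keeps count-sampling noise from swamping the planted log-scale
    # correlation structure.
    base_log2 <- runif(cf$n_genes, 5, 12)
    r <- cf$within_module_cor
    # Background genes have constant log-mean, so their count marginals are
    # exactly NB(mu, alpha); module genes add the unit-variance log2 signal
    # sqrt(r) * factor + sqrt(1 - r) * noise that yields expected
    # within-module correlation r on the log scale.
    noise <- matrix(rnorm(cf$n_genes * n_samp), cf$n_genes, n_samp)
    log2mu <- matrix(base_log2, cf$n_genes, n_samp)
    for (m in seq_len(n_mod)) {
      gi <- which(module_of_gene == sprintf("M%d", m))
      log2mu[gi, ] <- base_log2[gi] +
        sqrt(r) * matrix(latent[, m], length(gi), n_samp, byrow = TRUE) +
        sqrt(1 - r) * noise[gi, ]
    }
    if (cf$pop_effect_sd > 0) {
      pop_shift <- matrix(rnorm(cf$n_genes * n_pop, sd = cf$pop_effect_sd),
                          cf$n_genes, n_pop)
      log2mu <- log2mu + pop_shift[, pop_idx]
    }
    trt_idx <- as.integer(samples$treatment)
    for (m in seq_len(n_mod)) {
      if (all(cf$treatment_effect[m, ] == 0)) next
      gi <- which(module_of_gene == sprintf("M%d", m))
      log2mu[gi, ] <- log2mu[gi, ] +
        matrix(cf$treatment_effect[m, trt_idx], length(gi), n_samp, byrow = TRUE)
    }

    lib <- exp(runif(n_samp, log(cf$lib_size_range[1]), log(cf$lib_size_range[2])))
    mu <- 2^log2mu * matrix(lib, cf$n_genes, n_samp, byrow = TRUE)
    alpha <- rep(cf$nb_dispersion, length.out = cf$n_genes)
    counts <- matrix(0L, cf$n_genes, n_samp,
                     dimnames = list(gene_ids, samples$sample_id))
    pois <- alpha == 0
    if (any(pois))
      counts[pois, ] <- matrix(rpois(sum(pois) * n_samp, mu[pois, ]),
                               sum(pois), n_samp)
    if (any(!pois))
      counts[!pois, ] <- matrix(
        rnbinom(sum(!pois) * n_samp, mu = mu[!pois, ],
                size = 1 / alpha[!pois]),
        sum(!pois), n_samp)
    storage.mode(counts) <- "integer"

    de_rows <- which(apply(cf$treatment_effect != 0, 1, any))
    int_rows <- which(apply(cf$trait_slope, 1, function(z) max(z) - min(z) > 0))
    truth <- list(
      module_of_gene = module_of_gene,
      latent_activity = `rownames<-`(latent[, seq_len(n_mod), drop = FALSE],
                                     samples$sample_id),
      true_interaction_modules = sprintf("M%d", int_rows),
      true_de_genes = gene_ids[module_of_gene %in% sprintf("M%d", de_rows)],
      trait_latent = data.frame(sample_id = samples$sample_id,
                                male_trait = male1)
    )
    structure(list(counts = counts, samples = samples, traits = traits,
                   truth = truth, config = cf),
              class = "sim_dataset")
  })
}

#' Simulate a global-null dataset
#'
#' Convenience wrapper around [simulate_dataset()] that zeroes every planted
#' effect (population shifts, trait slopes, treatment shifts) while keeping
#' the module correlation structure; the truth sets come back empty. Under
#' this configuration downstream permutation eFDRs must be uniform.
#'
#' @inheritParams simulate_dataset
#' @return A `sim_dataset`; `true_interaction_modules` and `true_de_genes`
#'   are empty.
#' @export
simulate_null_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  config$pop_effect_sd <- 0
  config$trait_slope[] <- 0
  config$treatment_effect[] <- 0
  simulate_dataset(config)
}

#' Write a simulated dataset to disk
#'
#' Counts as TSV (genes as rows, first column `gene_id`, header the sample
#' ids) and optionally MatrixMarket with sidecar name files; metadata and
#' traits as CSV; ground truth as JSON. Output bytes are a pure function of
#' the dataset, so a fixed-seed simulation round-trips bit-identically.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @param matrixmarket Also write `counts.mtx` + `genes.txt`/`samples.txt`.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(sim, dir, matrixmarket = FALSE) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.csv"),
             traits = file.path(dir, "traits.csv"),
             truth = file.path(dir, "truth.json"))
  write_counts_tsv(sim$counts, files["counts"])
  data.table::fwrite(sim$samples, files["samples"])
  data.table::fwrite(sim$traits, files["traits"])
  truth <- sim$truth
  truth$latent_activity <- as.data.frame(truth$latent_activity)
  jsonlite::write_json(truth, files["truth"], digits = NA, auto_unbox = FALSE)
  if (matrixmarket) {
    files <- c(files, mtx = file.path(dir, "counts.mtx"))
    write_counts_mtx(sim$counts, files["mtx"])
  }
  invisible(files)
}
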