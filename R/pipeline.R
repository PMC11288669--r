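# End-to-end orchestration: simulate (or read) -> preprocess -> network ->
# models -> eFDR, with a run manifest, derived per-stage seeds, and resume
# support.

#' Pipeline run configuration
#'
#' Exactly one of `sim` (a [sim_config()] for a simulated run) or the three
#' input paths (`counts`, `samples`, `traits`) must be supplied; referenced
#' files must exist at launch.
#'
#' @param out_dir Output directory for all artifacts.
#' @param sim Optional [sim_config()] (or plain list of its arguments).
#' @param counts,samples,traits Optional input file paths (TSV/MTX counts,
#'   CSV metadata, CSV trait table).
#' @param network [network_params()].
#' @param permutation [permutation_config()] (its seed is derived from the
#'   global seed at run time).
#' @param pseudocount VST pseudocount.
#' @param top_fraction Fraction of most-variable genes kept (default 0.9).
#' @param qc List: `enabled`, `margin`, `k_low_mapping`, `exclude`.
#' @param seed Global seed; per-stage seeds are derived by a fixed
#'   labelled-hash scheme ([derive_seed()]).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, counts = NULL, samples = NULL,
                       traits = NULL, network = network_params(),
                       permutation = permutation_config(n_perm = 1000),
                       pseudocount = 1, top_fraction = 0.9,
                       qc = list(), seed = 1) {
  has_paths <- !is.null(counts)
  if (is.null(sim) == !has_paths)
    config_error("sim/counts", "exactly one of a sim config or input paths required")
  if (has_paths) {
    for (f in c(counts, samples, traits))
      if (!is.null(f) && !file.exists(f))
        config_error("inputs", paste("file not found:", f))
    if (is.null(samples)) config_error("samples", "required with counts")
  }
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    sim <- do.call(sim_config, sim)
  if (!inherits(network, "network_params"))
    network <- do.call(network_params, network)
  if (!inherits(permutation, "permutation_config"))
    permutation <- do.call(permutation_config, permutation)
  qc <- utils::modifyList(list(enabled = TRUE, margin = 2, k_low_mapping = 2,
                               exclude = character()), qc)
  structure(list(out_dir = out_dir, sim = sim, counts = counts,
                 samples = samples, traits = traits, network = network,
                 permutation = permutation, pseudocount = pseudocount,
                 top_fraction = top_fraction, qc = qc,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path A YAML file whose keys are the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Executes simulate/load -> preprocess -> network -> models -> eFDR,
#' halting on the first stage error, writing every artifact under
#' `config$out_dir`, and writing a manifest (config echo, package version,
#' per-stage wall-clock and output checksums, QC exclusions) last.
#' Re-running with an identical config reproduces identical outputs (the
#' manifest, which records timings, is the only non-reproducible file).
#' With `resume = TRUE`, stages whose outputs all exist and whose upstream
#' stages were skipped are loaded from disk instead of recomputed.
#'
#' @param config A [run_config()].
#' @param resume Reuse existing stage outputs where possible.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  manifest_stages <- list()
  upstream_ran <- FALSE

  stage <- function(name, outputs, compute, load) {
    paths <- file.path(dir, outputs)
    t0 <- proc.time()[["elapsed"]]
    skip <- resume && !upstream_ran && all(file.exists(paths))
    if (skip) load(paths) else { compute(paths); upstream_ran <<- TRUE }
    manifest_stages[[name]] <<- list(
      executed = !skip,
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = as.list(tools::md5sum(paths)))
    invisible(NULL)
  }

  # -- stage 1: simulate or load inputs ------------------------------------
  if (!is.null(config$sim)) {
    simcf <- config$sim
    simcf$seed <- derive_seed(config$seed, "simulate")
    stage("simulate",
          c("counts.tsv", "samples.csv", "traits.csv", "truth.json"),
          compute = function(paths) {
            ds <- simulate_dataset(simcf)
            write_dataset(ds, dir)
            st$counts <- ds$counts; st$samples <- ds$samples
            st$traits <- ds$traits
          },
          load = function(paths) {
            st$counts <- read_counts(paths[1])
            st$samples <- read_samples(paths[2],
                                       populations = simcf$populations,
                                       treatments = simcf$treatments)
            st$traits <- read_traits(paths[3])
          })
  } else {
    st$counts <- read_counts(config$counts)
    st$samples <- read_samples(config$samples)
    st$traits <- if (is.null(config$traits)) NULL else read_traits(config$traits)
    upstream_ran <- TRUE
  }

  # -- stage 2: preprocess --------------------------------------------------
  stage("preprocess",
        c("vst_filtered.tsv", "pca_scores.tsv", "samples_qc.csv",
          "qc_report.json"),
        compute = function(paths) {
          sf <- estimate_size_factors(st$counts)
          v <- vst(st$counts, sf, config$pseudocount)
          vf <- filter_top_variable(v, config$top_fraction)
          pca <- pca_samples(vf)
          sq <- if (config$qc$enabled)
            flag_qc_samples(pca, st$samples, margin = config$qc$margin,
                            k_low_mapping = config$qc$k_low_mapping,
                            exclude = config$qc$exclude)
          else cbind(st$samples, qc_flags = "")
          keep <- qc_pass(sq)
          st$vst <- vf[, keep, drop = FALSE]
          st$samples_qc <- sq
          write_matrix_tsv(st$vst, paths[1], "gene_id")
          write_matrix_tsv(pca$scores, paths[2], "sample_id")
          data.table::fwrite(sq, paths[3])
          jsonlite::write_json(list(
            transform = attr(v, "transform_tag"),
            top_fraction = config$top_fraction,
            size_factors = as.list(round(sf, 8)),
            excluded = lapply(
              which(sq$qc_flags != ""),
              function(i) list(sample_id = sq$sample_id[i],
                               reason = sq$qc_flags[i]))),
            paths[4], auto_unbox = TRUE, digits = NA)
        },
        load = function(paths) {
          st$vst <- read_matrix_tsv(paths[1])
          st$samples_qc <- as.data.frame(data.table::fread(paths[3]))
          st$samples_qc$qc_flags[is.na(st$samples_qc$qc_flags)] <- ""
        })
  samples_kept <- st$samples_qc[st$samples_qc$qc_flags == "", , drop = FALSE]
  samples_kept$population <- factor(samples_kept$population,
                                    levels = unique(st$samples_qc$population))
  samples_kept$treatment <- factor(samples_kept$treatment,
                                   levels = unique(st$samples_qc$treatment))

  # -- stage 3: network -----------------------------------------------------
  stage("network", c("modules.tsv", "eigengenes.tsv", "network_summary.json"),
        compute = function(paths) {
          cors <- correlation_matrix(st$vst, config$network)
          adj <- signed_adjacency(cors, config$network$power)
          tom <- tom_similarity(adj)
          mods <- detect_modules(tom, config$network)
          merged <- merge_close_modules(st$vst, mods,
                                        config$network$merge_cut_height)
          st$modules <- merged$modules
          st$eigengenes <- merged$eigengenes
          data.table::fwrite(data.table::data.table(
            gene_id = names(st$modules),
            module = as.character(st$modules),
            colour = module_colour_alias(as.character(st$modules))),
            paths[1], sep = "\t")
          write_matrix_tsv(st$eigengenes, paths[2], "sample_id")
          tabs <- table(factor(st$modules, attr(st$modules, "labels")))
          jsonlite::write_json(list(
            params = unclass(config$network),
            module_sizes = as.list(tabs),
            variance_explained =
              as.list(round(attr(st$eigengenes, "variance_explained"), 6))),
            paths[3], auto_unbox = TRUE, digits = NA)
        },
        load = function(paths) {
          mt <- data.table::fread(paths[1])
          st$modules <- relabel_by_size(
            stats::setNames(mt$module, mt$gene_id))
          st$eigengenes <- read_matrix_tsv(paths[2])
        })

  # -- stage 4: trait PCs and contrasts ------------------------------------
  stage("models", c("trait_pcs.csv", "contrasts.tsv"),
        compute = function(paths) {
          st$trait_pcs <- trait_pca(st$traits)
          data.table::fwrite(st$trait_pcs, paths[1])
          idx <- match(samples_kept$sample_id, rownames(st$eigengenes))
          ct <- module_contrasts(st$eigengenes[idx, , drop = FALSE],
                                 samples_kept)
          data.table::fwrite(ct, paths[2], sep = "\t")
        },
        load = function(paths) {
          st$trait_pcs <- read_traits(paths[1])
        })

  # -- stage 5: interaction models + eFDR ----------------------------------
  stage("efdr", c("models_efdr.tsv", "efdr_log.json"),
        compute = function(paths) {
          idx <- match(samples_kept$sample_id, rownames(st$eigengenes))
          eg <- st$eigengenes[idx, , drop = FALSE]
          tp <- st$trait_pcs[match(samples_kept$sample_id,
                                   st$trait_pcs$sample_id), , drop = FALSE]
          pc_cols <- setdiff(names(tp), "sample_id")
          res <- list(); logs <- list()
          for (pc in pc_cols) {
            pcfg <- config$permutation
            pcfg$seed <- derive_seed(config$seed, paste0("efdr:", pc))
            tab <- efdr(eg, samples_kept, tp[[pc]], pcfg)
            tab <- cbind(trait = pc, tab, stringsAsFactors = FALSE)
            res[[pc]] <- tab
            logs[[pc]] <- list(seed = pcfg$seed, n_perm = pcfg$n_perm,
                               degenerate_tally = attr(tab, "degenerate_tally"),
                               analysis_set = attr(tab, "analysis_set"))
          }
          st$models <- do.call(rbind, res)
          data.table::fwrite(st$models, paths[1], sep = "\t")
          jsonlite::write_json(logs, paths[2], auto_unbox = TRUE, digits = NA)
        },
        load = function(paths) {
          st$models <- as.data.frame(data.table::fread(paths[1]))
        })

  manifest <- list(
    package_version = as.character(utils::packageVersion("eigenchoice")),
    seed = config$seed,
    config = jsonlite::fromJSON(jsonlite::toJSON(
      unclass_deep(config), auto_unbox = TRUE, digits = NA, force = TRUE)),
    stages = manifest_stages,
    exclusions = st$samples_qc$sample_id[st$samples_qc$qc_flags != ""])
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

# Recursively strip S3 classes so a config echoes cleanly into JSON.
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (is.matrix(x)) x
  else unclass(x)
}
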