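# Permutation-based empirical FDR for the population-by-trait models:
# response rows are shuffled among samples (design columns never move), the
# type-II ANOVA is recomputed for every shuffle, and each observed
# parametric p is converted to the proportion of shuffles with p at least as
# small.

#' Permutation configuration
#'
#' @param n_perm Number of permutations (default 10 000, the published run;
#'   desk-scale checks typically use 1000).
#' @param seed Integer seed for the permutation plan.
#' @param scope `"per_response"` (each response compared to its own
#'   permutation null) or `"pooled"` (observed p compared to the permuted p
#'   pooled over responses).
#' @param plus_one Use the `(b + 1) / (B + 1)` correction instead of the
#'   plain proportion `b / B`, so the smallest attainable value is
#'   `1/(B + 1)` rather than 0.
#' @param literal_direction Report the literal published reading (proportion
#'   of shuffles with p *greater* than observed, i.e. `1 -` the standard
#'   proportion); kept as a documented alternative only.
#' @return List of class `permutation_config`.
#' @export
permutation_config <- function(n_perm = 10000, seed = 1,
                               scope = c("per_response", "pooled"),
                               plus_one = FALSE, literal_direction = FALSE) {
  scope <- match.arg(scope)
  if (n_perm < 1) config_error("n_perm", "must be >= 1")
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 scope = scope, plus_one = plus_one,
                 literal_direction = literal_direction),
            class = "permutation_config")
}

#' Seeded permutation plan
#'
#' `n_perm` independent uniform permutations of `1..n_samples` from a seeded
#' generator. One plan is applied to every response in a run so that
#' inter-module correlation is preserved under the null.
#'
#' @param n_samples Number of samples (>= 3).
#' @param config [permutation_config()].
#' @return Integer matrix, `n_perm` x `n_samples`; each row a permutation.
#' @export
permutation_plan <- function(n_samples, config = permutation_config()) {
  if (n_samples < 3) stop("need at least 3 samples", call. = FALSE)
  with_seed(config$seed, {
    t(replicate(config$n_perm, sample.int(n_samples)))
  })
}

#' Permutation empirical FDR for model terms
#'
#' For every response column: the observed type-II ANOVA p-value of each
#' term, and the eFDR = proportion of permutations whose recomputed p is
#' less than or equal to the observed p. Rows of the response matrix are
#' reindexed jointly by one permutation plan; the design (population,
#' trait) is never permuted, and shuffling is unrestricted across
#' populations — the documented exchangeability assumption. Degenerate
#' permuted fits get p = 1 and are tallied.
#'
#' @param responses Sample x response numeric matrix (e.g. eigengenes), rows
#'   aligned with `samples`.
#' @param samples Sample metadata.
#' @param trait Per-sample covariate; rows with `NA` trait are excluded
#'   before anything is permuted.
#' @param config [permutation_config()].
#' @return data.frame: response, term, F, df1, df2, p_param, efdr. Attributes:
#'   `n_perm`, `seed`, `degenerate_tally`, `analysis_set`.
#' @export
efdr <- function(responses, samples, trait, config = permutation_config()) {
  check_samples(samples)
  responses <- as.matrix(responses)
  stopifnot(nrow(responses) == nrow(samples), length(trait) == nrow(samples))
  if (is.null(colnames(responses)))
    colnames(responses) <- sprintf("R%d", seq_len(ncol(responses)))
  keep <- !is.na(trait) & stats::complete.cases(responses)
  Y <- responses[keep, , drop = FALSE]
  eng <- .term_engine(samples$population[keep], trait[keep])
  obs <- .term_pvalues(eng, Y)
  terms <- c("population", "trait", "interaction")
  p_obs <- rbind(obs$population$p, obs$trait$p, obs$interaction$p)
  rownames(p_obs) <- terms

  plan <- permutation_plan(nrow(Y), config)
  B <- config$n_perm
  counts <- matrix(0, 3, ncol(Y), dimnames = dimnames(p_obs))
  tally <- 0L
  pooled <- if (config$scope == "pooled")
    stats::setNames(lapply(terms, function(t) vector("list", B)), terms)
  else NULL
  for (b in seq_len(B)) {
    pb <- .term_pvalues(eng, Y[plan[b, ], , drop = FALSE])
    pm <- rbind(pb$population$p, pb$trait$p, pb$interaction$p)
    bad <- !is.finite(pm)
    if (any(bad)) { pm[bad] <- 1; tally <- tally + sum(bad) }
    if (config$scope == "per_response") {
      counts <- counts + (pm <= p_obs)
    } else {
      for (t in seq_along(terms))
        pooled[[t]][[b]] <- pm[t, ]
    }
  }
  ef <- if (config$scope == "per_response") {
    if (config$plus_one) (counts + 1) / (B + 1) else counts / B
  } else {
    out <- counts
    for (t in seq_along(terms)) {
      null_p <- sort(unlist(pooled[[t]]))
      hits <- findInterval(p_obs[t, ], null_p)
      out[t, ] <- if (config$plus_one) (hits + 1) / (length(null_p) + 1)
                  else hits / length(null_p)
    }
    out
  }
  if (config$literal_direction) ef <- 1 - ef

  res <- data.frame(
    response = rep(colnames(Y), each = 3),
    term = rep(c("population", "trait", "population:trait"), ncol(Y)),
    F = as.numeric(rbind(obs$population$F, obs$trait$F, obs$interaction$F)),
    df1 = rep(c(obs$population$df1, obs$trait$df1, obs$interaction$df1),
              ncol(Y)),
    df2 = obs$df2,
    p_param = as.numeric(p_obs),
    efdr = as.numeric(ef),
    stringsAsFactors = FALSE)
  attr(res, "n_perm") <- B
  attr(res, "seed") <- config$seed
  attr(res, "degenerate_tally") <- tally
  attr(res, "analysis_set") <- as.character(samples$sample_id[keep])
  res
}
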