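#' Configuration of the permutation significance test
#'
#' @param n_permutations Number of permuted matrices (>= 1; default 100,
#'   which resolves the 0.05 significance level with the plus-one
#'   estimator).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param budget_factor Fraction of the full optimizer iteration budget
#'   spent on each permuted matrix, in (0, 1\].
#' @param null_statistic `"reoptimize"` (default): the null value for each
#'   permutation is the re-optimized maximum weight on the permuted matrix,
#'   which accounts for the selection step and is therefore conservative.
#'   `"fixed-set"`: the observed gene set's weight recomputed on the
#'   permuted matrix (cheaper, anti-conservative).
#' @param seed Integer RNG seed for the permutations.
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 100L, alpha = 0.05,
                        budget_factor = 0.5,
                        null_statistic = c("reoptimize", "fixed-set"),
                        seed = 1L) {
  cfg <- list(n_permutations = as.integer(n_permutations),
              alpha = alpha, budget_factor = budget_factor,
              null_statistic = match.arg(null_statistic),
              seed = as.integer(seed))
  stopifnot(cfg$n_permutations >= 1L, cfg$alpha > 0, cfg$alpha < 1,
            cfg$budget_factor > 0, cfg$budget_factor <= 1)
  class(cfg) <- "perm_config"
  cfg
}

#' Permute each gene's mutations independently across patients
#'
#' The null model shuffles every gene column independently over patients,
#' which preserves each gene's marginal mutation frequency exactly (the
#' quantity the fusion covariates model) while destroying any
#' coverage/exclusivity structure between genes — the property under test.
#' Per-patient mutation counts are generally not preserved.
#'
#' @param matrix A [mutation_matrix()].
#' @return A `mutation_matrix` of the same dimensions and labels with
#'   identical column sums. Consumes the current RNG stream.
#' @export
permute_matrix <- function(matrix) {
  stopifnot(is_mutation_matrix(matrix))
  m <- nrow(matrix)
  E <- unclass(matrix)
  if (m > 1L) {
    for (j in seq_len(ncol(E))) E[, j] <- E[sample.int(m), j]
  }
  mutation_matrix(E, rownames(matrix), colnames(matrix))
}

#' Permutation test of an identified pathway's weight
#'
#' Estimates how often gene sets as heavy as the observed one arise when
#' mutations carry no between-gene structure. For each of
#' `config$n_permutations` column-permuted matrices the null statistic is
#' computed (by default the re-optimized maximum weight at the same k and a
#' reduced iteration budget), and the p-value is the plus-one estimator
#' \deqn{p = (1 + \#\{W_{null} \ge W_{obs}\}) / (n_{perm} + 1),}
#' which is never exactly zero.
#'
#' @param matrix The [mutation_matrix()] the result was obtained on.
#' @param result A [pathway_result()] from [mbf_optimize()].
#' @param covariates Per-gene weights used for the original optimization,
#'   or `NULL`.
#' @param config A [perm_config()].
#' @param params The [mbf_params()] of the original optimization; the
#'   per-permutation budget is `max_iter * budget_factor` iterations (and
#'   the restart count scaled the same way, at least 1).
#' @return The `pathway_result` with `p_value` filled in and a
#'   `null_weights` vector of the permuted statistics attached.
#' @export
permutation_test <- function(matrix, result, covariates = NULL,
                             config = perm_config(), params = mbf_params()) {
  stopifnot(inherits(result, "pathway_result"))
  v <- align_covariates(matrix, covariates)
  observed <- weighted_objective(matrix, result$genes, v)
  reduced <- params
  reduced$max_iter <- max(1L, as.integer(round(params$max_iter *
                                                 config$budget_factor)))
  reduced$stagnation <- min(reduced$stagnation, reduced$max_iter)
  reduced$restarts <- max(1L, as.integer(ceiling(params$restarts *
                                                   config$budget_factor)))
  null_weights <- numeric(config$n_permutations)
  for (b in seq_len(config$n_permutations)) {
    set.seed((config$seed + 104729L * b) %% .Machine$integer.max)
    perm <- permute_matrix(matrix)
    null_weights[b] <- if (config$null_statistic == "reoptimize") {
      reduced$seed <- (config$seed + b) %% .Machine$integer.max
      mbf_optimize(perm, result$k, v, reduced)$weight
    } else {
      weighted_objective(perm, result$genes, v)
    }
  }
  result$p_value <- (1 + sum(null_weights >= observed)) /
    (config$n_permutations + 1)
  result$null_weights <- null_weights
  result
}

#' Walk a ranked candidate list until a significant pathway is found
#'
#' Tests candidates in decreasing order of fitness; the first whose
#' permutation p-value reaches `config$alpha` is returned with its p-value
#' attached. If no candidate is significant, returns `NULL` with a warning;
#' the p-values of every tested candidate are available in the
#' `tested_p_values` attribute of the return value (or of the warning
#' condition via the `all_p` field when `NULL`).
#'
#' @param ranked Non-empty list of [pathway_result()] candidates sorted by
#'   decreasing fitness (e.g. the `ranked` field of [mbf_optimize()]).
#' @inheritParams permutation_test
#' @param max_candidates Cap on how many candidates to test (default 10).
#' @return The first significant `pathway_result` (with `tested_p_values`
#'   attribute), or `NULL`.
#' @export
select_significant_pathway <- function(ranked, matrix, covariates = NULL,
                                       config = perm_config(),
                                       params = mbf_params(),
                                       max_candidates = 10L) {
  if (length(ranked) == 0L) {
    stop("ranked candidate list must be non-empty", call. = FALSE)
  }
  tested <- numeric(0)
  for (i in seq_len(min(length(ranked), max_candidates))) {
    cfg_i <- config
    cfg_i$seed <- (config$seed + 7L * (i - 1L)) %% .Machine$integer.max
    cand <- permutation_test(matrix, ranked[[i]], covariates, cfg_i, params)
    tested[paste(cand$gene_ids, collapse = ",")] <- cand$p_value
    if (cand$p_value <= config$alpha) {
      attr(cand, "tested_p_values") <- tested
      return(cand)
    }
  }
  warning(sprintf("no candidate reached significance at alpha = %g (tested %d; p-values: %s)",
                  config$alpha, length(tested),
                  paste(format(tested, digits = 3), collapse = ", ")),
          call. = FALSE)
  NULL
}
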