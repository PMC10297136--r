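#' Random Bernoulli mutation matrix
#'
#' Generates an m x n matrix of i.i.d. Bernoulli(rate) entries — the null
#' background against which planted pathways are hidden, and the kind of
#' random matrix used to study the method's computational scaling
#' (m up to 1000, n up to 10,000). Patients are labeled `P001...`, genes
#' `G001...`.
#'
#' @param m Number of patients (>= 1).
#' @param n Number of genes (>= 1).
#' @param rate Per-entry mutation probability in \[0, 1\].
#' @param seed Integer RNG seed.
#' @return A [mutation_matrix()].
#' @export
random_matrix <- function(m, n, rate = 0.05, seed = 1L) {
  stopifnot(m >= 1, n >= 1, rate >= 0, rate <= 1)
  set.seed(as.integer(seed))
  entries <- matrix(stats::rbinom(m * n, 1L, rate), m, n)
  mutation_matrix(entries, default_labels("P", m), default_labels("G", n))
}

#' Mutation matrix with a planted high-coverage, high-exclusivity pathway
#'
#' Emulates the structure a driver pathway leaves in somatic mutation data:
#' `k_planted` genes jointly cover a `coverage` fraction of patients, with
#' most covered patients carrying exactly one planted mutation. Each
#' patient is covered independently with probability `coverage`; a covered
#' patient receives one planted mutation (uniformly chosen) with
#' probability `1 - co_mutation_rate`, otherwise two distinct planted
#' mutations (the minimal departure from perfect exclusivity). Every other
#' entry is i.i.d. Bernoulli(`background_rate`) passenger noise.
#'
#' @param m Number of patients.
#' @param n Number of genes (`k_planted <= n`); the planted genes occupy
#'   columns drawn at random.
#' @param k_planted Size of the planted gene set.
#' @param coverage Probability a patient is covered by the planted set.
#' @param co_mutation_rate Probability a covered patient carries two
#'   planted mutations instead of one.
#' @param background_rate Bernoulli rate of passenger entries; must be
#'   below `coverage` or the planting is undetectable by construction.
#' @param seed Integer RNG seed.
#' @return A list with `matrix` (the [mutation_matrix()]) and `planted`
#'   (sorted integer indices of the planted genes).
#' @examples
#' sim <- planted_matrix(m = 100, n = 40, k_planted = 3, seed = 2)
#' coverage_fraction(sim$matrix, sim$planted)
#' @export
planted_matrix <- function(m = 200L, n = 100L, k_planted = 4L,
                           coverage = 0.8, co_mutation_rate = 0.05,
                           background_rate = 0.02, seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1,
            co_mutation_rate >= 0, co_mutation_rate <= 1,
            background_rate >= 0, k_planted <= n, m >= 1)
  if (coverage > 0 && background_rate >= coverage) {
    stop("background_rate must be below coverage for the planted set to be detectable",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  entries <- matrix(stats::rbinom(m * n, 1L, background_rate), m, n)
  planted <- sort(sample.int(n, k_planted))
  entries[, planted] <- 0L
  covered <- which(stats::runif(m) < coverage)
  for (i in covered) {
    if (k_planted >= 2L && stats::runif(1) < co_mutation_rate) {
      entries[i, sample(planted, 2L)] <- 1L
    } else {
      entries[i, sample(planted, 1L)] <- 1L
    }
  }
  list(matrix = mutation_matrix(entries, default_labels("P", m),
                                default_labels("G", n)),
       planted = planted)
}

#' Mutually correlated gene covariates from a shared latent factor
#'
#' Generates expression level, replication time, and chromosome status as
#' \eqn{\sqrt{\rho} \cdot \ell + \sqrt{1-\rho} \cdot \epsilon} with a
#' shared standard-normal latent factor \eqn{\ell} and independent noise
#' \eqn{\epsilon}, so all pairwise correlations are approximately `rho` —
#' the strongly correlated regime in which one principal component captures
#' the three covariates.
#'
#' @param n Number of genes (>= 2).
#' @param correlation Target pairwise correlation in \[0, 1).
#' @param seed Integer RNG seed.
#' @return A [covariate_table()] with genes labeled `G001...`.
#' @export
correlated_covariates <- function(n, correlation = 0.8, seed = 1L) {
  stopifnot(n >= 2, correlation >= 0, correlation < 1)
  set.seed(as.integer(seed))
  latent <- stats::rnorm(n)
  col <- function() sqrt(correlation) * latent +
    sqrt(1 - correlation) * stats::rnorm(n)
  covariate_table(default_labels("G", n), col(), col(), col())
}
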