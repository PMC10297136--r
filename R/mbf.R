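#' Parameters of the Mouth Brooding Fish optimizer
#'
#' The metaheuristic keeps a school of `n_fish` candidate solutions
#' ("cichlids") encoded as continuous positions in the unit hypercube. Each
#' iteration every non-elite cichlid is attracted toward the incumbent best
#' position (the "mother") with strength `sp`, damped geometrically by
#' `sp_damp`; with probability `p_dis` a cichlid instead disperses from the
#' mother — it restarts at her position with `ceiling(dis)` coordinates
#' exchanged (uniformly chosen genes leave and enter the selected set),
#' probing the incumbent's neighborhood in subset space. The five named
#' parameters and their defaults (SP = 0.6,
#' nFish = 50, Dis = 1.8, Pdis = 0.2, SPdamp = 0.95) are the standard
#' calibration of the algorithm, derived from observed mouth brooding fish
#' behavior.
#'
#' @param sp Mother-position attraction strength (> 0).
#' @param n_fish Population size (>= 2).
#' @param dis Dispersal distance: `ceiling(dis)` coordinates of a
#'   dispersing cichlid are exchanged between the selected and unselected
#'   bands (a `ceiling(dis)/2`-gene swap of the incumbent set).
#' @param p_dis Per-cichlid dispersal probability in \[0, 1\].
#' @param sp_damp Per-iteration multiplicative damping of `sp`, in (0, 1\].
#' @param max_iter Iteration cap per run (>= 1).
#' @param stagnation Stop a run early after this many iterations without
#'   incumbent improvement.
#' @param restarts Number of independent restarts; the best result over all
#'   restarts is returned.
#' @param seed Integer RNG seed; every source of randomness in the
#'   optimizer flows from it.
#' @return A list of class `mbf_params`.
#' @export
mbf_params <- function(sp = 0.6, n_fish = 50L, dis = 1.8, p_dis = 0.2,
                       sp_damp = 0.95, max_iter = 200L, stagnation = 50L,
                       restarts = 3L, seed = 1L) {
  p <- list(sp = sp, n_fish = as.integer(n_fish), dis = dis, p_dis = p_dis,
            sp_damp = sp_damp, max_iter = as.integer(max_iter),
            stagnation = as.integer(stagnation),
            restarts = as.integer(restarts),
            seed = as.integer(seed))
  stopifnot(p$sp > 0, p$n_fish >= 2L, p$dis > 0,
            p$p_dis >= 0, p$p_dis <= 1,
            p$sp_damp > 0, p$sp_damp <= 1,
            p$max_iter >= 1L, p$stagnation >= 1L, p$restarts >= 1L)
  class(p) <- "mbf_params"
  p
}

#' Decode a continuous position into a k-gene set
#'
#' The cardinality constraint is enforced by construction: a position in
#' \eqn{[0,1]^n} decodes to the indices of its k largest components, so
#' every candidate the optimizer visits is a valid k-subset. Ties are broken
#' by lowest gene index, making the decode deterministic.
#'
#' @param position Numeric vector of length n.
#' @param k Number of genes to select (1 <= k <= n).
#' @return Sorted integer vector of k gene indices.
#' @export
decode_position <- function(position, k) {
  n <- length(position)
  k <- as.integer(k)
  if (k > n) stop(sprintf("k = %d exceeds the number of genes n = %d", k, n),
                  call. = FALSE)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  sort(order(position, decreasing = TRUE)[seq_len(k)])
}

## Problem context precomputed once per optimization: numeric copy of the
## matrix and the per-gene penalty terms v_j * |Gamma(j)|.
mbf_problem <- function(matrix, covariates, k) {
  stopifnot(is_mutation_matrix(matrix))
  v <- align_covariates(matrix, covariates)
  k <- as.integer(k)
  if (k > ncol(matrix)) {
    stop(sprintf("k = %d exceeds the number of genes n = %d", k, ncol(matrix)),
         call. = FALSE)
  }
  A <- matrix
  class(A) <- "matrix"
  storage.mode(A) <- "double"
  list(A = A, penalty = v * colSums(A), n = ncol(A), k = k)
}

## Canonical re-encoding of an incumbent position: selected coordinates are
## mapped into (0.75, 1], unselected into (0, 0.5], preserving within-group
## ranks. Decode is unchanged, but a dispersal probe that redraws a
## coordinate uniformly then has a threshold-independent chance (~1/4) of
## moving a gene in or out of the set, however much attraction has
## compressed the school.
canonical_position <- function(position, genes) {
  n <- length(position)
  out <- rank(position, ties.method = "first") / (2 * n)
  out[genes] <- 0.75 + 0.25 * rank(position[genes],
                                   ties.method = "first") / length(genes)
  out
}

## Vectorized fitness of a whole population: the top-k decode of all fish is
## taken with k passes of max.col (ties to the lowest index, matching
## decode_position), and fitness needs one m x n_fish matrix product.
eval_positions <- function(prob, positions) {
  f <- nrow(positions)
  k <- prob$k
  scratch <- positions
  picks <- matrix(0L, f, k)
  for (j in seq_len(k)) {
    mc <- max.col(scratch, ties.method = "first")
    picks[, j] <- mc
    scratch[cbind(seq_len(f), mc)] <- -Inf
  }
  Y <- matrix(0, prob$n, f)
  Y[cbind(as.vector(t(picks)), rep(seq_len(f), each = k))] <- 1
  hits <- prob$A %*% Y
  fitness <- 2 * colSums(hits > 0) - as.vector(crossprod(prob$penalty, Y))
  # recover each fish's sorted gene set from Y in one pass: column-major
  # order of the nonzero entries is ascending within each fish
  rows <- (which(Y == 1) - 1L) %% prob$n + 1L
  decoded <- lapply(seq_len(f), function(i) rows[((i - 1L) * k + 1L):(i * k)])
  list(decoded = decoded, fitness = fitness)
}

#' Initialize a Mouth Brooding Fish population
#'
#' Draws `n_fish` positions uniformly on the unit hypercube and evaluates
#' their fitness. Consumes the current RNG stream, so a preceding
#' `set.seed()` makes the population reproducible ([mbf_optimize()] seeds
#' for you).
#'
#' @param matrix A [mutation_matrix()].
#' @param k Gene-set size.
#' @param covariates Per-gene weights (see [align_covariates()]) or `NULL`.
#' @param params An [mbf_params()] object.
#' @return A list of class `mbf_population` with `positions` (n_fish x n),
#'   `fitness`, `decoded` (list of gene-index vectors), `sp` (current
#'   attraction strength) and `best` (list: `position`, `genes`, `fitness`).
#' @export
initialize_population <- function(matrix, k, covariates = NULL,
                                  params = mbf_params()) {
  init_population(mbf_problem(matrix, covariates, k), params)
}

init_population <- function(prob, params) {
  positions <- matrix(stats::runif(params$n_fish * prob$n),
                      nrow = params$n_fish, ncol = prob$n)
  ev <- eval_positions(prob, positions)
  b <- which.max(ev$fitness)
  pop <- list(positions = positions, fitness = ev$fitness,
              decoded = ev$decoded, sp = params$sp,
              best = list(position = canonical_position(positions[b, ],
                                                        ev$decoded[[b]]),
                          genes = ev$decoded[[b]],
                          fitness = ev$fitness[b]))
  class(pop) <- "mbf_population"
  pop
}

#' Advance a Mouth Brooding Fish population by one iteration
#'
#' With probability `p_dis` a non-elite cichlid disperses: it is reset to
#' the incumbent best (mother) position and performs a uniform gene swap —
#' `ceiling(dis)` coordinates are exchanged, with `ceiling(dis)/2`
#' uniformly chosen member genes pushed out of the selected band and as
#' many uniformly chosen outside genes pulled in — a local probe of the
#' incumbent's swap neighborhood. Every
#' other non-elite cichlid moves toward the mother by
#' `sp * u * (best - self)` with `u` uniform per coordinate. Positions stay
#' in \[0, 1\]; `sp` is damped by `sp_damp`. The incumbent is replaced only
#' on strict improvement, so its fitness is non-decreasing across
#' iterations.
#'
#' @param pop An `mbf_population` from [initialize_population()].
#' @inheritParams initialize_population
#' @return The updated `mbf_population`.
#' @export
mbf_step <- function(pop, matrix, k, covariates = NULL,
                     params = mbf_params()) {
  step_population(pop, mbf_problem(matrix, covariates, k), params)
}

step_population <- function(pop, prob, params) {
  P <- pop$positions
  f <- nrow(P)
  elite <- which.max(pop$fitness)
  move <- setdiff(seq_len(f), elite)
  disperse <- move[stats::runif(length(move)) < params$p_dis]
  attract <- setdiff(move, disperse)
  if (length(attract) && pop$sp > 0) {
    U <- matrix(stats::runif(length(attract) * prob$n), length(attract), prob$n)
    target <- matrix(pop$best$position, length(attract), prob$n, byrow = TRUE)
    P[attract, ] <- P[attract, ] + pop$sp * U * (target - P[attract, ])
  }
  if (length(disperse) && prob$k < prob$n) {
    # each dispersing cichlid leaves the mother's set by a uniform
    # n_swap-gene exchange: ceiling(dis) coordinates touched, half leaving
    # the selected band, half entering it
    n_swap <- max(1L, min(ceiling(params$dis) %/% 2L, prob$k,
                          prob$n - prob$k))
    outside <- setdiff(seq_len(prob$n), pop$best$genes)
    for (i in disperse) {
      P[i, ] <- pop$best$position
      leave <- pop$best$genes[sample.int(prob$k, n_swap)]
      enter <- outside[sample.int(length(outside), n_swap)]
      P[i, leave] <- stats::runif(n_swap, 0, 0.5)
      P[i, enter] <- stats::runif(n_swap, 0.95, 1)
    }
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  ev <- eval_positions(prob, P)
  pop$positions <- P
  pop$fitness <- ev$fitness
  pop$decoded <- ev$decoded
  b <- which.max(ev$fitness)
  if (ev$fitness[b] > pop$best$fitness) {
    pop$best <- list(position = canonical_position(P[b, ], ev$decoded[[b]]),
                     genes = ev$decoded[[b]],
                     fitness = ev$fitness[b])
  }
  pop$sp <- pop$sp * params$sp_damp
  pop
}

#' Maximize the weighted submatrix objective over k-gene sets
#'
#' Runs `params$restarts` independent Mouth Brooding Fish searches (each
#' seeded deterministically from `params$seed`), each iterating until
#' `max_iter` or until the incumbent has stagnated for `stagnation`
#' iterations, and returns the best gene set found. The result also carries
#' the deduplicated final candidate pool ranked by fitness, which the
#' significance module walks when the top pathway fails the permutation
#' test.
#'
#' @inheritParams initialize_population
#' @return A [pathway_result()] with two extra fields: `ranked`, a list of
#'   candidate results (the returned one first) sorted by decreasing
#'   weight, and `params`, the `mbf_params` used.
#' @examples
#' A <- random_matrix(30, 12, rate = 0.15, seed = 4)
#' res <- mbf_optimize(A, k = 2, params = mbf_params(max_iter = 50, seed = 4))
#' res$weight == exhaustive_search(A, k = 2)$objective
#' @export
mbf_optimize <- function(matrix, k, covariates = NULL,
                         params = mbf_params()) {
  prob <- mbf_problem(matrix, covariates, k)
  v <- align_covariates(matrix, covariates)
  pool <- new.env(parent = emptyenv())
  best_genes <- NULL
  best_fit <- -Inf
  for (r in seq_len(params$restarts)) {
    set.seed((params$seed + 7919L * (r - 1L)) %% .Machine$integer.max)
    pop <- init_population(prob, params)
    stale <- 0L
    for (iter in seq_len(params$max_iter)) {
      prev <- pop$best$fitness
      pop <- step_population(pop, prob, params)
      stale <- if (pop$best$fitness > prev) 0L else stale + 1L
      if (stale >= params$stagnation) break
    }
    record_candidates(pool, pop)
    if (pop$best$fitness > best_fit) {
      best_fit <- pop$best$fitness
      best_genes <- pop$best$genes
    }
  }
  ranked <- ranked_pool(pool)
  out <- pathway_result(matrix, best_genes, v, seed = params$seed)
  out$ranked <- lapply(ranked, function(cand) {
    pathway_result(matrix, cand$genes, v, seed = params$seed)
  })
  out$params <- params
  out
}

record_candidates <- function(pool, pop) {
  cands <- c(pop$decoded, list(pop$best$genes))
  fits <- c(pop$fitness, pop$best$fitness)
  for (i in seq_along(cands)) {
    key <- paste(cands[[i]], collapse = ",")
    if (is.null(pool[[key]])) {
      pool[[key]] <- list(genes = cands[[i]], fitness = fits[i])
    }
  }
}

ranked_pool <- function(pool) {
  cands <- as.list(pool)
  fits <- vapply(cands, `[[`, numeric(1), "fitness")
  keys <- names(cands)
  ord <- order(-fits, keys)
  unname(cands[ord])
}

#' Exhaustively maximize the weighted objective over all k-subsets
#'
#' Brute-force oracle used to validate the metaheuristic on small
#' instances. Enumerates all \eqn{\binom{n}{k}} subsets in lexicographic
#' order and returns the first global maximizer (so ties break
#' lexicographically on the sorted index tuple). Refuses instances with
#' more than `max_subsets` candidates.
#'
#' @inheritParams initialize_population
#' @param max_subsets Guard on \eqn{\binom{n}{k}} (default 1e6).
#' @return A list with `genes` (sorted indices) and `objective`.
#' @export
exhaustive_search <- function(matrix, k, covariates = NULL,
                              max_subsets = 1e6) {
  prob <- mbf_problem(matrix, covariates, k)
  n_sub <- choose(prob$n, prob$k)
  if (n_sub > max_subsets) {
    stop(sprintf("choose(%d, %d) = %.0f subsets exceeds the exhaustive-search guard (%g)",
                 prob$n, prob$k, n_sub, max_subsets), call. = FALSE)
  }
  subsets <- utils::combn(prob$n, prob$k)
  best_val <- -Inf
  best_idx <- NULL
  chunk <- 4096L
  for (start in seq(1L, ncol(subsets), by = chunk)) {
    cols <- start:min(start + chunk - 1L, ncol(subsets))
    Y <- matrix(0, prob$n, length(cols))
    Y[cbind(as.vector(subsets[, cols]),
            rep(seq_along(cols), each = prob$k))] <- 1
    hits <- prob$A %*% Y
    vals <- 2 * colSums(hits > 0) - as.vector(crossprod(prob$penalty, Y))
    w <- which.max(vals)
    if (vals[w] > best_val) {
      best_val <- vals[w]
      best_idx <- subsets[, cols[w]]
    }
  }
  list(genes = sort(best_idx), objective = best_val)
}

#' Scan a range of pathway sizes k and collect the identified driver genes
#'
#' Runs an independent optimization for each k in `k_range` (RNG seed
#' offset by k so runs are decoupled but reproducible) and aggregates the
#' union of identified genes as the driver-gene set.
#'
#' @inheritParams initialize_population
#' @param k_range Integer vector of pathway sizes, each between 1 and n.
#' @return A list of class `pathway_scan` with `results` (one
#'   [pathway_result()] per k) and `driver_genes` (character union of all
#'   identified gene labels, in matrix order).
#' @export
multi_k_scan <- function(matrix, k_range, covariates = NULL,
                         params = mbf_params()) {
  k_range <- as.integer(k_range)
  if (length(k_range) == 0L) stop("k_range must be non-empty", call. = FALSE)
  results <- lapply(k_range, function(k) {
    pk <- params
    pk$seed <- (params$seed + k) %% .Machine$integer.max
    mbf_optimize(matrix, k, covariates, pk)
  })
  idx <- sort(unique(unlist(lapply(results, `[[`, "genes"))))
  out <- list(results = results,
              driver_genes = colnames(matrix)[idx],
              k_range = k_range)
  class(out) <- "pathway_scan"
  out
}

#' @export
print.pathway_scan <- function(x, ...) {
  cat(sprintf("pathway_scan over k = %s\n",
              paste(x$k_range, collapse = ", ")))
  print(as.data.frame(x))
  cat(sprintf("driver genes (union): %s\n",
              paste(x$driver_genes, collapse = " ")))
  invisible(x)
}

#' @export
as.data.frame.pathway_scan <- function(x, ...) {
  do.call(rbind, lapply(x$results, as.data.frame))
}
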