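test_that("decode selects the top-k coordinates with index tie-break", {
  expect_identical(decode_position(c(0.9, 0.1, 0.8, 0.2), 2), c(1L, 3L))
  expect_identical(decode_position(rep(0.5, 5), 3), 1:3)
  expect_identical(decode_position(c(0.2, 0.7, 0.4), 3), 1:3)  # k = n
  expect_error(decode_position(c(0.1, 0.2), 3), "exceeds")
  expect_error(decode_position(c(0.1, 0.2), 0), "at least 1")
})

test_that("population initialization is seeded and cardinality-constrained", {
  A <- random_matrix(20, 10, 0.2, seed = 2)
  p <- mbf_params(n_fish = 17)
  set.seed(99); pop1 <- initialize_population(A, 3, NULL, p)
  set.seed(99); pop2 <- initialize_population(A, 3, NULL, p)
  expect_identical(pop1, pop2)
  expect_equal(nrow(pop1$positions), 17)
  expect_true(all(lengths(pop1$decoded) == 3))
  expect_equal(pop1$best$fitness, max(pop1$fitness))
  # fitness agrees with the scoring module
  for (i in c(1, 8, 17)) {
    expect_equal(pop1$fitness[i], pathway_weight(A, pop1$decoded[[i]]))
  }
})

test_that("stepping keeps the cardinality constraint and a monotone incumbent", {
  A <- random_matrix(40, 12, 0.15, seed = 8)
  p <- mbf_params(seed = 8)
  set.seed(8)
  pop <- initialize_population(A, 3, NULL, p)
  trace <- numeric(30)
  for (it in 1:30) {
    prev <- pop$best$fitness
    pop <- mbf_step(pop, A, 3, NULL, p)
    expect_true(all(lengths(pop$decoded) == 3))
    expect_gte(pop$best$fitness, prev)
    trace[it] <- pop$best$fitness
  }
  expect_gte(trace[30], trace[1])
  # sp is damped each step
  expect_equal(pop$sp, p$sp * p$sp_damp^30, tolerance = 1e-12)
})

test_that("without dispersal and with full attraction the school collapses", {
  A <- random_matrix(25, 8, 0.2, seed = 5)
  p <- mbf_params(sp = 1, p_dis = 0, sp_damp = 1, seed = 5)
  set.seed(5)
  pop <- initialize_population(A, 2, NULL, p)
  for (it in 1:60) pop <- mbf_step(pop, A, 2, NULL, p)
  sets <- vapply(pop$decoded, paste, character(1), collapse = ",")
  expect_equal(length(unique(sets)), 1L)
  expect_identical(pop$decoded[[1L]], pop$best$genes)
})

test_that("exhaustive search enumerates and tie-breaks lexicographically", {
  A <- mutation_matrix(rbind(c(1, 0, 0, 0),
                             c(1, 1, 0, 0),
                             c(0, 0, 1, 0),
                             c(0, 1, 0, 1)))
  # independent oracle: enumerate the 6 pairs by hand via the public scorer
  pairs <- utils::combn(4, 2)
  vals <- apply(pairs, 2, function(g) pathway_weight(A, g))
  best <- pairs[, which.max(vals)]
  ex <- exhaustive_search(A, 2)
  expect_equal(ex$objective, max(vals))
  expect_identical(ex$genes, sort(best))
  expect_identical(exhaustive_search(A, 4)$genes, 1:4)  # k = n
  Z <- mutation_matrix(matrix(0L, 3, 5))
  expect_identical(exhaustive_search(Z, 2)$genes, 1:2)  # lexicographic tie
  expect_equal(exhaustive_search(Z, 2)$objective, 0)
  expect_error(exhaustive_search(random_matrix(5, 40, 0.1, 1), 15),
               "guard")
})

test_that("optimization is deterministic and matches closed forms", {
  A <- random_matrix(50, 15, 0.1, seed = 31)
  p <- mbf_params(seed = 31, max_iter = 80)
  r1 <- mbf_optimize(A, 3, params = p)
  r2 <- mbf_optimize(A, 3, params = p)
  expect_identical(r1[c("genes", "weight", "coverage", "mutex_degree")],
                   r2[c("genes", "weight", "coverage", "mutex_degree")])
  # k = 1 reduces to a scan over single genes
  v <- runif(15, 0.5, 1.5)
  single <- vapply(1:15, function(g) weighted_objective(A, g, v), numeric(1))
  rk1 <- mbf_optimize(A, 1, v, p)
  expect_equal(rk1$weight, max(single))
  expect_identical(rk1$genes, which.max(single))
  expect_error(mbf_optimize(A, 99, params = p), "exceeds")
})

test_that("a dominant planted gene set is recovered and ranked first", {
  sim <- planted_matrix(m = 80, n = 30, k_planted = 3, coverage = 0.9,
                        co_mutation_rate = 0, background_rate = 0.01,
                        seed = 44)
  res <- mbf_optimize(sim$matrix, 3, params = mbf_params(seed = 44))
  expect_identical(res$genes, sim$planted)
  ex <- exhaustive_search(sim$matrix, 3)
  expect_equal(res$weight, ex$objective)
  # ranked candidate pool: sorted, deduplicated, headed by the optimum
  ws <- vapply(res$ranked, `[[`, numeric(1), "weight")
  expect_true(all(diff(ws) <= 0))
  keys <- vapply(res$ranked, function(r) paste(r$genes, collapse = ","),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(res$ranked[[1L]]$genes, res$genes)
})

test_that("multi-k scan runs one seeded optimization per k and unions genes", {
  A <- random_matrix(40, 12, 0.15, seed = 12)
  p <- mbf_params(seed = 12, max_iter = 60)
  scan <- multi_k_scan(A, 2:4, params = p)
  expect_length(scan$results, 3)
  expect_identical(vapply(scan$results, `[[`, integer(1), "k"), 2:4)
  union_idx <- sort(unique(unlist(lapply(scan$results, `[[`, "genes"))))
  expect_identical(scan$driver_genes, colnames(A)[union_idx])
  # k_range of one element equals a plain optimize at the offset seed
  p3 <- p; p3$seed <- p$seed + 3L
  solo <- mbf_optimize(A, 3, params = p3)
  expect_identical(multi_k_scan(A, 3, params = p)$results[[1L]]$genes,
                   solo$genes)
  expect_error(multi_k_scan(A, integer(0), params = p), "non-empty")
  df <- as.data.frame(scan)
  expect_equal(nrow(df), 3)
})
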