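test_that("normalization z-scores with the population variance", {
  tab <- covariate_table(c("a", "b", "c"), c(1, 2, 3), c(5, 5, 5), c(0, 1, 0))
  Z <- normalize_covariates(tab)
  s <- sqrt(2 / 3)  # population sd of (1,2,3)
  expect_equal(Z[, "expression"], c(-1, 0, 1) / s)
  expect_equal(Z[, "replication_time"], c(0, 0, 0))  # constant column
  expect_equal(colMeans(Z), c(expression = 0, replication_time = 0,
                              chromosome_status = 0))
  # idempotence: re-normalizing a standardized column is a no-op
  tab2 <- covariate_table(c("a", "b", "c"), Z[, 1], Z[, 1], Z[, 3])
  expect_equal(normalize_covariates(tab2)[, 1], Z[, 1], tolerance = 1e-12)
  expect_error(covariate_table("a", 1, 1, 1), "at least two")
  expect_error(covariate_table(c("a", "b"), c(1, Inf), c(1, 2), c(1, 2)),
               "non-finite")
})

test_that("covariance of standardized inputs is the correlation matrix", {
  set.seed(7)
  x <- random_standardized(40)
  same <- covariance_matrix(cbind(x, x, x))
  expect_equal(same, matrix(1, 3, 3), ignore_attr = TRUE)
  # pairwise-orthogonal standardized columns -> identity
  q <- qr.Q(qr(matrix(rnorm(40 * 3), 40)))
  q <- apply_zscore(q)
  C <- covariance_matrix(q)
  expect_equal(diag(C), rep(1, 3), tolerance = 1e-6)
  expect_lt(max(abs(C[upper.tri(C)])), 0.3)
  # block structure: x' = y' orthogonal to z'
  z <- random_standardized(40)
  z <- z - x * sum(x * z) / sum(x * x)
  z <- z / sqrt(mean(z^2))
  B <- covariance_matrix(cbind(x, x, z))
  expect_equal(B, rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("leading eigenpair uses the stated sign and tie-break rules", {
  ep <- leading_eigenpair(matrix(1, 3, 3))
  expect_equal(ep$value, 3)
  expect_equal(ep$vector, rep(1 / sqrt(3), 3))
  ep2 <- leading_eigenpair(diag(3))
  expect_equal(ep2$value, 1)
  expect_equal(ep2$vector, c(1, 0, 0))  # degenerate spectrum tie-break
  ep3 <- leading_eigenpair(rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_equal(ep3$value, 2)
  expect_equal(ep3$vector, c(1, 1, 0) / sqrt(2))
  expect_equal(sqrt(sum(ep3$vector^2)), 1, tolerance = 1e-9)
  expect_error(leading_eigenpair(rbind(c(1, 2), c(0, 1))), "symmetric")
})

test_that("fusion composes the pipeline and rescales into (0, inf)", {
  n <- 10
  x <- 1:10  # three perfectly correlated columns (affine copies)
  tab <- covariate_table(paste0("g", 1:n), x, 3 * x + 2, -0 + x / 4)
  fus <- fuse_covariates(tab)
  expect_equal(fus$report$eigenvalue, 3, tolerance = 1e-9)
  expect_equal(fus$report$loadings, rep(1 / sqrt(3), 3), tolerance = 1e-9)
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(fus$report$raw_fused, sqrt(3) * zx, tolerance = 1e-9)
  expect_equal(min(fus$weights), 0.5)
  expect_equal(max(fus$weights), 1.5)
  expect_identical(names(fus$weights), tab$gene)
  # degenerate all-constant table -> neutral weights
  flat <- covariate_table(c("a", "b", "c"), c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  expect_equal(unname(fuse_covariates(flat)$weights), rep(1, 3))
})

test_that("fused weights are invariant to affine transforms of each column", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 30
    tab <- correlated_covariates(n, 0.6, seed = rep)
    shifted <- covariate_table(tab$gene,
                               5 - 2 * tab$expression,
                               0.1 * tab$replication_time + 7,
                               tab$chromosome_status * 100)
    f1 <- fuse_covariates(tab)
    f2 <- fuse_covariates(shifted)
    # flipping a column's sign flips its loading; weights agree up to the
    # eigenvector sign convention, so compare against both orientations
    d <- min(max(abs(f2$weights - f1$weights)),
             max(abs(f2$weights - (2 - f1$weights))))
    expect_lt(d, 1e-9)
    expect_true(all(f1$weights > 0))
    expect_gte(f1$report$eigenvalue, 1 - 1e-9)
    expect_lte(f1$report$eigenvalue, 3 + 1e-9)
  }
})

test_that("loadings are equivariant under permuting the three columns", {
  tab <- correlated_covariates(50, 0.5, seed = 3)
  perm <- covariate_table(tab$gene, tab$replication_time,
                          tab$chromosome_status, tab$expression)
  a <- fuse_covariates(tab)$report$loadings
  b <- fuse_covariates(perm)$report$loadings
  expect_equal(b, a[c(2, 3, 1)], tolerance = 1e-9)
})

test_that("alignment matches labels and defaults missing genes to 1", {
  A <- toy_matrix()
  fus <- fuse_covariates(covariate_table(
    c("KRAS", "TP53", "NF1", "EGFR", "STK11"),
    c(1, 2, 3, 4, 5), c(2, 1, 5, 3, 4), c(1, 1, 0, 0, 1)))
  v <- align_covariates(A, fus)
  expect_length(v, 4)
  expect_equal(v[1], unname(fus$weights["TP53"]))
  expect_equal(v[4], unname(fus$weights["STK11"]))
  partial <- fus$weights[c("KRAS", "EGFR")]
  expect_warning(v2 <- align_covariates(A, partial), "neutral weight")
  expect_equal(v2[c(1, 4)], c(1, 1))
  expect_equal(align_covariates(A, NULL), rep(1, 4))
})
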