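#' Construct a per-gene covariate table
#'
#' Holds the three covariates known to track regional mutation-rate
#' heterogeneity: gene expression level, DNA replication time, and
#' chromosome (chromatin) status. They are strongly mutually correlated,
#' which is what makes a single principal component an adequate summary.
#'
#' @param gene_ids Character vector of n unique gene labels (n >= 2).
#' @param expression,replication_time,chromosome_status Numeric vectors of
#'   length n, finite.
#' @return A `data.frame` of class `covariate_table` with those four columns.
#' @export
covariate_table <- function(gene_ids, expression, replication_time,
                            chromosome_status) {
  gene_ids <- as.character(gene_ids)
  n <- length(gene_ids)
  if (n < 2L) stop("need at least two genes", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids", call. = FALSE)
  cols <- list(expression = expression,
               replication_time = replication_time,
               chromosome_status = chromosome_status)
  for (nm in names(cols)) {
    v <- as.numeric(cols[[nm]])
    if (length(v) != n) {
      stop(sprintf("%s has length %d, expected %d", nm, length(v), n),
           call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop(sprintf("%s contains non-finite values", nm), call. = FALSE)
    }
    cols[[nm]] <- v
  }
  out <- data.frame(gene = gene_ids, cols, stringsAsFactors = FALSE)
  class(out) <- c("covariate_table", class(out))
  out
}

#' Z-score the three covariate columns
#'
#' Centers and scales each covariate to mean 0 and standard deviation 1,
#' using the population (1/n) variance convention. A constant column maps to
#' all zeros rather than dividing by zero, so an uninformative covariate
#' simply drops out of the fusion.
#'
#' @param table A [covariate_table()].
#' @return An n x 3 numeric matrix with columns `expression`,
#'   `replication_time`, `chromosome_status`.
#' @export
normalize_covariates <- function(table) {
  stopifnot(inherits(table, "covariate_table"))
  X <- as.matrix(table[, c("expression", "replication_time",
                           "chromosome_status")])
  apply_zscore(X)
}

apply_zscore <- function(X) {
  n <- nrow(X)
  ctr <- sweep(X, 2, colMeans(X))
  sd_pop <- sqrt(colMeans(ctr^2))
  keep <- sd_pop > 0
  ctr[, keep] <- sweep(ctr[, keep, drop = FALSE], 2, sd_pop[keep], "/")
  ctr[, !keep] <- 0
  ctr
}

#' Covariance matrix of the normalized covariates
#'
#' Population covariance (1/n). With z-scored inputs this is the 3 x 3
#' correlation matrix of the covariates (unit diagonal except for
#' zero-variance columns).
#'
#' @param normalized An n x 3 matrix as returned by [normalize_covariates()].
#' @return A symmetric positive semi-definite 3 x 3 matrix.
#' @export
covariance_matrix <- function(normalized) {
  X <- as.matrix(normalized)
  ctr <- sweep(X, 2, colMeans(X))
  crossprod(ctr) / nrow(ctr)
}

#' Leading eigenvalue and unit eigenvector of a symmetric matrix
#'
#' Extracts the largest eigenvalue and its unit eigenvector (the first
#' principal component loadings). Two conventions make the result
#' deterministic across linear-algebra backends: the sign is fixed so that
#' the component sum is positive (first nonzero component positive if the
#' sum is zero), and when the top eigenvalue is degenerate the returned
#' vector is the normalized projection of the first standard basis vector
#' onto the top eigenspace (falling back to later basis vectors if that
#' projection vanishes) — for a fully degenerate spectrum this yields the
#' first standard basis vector.
#'
#' @param cov A symmetric numeric matrix (asymmetry beyond 1e-9 is an error).
#' @param tol Degeneracy tolerance on eigenvalue gaps.
#' @return A list with `value` (largest eigenvalue) and `vector`
#'   (unit-norm loadings).
#' @export
leading_eigenpair <- function(cov, tol = 1e-9) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov) ||
      max(abs(cov - t(cov))) > 1e-9 * max(1, max(abs(cov)))) {
    stop("covariance matrix must be symmetric", call. = FALSE)
  }
  es <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  lambda <- es$values[1L]
  top <- which(es$values >= lambda - tol * max(1, abs(lambda)))
  V <- es$vectors[, top, drop = FALSE]
  vec <- es$vectors[, 1L]
  if (length(top) > 1L) {
    for (j in seq_len(nrow(cov))) {
      proj <- V %*% crossprod(V, diag(nrow(cov))[, j])
      if (sqrt(sum(proj^2)) > tol) {
        vec <- as.vector(proj) / sqrt(sum(proj^2))
        break
      }
    }
  }
  s <- sum(vec)
  if (abs(s) > tol) {
    if (s < 0) vec <- -vec
  } else {
    nz <- which(abs(vec) > tol)
    if (length(nz) && vec[nz[1L]] < 0) vec <- -vec
  }
  list(value = lambda, vector = vec)
}

#' Fuse the three gene covariates into one positive per-gene weight
#'
#' Runs the full principal-component fusion: z-score each covariate, form
#' their correlation matrix, take the leading unit eigenvector
#' \eqn{a = (a_1, a_2, a_3)}, and project each gene onto it,
#' \eqn{\upsilon_j = a_1 x'_j + a_2 y'_j + a_3 z'_j}. Because the raw
#' projection is centered (and so takes negative values), it is affinely
#' rescaled to the interval `bounds` (default \[0.5, 1.5\]) so every weight
#' is strictly positive and the average gene sits near the neutral weight 1.
#' A degenerate (constant) projection maps to all ones.
#'
#' @param table A [covariate_table()].
#' @param bounds Length-2 numeric, the positive target interval for the
#'   rescaled weights; `bounds[1] > 0`, `bounds[2] > bounds[1]`.
#' @return A list of class `covariate_fusion` with elements:
#'   `weights` (named numeric vector, one per gene), and `report` — a list
#'   with `eigenvalue`, `loadings` (unit vector), `raw_fused` (pre-rescale
#'   scores), and `rescale_bounds`.
#' @examples
#' tab <- covariate_table(paste0("G", 1:4), c(1, 2, 3, 4), c(2, 4, 6, 8),
#'                        c(0, 1, 2, 3))
#' fus <- fuse_covariates(tab)
#' fus$report$loadings  # (1,1,1)/sqrt(3): perfectly correlated covariates
#' @export
fuse_covariates <- function(table, bounds = c(0.5, 1.5)) {
  stopifnot(length(bounds) == 2L, bounds[1L] > 0, bounds[2L] > bounds[1L])
  Z <- normalize_covariates(table)
  C <- covariance_matrix(Z)
  ep <- leading_eigenpair(C)
  raw <- as.vector(Z %*% ep$vector)
  rng <- range(raw)
  if (diff(rng) < 1e-12) {
    w <- rep(1, nrow(Z))
  } else {
    w <- bounds[1L] + (raw - rng[1L]) / diff(rng) * diff(bounds)
  }
  names(w) <- table$gene
  out <- list(
    weights = w,
    report = list(eigenvalue = ep$value, loadings = ep$vector,
                  raw_fused = raw, rescale_bounds = bounds)
  )
  class(out) <- "covariate_fusion"
  out
}

#' @export
print.covariate_fusion <- function(x, ...) {
  cat(sprintf("covariate_fusion: %d genes, lambda = %.4f, loadings = (%s)\n",
              length(x$weights), x$report$eigenvalue,
              paste(sprintf("%.3f", x$report$loadings), collapse = ", ")))
  invisible(x)
}

#' Align fused covariate weights to a mutation matrix's gene order
#'
#' Matches weights to matrix columns by gene label. Matrix genes missing
#' from the fusion receive the neutral weight 1 (with a warning); weights
#' for genes absent from the matrix are dropped.
#'
#' @param matrix A [mutation_matrix()].
#' @param fusion A `covariate_fusion` object, a named numeric vector of
#'   weights, or `NULL` for the neutral all-ones vector.
#' @return Numeric vector of length `ncol(matrix)` in matrix gene order.
#' @export
align_covariates <- function(matrix, fusion) {
  if (is.null(fusion)) return(rep(1, ncol(matrix)))
  w <- if (inherits(fusion, "covariate_fusion")) fusion$weights else fusion
  if (is.null(names(w))) {
    return(check_covariates(matrix, w))
  }
  idx <- match(colnames(matrix), names(w))
  out <- rep(1, ncol(matrix))
  hit <- !is.na(idx)
  out[hit] <- as.numeric(w[idx[hit]])
  if (any(!hit)) {
    warning(sprintf("%d matrix gene(s) missing from covariates; using neutral weight 1",
                    sum(!hit)), call. = FALSE)
  }
  out
}
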