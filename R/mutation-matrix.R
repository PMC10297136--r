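#' Construct a binary patient-by-gene mutation matrix
#'
#' The central data structure of the package: an m x n binary incidence
#' matrix with patients in rows and genes in columns. Entry \eqn{A_{ij} = 1}
#' means gene j carries a somatic mutation in patient i.
#'
#' @param entries Matrix (or object coercible to one) of 0/1 values,
#'   patients in rows, genes in columns.
#' @param patient_ids Character vector of m unique patient labels. Defaults
#'   to the rownames of `entries`, or `P001...` if absent.
#' @param gene_ids Character vector of n unique gene labels. Defaults to the
#'   colnames of `entries`, or `G001...` if absent.
#' @return An integer matrix of class `mutation_matrix` with dimnames set to
#'   the patient and gene labels.
#' @examples
#' A <- mutation_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
#' dim(A)
#' @export
mutation_matrix <- function(entries, patient_ids = NULL, gene_ids = NULL) {
  entries <- as.matrix(entries)
  if (nrow(entries) < 1L || ncol(entries) < 1L) {
    stop("mutation matrix must have at least one patient and one gene",
         call. = FALSE)
  }
  if (anyNA(entries) || !all(entries %in% c(0, 1))) {
    bad <- which(!(entries %in% c(0, 1)))[1L]
    stop(sprintf("mutation matrix entries must be 0 or 1 (offending entry at row %d, column %d)",
                 (bad - 1L) %% nrow(entries) + 1L, (bad - 1L) %/% nrow(entries) + 1L),
         call. = FALSE)
  }
  storage.mode(entries) <- "integer"
  if (is.null(patient_ids)) {
    patient_ids <- rownames(entries)
    if (is.null(patient_ids)) patient_ids <- default_labels("P", nrow(entries))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(entries)
    if (is.null(gene_ids)) gene_ids <- default_labels("G", ncol(entries))
  }
  patient_ids <- as.character(patient_ids)
  gene_ids <- as.character(gene_ids)
  if (length(patient_ids) != nrow(entries)) {
    stop("patient_ids length does not match number of rows", call. = FALSE)
  }
  if (length(gene_ids) != ncol(entries)) {
    stop("gene_ids length does not match number of columns", call. = FALSE)
  }
  if (anyDuplicated(patient_ids)) stop("duplicate patient_ids", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids", call. = FALSE)
  dimnames(entries) <- list(patient_ids, gene_ids)
  class(entries) <- c("mutation_matrix", class(entries))
  entries
}

default_labels <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(3L, nchar(as.character(n))), seq_len(n))
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d patients x %d genes, %d mutations (rate %.3f)\n",
              nrow(x), ncol(x), sum(x), mean(x)))
  invisible(x)
}

#' Test for the mutation_matrix class
#' @param x Object to test.
#' @return `TRUE` if `x` is a `mutation_matrix`.
#' @export
is_mutation_matrix <- function(x) inherits(x, "mutation_matrix")

#' @export
`[.mutation_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) class(out) <- c("mutation_matrix", class(out))
  out
}

## Resolve a gene-set argument (integer indices or character labels) against
## the matrix columns; returns sorted unique 1-based indices.
resolve_genes <- function(matrix, genes) {
  n <- ncol(matrix)
  if (is.character(genes)) {
    idx <- match(genes, colnames(matrix))
    if (anyNA(idx)) {
      stop(sprintf("unknown gene label(s): %s",
                   paste(genes[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
  } else {
    idx <- as.integer(genes)
    if (length(idx) && (anyNA(idx) || any(idx < 1L) || any(idx > n))) {
      bad <- idx[is.na(idx) | idx < 1L | idx > n][1L]
      stop(sprintf("gene index out of range [1, %d]: %s", n, bad), call. = FALSE)
    }
  }
  sort(unique(idx))
}

#' Patients covered by a gene set
#'
#' Returns \eqn{\Gamma(M)}, the set of patients with at least one mutation
#' among the genes in `genes`.
#'
#' @param matrix A [mutation_matrix()].
#' @param genes Gene set: integer column indices (1-based) or gene labels.
#' @return Sorted integer vector of patient row indices; empty for an empty
#'   gene selection.
#' @export
patient_support <- function(matrix, genes) {
  idx <- resolve_genes(matrix, genes)
  if (length(idx) == 0L) return(integer(0))
  as.integer(which(rowSums(matrix[, idx, drop = FALSE]) > 0))
}

#' Maximum weight submatrix score of a gene set
#'
#' The unweighted coverage/exclusivity balance
#' \deqn{W(M) = 2|\Gamma(M)| - \sum_{g \in M} |\Gamma(g)|,}
#' i.e. coverage minus the excess of co-occurring mutations. Equal to the
#' coverage count when the gene supports are pairwise disjoint.
#'
#' @inheritParams patient_support
#' @return A single number (can be negative for heavily overlapping sets).
#' @examples
#' A <- mutation_matrix(rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0)))
#' pathway_weight(A, 1:2)  # 2*3 - (2 + 2) = 2
#' @export
pathway_weight <- function(matrix, genes) {
  weighted_objective(matrix, genes, covariates = NULL)
}

#' Covariate-weighted maximum weight submatrix objective
#'
#' Generalizes [pathway_weight()] by weighting each gene's mutation-count
#' penalty with a positive per-gene fusion covariate \eqn{v_j}:
#' \deqn{W_v(M) = 2|\Gamma(M)| - \sum_{j \in M} v_j |\Gamma(j)|.}
#' Genes with high expected mutability (large \eqn{v_j}) pay a larger
#' exclusivity penalty, which discounts frequently mutated passengers.
#' With all \eqn{v_j = 1} this reduces to the unweighted score.
#'
#' @inheritParams patient_support
#' @param covariates Numeric vector of per-gene weights, one per matrix
#'   column (names ignored; alignment is positional), or `NULL` for the
#'   neutral all-ones weighting.
#' @return A single number.
#' @export
weighted_objective <- function(matrix, genes, covariates = NULL) {
  idx <- resolve_genes(matrix, genes)
  v <- check_covariates(matrix, covariates)
  if (length(idx) == 0L) return(0)
  sub <- matrix[, idx, drop = FALSE]
  covered <- sum(rowSums(sub) > 0)
  2 * covered - sum(v[idx] * colSums(sub))
}

check_covariates <- function(matrix, covariates) {
  if (is.null(covariates)) return(rep(1, ncol(matrix)))
  v <- as.numeric(covariates)
  if (length(v) != ncol(matrix)) {
    stop(sprintf("covariate vector has length %d but matrix has %d genes",
                 length(v), ncol(matrix)), call. = FALSE)
  }
  if (anyNA(v) || any(!is.finite(v))) {
    stop("covariates must be finite", call. = FALSE)
  }
  v
}

#' Fraction of patients covered by a gene set
#'
#' \eqn{|\Gamma(M)| / m}: the proportion of patients carrying at least one
#' mutation in the set.
#'
#' @inheritParams patient_support
#' @return A fraction in \[0, 1\].
#' @export
coverage_fraction <- function(matrix, genes) {
  length(patient_support(matrix, genes)) / nrow(matrix)
}

#' Mutual exclusivity degree of a gene set
#'
#' The proportion of patients with *exactly one* mutated gene in the set.
#' By default the denominator is all m patients, so the value never exceeds
#' [coverage_fraction()]; with `covered_only = TRUE` it is the covered
#' patients only.
#'
#' @inheritParams patient_support
#' @param covered_only Logical; restrict the denominator to covered patients.
#' @return A fraction in \[0, 1\].
#' @export
mutex_degree <- function(matrix, genes, covered_only = FALSE) {
  idx <- resolve_genes(matrix, genes)
  if (length(idx) == 0L) return(0)
  counts <- rowSums(matrix[, idx, drop = FALSE])
  exclusive <- sum(counts == 1)
  denom <- if (covered_only) sum(counts > 0) else nrow(matrix)
  if (denom == 0L) return(0)
  exclusive / denom
}

#' Fraction of an identified gene set found in a reference driver list
#'
#' Measures how many of the k identified genes appear in a user-supplied
#' reference list of known cancer genes (for example, members of
#' cancer-related KEGG pathways).
#'
#' @param genes Character vector of identified gene labels, or integer
#'   indices if `matrix` is supplied.
#' @param reference Non-empty character vector of reference gene labels.
#' @param matrix Optional [mutation_matrix()] used to translate integer
#'   indices to labels.
#' @param fold_case Logical; match case-insensitively (uppercase folding).
#' @return \eqn{|M \cap R| / k}, a fraction in \[0, 1\].
#' @export
accuracy_vs_reference <- function(genes, reference, matrix = NULL,
                                  fold_case = FALSE) {
  if (length(reference) == 0L) {
    stop("reference gene list must be non-empty", call. = FALSE)
  }
  if (!is.character(genes)) {
    if (is.null(matrix)) {
      stop("integer gene indices require `matrix` to resolve labels",
           call. = FALSE)
    }
    genes <- colnames(matrix)[resolve_genes(matrix, genes)]
  }
  reference <- as.character(reference)
  if (fold_case) {
    genes <- toupper(genes)
    reference <- toupper(reference)
  }
  sum(genes %in% reference) / length(genes)
}

#' Bundle an identified pathway with its evaluation metrics
#'
#' Internal constructor used by the optimizer and the permutation test; the
#' weight, coverage, and exclusivity fields are always recomputed from the
#' matrix so they cannot drift from the gene set.
#'
#' @param matrix A [mutation_matrix()].
#' @param genes Gene indices of the identified set.
#' @param covariates Per-gene weight vector or `NULL`.
#' @param seed RNG seed used to produce the result (for the record).
#' @param p_value Permutation p-value, or `NA` before testing.
#' @return An object of class `pathway_result`: a list with elements
#'   `genes` (sorted indices), `gene_ids` (labels), `k`, `weight`,
#'   `coverage`, `mutex_degree`, `p_value`, `seed`.
#' @export
pathway_result <- function(matrix, genes, covariates = NULL, seed = NA_integer_,
                           p_value = NA_real_) {
  idx <- resolve_genes(matrix, genes)
  out <- list(
    genes = idx,
    gene_ids = colnames(matrix)[idx],
    k = length(idx),
    weight = weighted_objective(matrix, idx, covariates),
    coverage = coverage_fraction(matrix, idx),
    mutex_degree = mutex_degree(matrix, idx),
    p_value = p_value,
    seed = seed
  )
  class(out) <- "pathway_result"
  out
}

#' @export
print.pathway_result <- function(x, ...) {
  cat(sprintf("pathway_result (k = %d): %s\n", x$k,
              paste(x$gene_ids, collapse = " ")))
  cat(sprintf("  weight %.3f | coverage %.3f | mutex %.3f | p %s\n",
              x$weight, x$coverage, x$mutex_degree,
              if (is.na(x$p_value)) "(untested)" else format(x$p_value)))
  invisible(x)
}

#' @export
as.data.frame.pathway_result <- function(x, ...) {
  data.frame(
    k = x$k,
    genes = paste(x$gene_ids, collapse = ","),
    weight = x$weight,
    coverage = x$coverage,
    mutex_degree = x$mutex_degree,
    p_value = x$p_value,
    seed = x$seed,
    stringsAsFactors = FALSE
  )
}
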