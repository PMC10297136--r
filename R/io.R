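#' Read a binary mutation matrix from TSV
#'
#' Two on-disk layouts are supported. `dense`: a tab-separated table whose
#' header row holds gene labels (first cell names the patient column), one
#' row per patient, entries 0/1; comment lines starting with `#` (such as
#' the `#orientation=patients_x_genes` marker written by
#' [write_mutation_matrix()]) are ignored. `sparse`: two tab-separated
#' columns `patient_label<TAB>gene_label`, one mutated pair per line
#' (optional `patient	gene` header); duplicate pairs collapse to a
#' single 1, since the matrix is binary by definition. `auto` picks sparse
#' for two-column files, dense otherwise.
#'
#' @param path Path to the file.
#' @param format `"auto"`, `"dense"`, or `"sparse"`.
#' @return A [mutation_matrix()].
#' @export
read_mutation_matrix <- function(path, format = c("auto", "dense", "sparse")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop(sprintf("%s: no data lines", path), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (all(lengths(fields) == 2L)) "sparse" else "dense"
  }
  if (format == "sparse") {
    if (any(lengths(fields) != 2L)) {
      bad <- lineno[which(lengths(fields) != 2L)[1L]]
      stop(sprintf("%s: line %d does not have two tab-separated columns",
                   path, bad), call. = FALSE)
    }
    pairs <- do.call(rbind, fields)
    if (identical(tolower(pairs[1L, ]), c("patient", "gene"))) {
      pairs <- pairs[-1L, , drop = FALSE]
    }
    if (nrow(pairs) == 0L) stop(sprintf("%s: no mutation records", path),
                                call. = FALSE)
    patients <- unique(pairs[, 1L])
    genes <- unique(pairs[, 2L])
    E <- matrix(0L, length(patients), length(genes),
                dimnames = list(patients, genes))
    E[cbind(match(pairs[, 1L], patients), match(pairs[, 2L], genes))] <- 1L
    return(mutation_matrix(E, patients, genes))
  }
  header <- fields[[1L]]
  genes <- header[-1L]
  if (length(genes) == 0L) {
    stop(sprintf("%s: header row has no gene columns", path), call. = FALSE)
  }
  body <- fields[-1L]
  if (length(body) == 0L) stop(sprintf("%s: no patient rows", path), call. = FALSE)
  ragged <- which(lengths(body) != length(header))
  if (length(ragged)) {
    stop(sprintf("%s: line %d has %d fields, expected %d", path,
                 lineno[ragged[1L] + 1L], lengths(body)[ragged[1L]],
                 length(header)), call. = FALSE)
  }
  tab <- do.call(rbind, body)
  patients <- tab[, 1L]
  vals <- suppressWarnings(as.numeric(tab[, -1L, drop = FALSE]))
  entries <- matrix(vals, nrow = length(body))
  bad <- which(is.na(entries) | !(entries %in% c(0, 1)))
  if (length(bad)) {
    r <- (bad[1L] - 1L) %% nrow(entries) + 1L
    stop(sprintf("%s: non-binary entry '%s' at line %d (patient %s)", path,
                 tab[r, (bad[1L] - 1L) %/% nrow(entries) + 2L],
                 lineno[r + 1L], patients[r]), call. = FALSE)
  }
  mutation_matrix(entries, patients, genes)
}

#' Write a mutation matrix as TSV
#'
#' The dense layout leads with a `#orientation=patients_x_genes` comment
#' line so the row/column convention is explicit in the file; the sparse
#' layout writes a `patient	gene` header followed by one mutated pair
#' per line. Both round-trip through [read_mutation_matrix()].
#'
#' @param matrix A [mutation_matrix()].
#' @param path Output path.
#' @param format `"dense"` or `"sparse"`.
#' @return `path`, invisibly.
#' @export
write_mutation_matrix <- function(matrix, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  stopifnot(is_mutation_matrix(matrix))
  if (format == "dense") {
    header <- paste(c("patient", colnames(matrix)), collapse = "\t")
    rows <- vapply(seq_len(nrow(matrix)), function(i) {
      paste(c(rownames(matrix)[i], matrix[i, ]), collapse = "\t")
    }, character(1))
    writeLines(c("#orientation=patients_x_genes", header, rows), path)
  } else {
    hits <- which(unclass(matrix) == 1L, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    writeLines(c("patient\tgene",
                 paste(rownames(matrix)[hits[, 1L]],
                       colnames(matrix)[hits[, 2L]], sep = "\t")), path)
  }
  invisible(path)
}

#' Read a per-gene covariate table from TSV
#'
#' Expects a header with columns `gene`, `expression`, `replication_time`,
#' `chromosome_status` (any order; extra columns ignored).
#'
#' @param path Path to the TSV file.
#' @return A [covariate_table()].
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  need <- c("gene", "expression", "replication_time", "chromosome_status")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (nm in need[-1L]) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v)) {
      stop(sprintf("%s: non-numeric value in column '%s' (row %d)", path, nm,
                   which(is.na(v))[1L]), call. = FALSE)
    }
    df[[nm]] <- v
  }
  covariate_table(df$gene, df$expression, df$replication_time,
                  df$chromosome_status)
}

#' Write a covariate table as TSV
#' @param table A [covariate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(table, path) {
  stopifnot(inherits(table, "covariate_table"))
  utils::write.table(as.data.frame(unclass(table)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference gene list (one symbol per line)
#' @param path Path to the file; blank lines and `#` comments are skipped.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0L) stop(sprintf("%s: empty gene list", path), call. = FALSE)
  lines
}

result_record <- function(r) {
  rec <- list(k = r$k, genes = as.list(r$gene_ids),
              gene_indices = as.list(r$genes),
              weight = r$weight, coverage = r$coverage,
              mutex_degree = r$mutex_degree,
              p_value = if (is.na(r$p_value)) NULL else r$p_value,
              seed = if (is.na(r$seed)) NULL else r$seed)
  Filter(Negate(is.null), rec)
}

#' Serialize pathway results to TSV or JSON
#'
#' Writes one record per identified pathway (k, gene labels, weight,
#' coverage, mutual exclusivity degree, p-value, seed). The JSON format
#' round-trips losslessly through [read_results()].
#'
#' @param results A [pathway_result()], a list of them, or a
#'   `pathway_scan`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "pathway_scan")) results <- results$results
  if (inherits(results, "pathway_result")) results <- list(results)
  if (length(results) == 0L) stop("no results to write", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "pathway_result")))
  if (format == "tsv") {
    df <- do.call(rbind, lapply(results, as.data.frame))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(lapply(results, result_record), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read pathway results back from a JSON file written by [write_results()]
#' @param path Path to the JSON file.
#' @return A list of [pathway_result()]-shaped lists.
#' @export
read_results <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    out <- list(genes = as.integer(unlist(r$gene_indices)),
                gene_ids = as.character(unlist(r$genes)),
                k = as.integer(r$k),
                weight = as.numeric(r$weight),
                coverage = as.numeric(r$coverage),
                mutex_degree = as.numeric(r$mutex_degree),
                p_value = if (is.null(r$p_value)) NA_real_ else as.numeric(r$p_value),
                seed = if (is.null(r$seed)) NA_integer_ else as.integer(r$seed))
    class(out) <- "pathway_result"
    out
  })
}
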