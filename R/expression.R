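#' Genes x samples expression matrix
#'
#' A thin container over a numeric matrix with unique gene and sample
#' identifiers and an explicit `kind`: `"counts"` for RNA-seq-like
#' nonnegative integers, `"continuous"` for log-scale or microarray-like
#' intensities.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids unique identifiers; default to dimnames.
#' @param kind `"counts"` or `"continuous"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              kind = c("counts", "continuous")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("dimensions inconsistent with identifiers")
  if (kind == "counts") {
    if (any(values < 0) || any(values != round(values)))
      stop("counts must be nonnegative integers")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids), kind = kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d genes x %d samples\n", x$kind,
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Read / write a TSV expression matrix
#'
#' Layout: first column `gene_id`, remaining columns one per sample.
#'
#' @param path TSV file.
#' @param kind passed to [expression_matrix()].
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(path, kind = c("counts", "continuous")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "gene_id")
    stop("first column must be 'gene_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  expression_matrix(m, kind = kind)
}

#' @rdname read_expression_tsv
#' @param expr an `expression_matrix` to write.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = expr$gene_ids, expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log counts-per-million transformation
#'
#' Normalizes each sample by its library size to counts per million and
#' applies log2 with a pseudocount:
#' `log2((x + prior_count) / (lib + 2 * prior_count) * 1e6)`.
#' The doubled pseudocount in the denominator keeps the transform consistent
#' when a gene carries the entire library.
#'
#' @param counts an `expression_matrix` of kind `"counts"`.
#' @param prior_count pseudocount added to each count.
#' @return An `expression_matrix` of kind `"continuous"`, same shape.
#' @export
log_cpm <- function(counts, prior_count = 0.5) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$kind != "counts") stop("log_cpm expects a counts matrix")
  lib <- colSums(counts$values)
  if (any(lib == 0)) {
    stop("sample(s) with zero total count: ",
         paste(counts$sample_ids[lib == 0], collapse = ", "))
  }
  v <- log2(sweep(counts$values + prior_count, 2L, lib + 2 * prior_count,
                  "/") * 1e6)
  expression_matrix(v, counts$gene_ids, counts$sample_ids,
                    kind = "continuous")
}
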