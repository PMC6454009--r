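#' Read a gene-by-sample RPKM expression table
#'
#' Expects a TSV with a header row of sample ids and gene ids in the first
#' column.  Entries must be non-negative; gene ids must be unique.
#'
#' @param path TSV file.
#' @return An object of class `expression_table`: list with `genes`,
#'   `samples` and the numeric `values` matrix (genes x samples).
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  genes <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  expression_table(genes, colnames(vals), vals)
}

#' Construct an expression table in memory
#' @param genes Gene ids (unique).
#' @param samples Sample ids.
#' @param values Numeric genes x samples matrix of RPKM (non-negative).
#' @export
expression_table <- function(genes, samples, values) {
  values <- as.matrix(values)
  if (anyDuplicated(genes)) stop("gene ids must be unique")
  if (nrow(values) != length(genes) || ncol(values) != length(samples))
    stop("values matrix must be genes x samples")
  if (any(values < 0, na.rm = TRUE)) stop("RPKM values must be non-negative")
  dimnames(values) <- list(genes, samples)
  structure(list(genes = genes, samples = samples, values = values),
            class = "expression_table")
}

#' Write an expression table to TSV
#' @param x An `expression_table`.
#' @param path Output file.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = x$genes, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Differentially expressed genes by two-sample Kolmogorov-Smirnov test
#'
#' Compares each gene's patient RPKM values against the normal-sample
#' values with a two-sided two-sample KS test.  RPKM-level tests are rank
#' based, so no transformation or pseudo-count is applied.  Multiple
#' testing correction defaults to none (RPKM comparisons are a screening
#' step, not an inference); Bonferroni over the number of genes tested is
#' available as an option.
#'
#' @param patients,normals `expression_table`s sharing gene ids.  Genes
#'   absent from one table, or with fewer than 2 finite values on a side,
#'   are skipped with a warning.
#' @param alpha Selection threshold on the (corrected) p-value.
#' @param correction `"none"` or `"bonferroni"`.
#' @param keep_all Return all tested genes instead of only the selected.
#' @return A `data.frame` with columns `gene`, `ks_statistic`, `p_value`,
#'   `direction` (`"up"`/`"down"`, sign of median patient minus median
#'   normal), `selected`; selected genes sorted by p-value first.
#' @export
ks_differential_genes <- function(patients, normals, alpha = 0.05,
                                  correction = c("none", "bonferroni"),
                                  keep_all = FALSE) {
  correction <- match.arg(correction)
  shared <- intersect(patients$genes, normals$genes)
  missing <- setdiff(union(patients$genes, normals$genes), shared)
  if (length(missing) > 0L)
    warning("skipping ", length(missing), " gene(s) absent from one table")
  res <- lapply(shared, function(g) {
    x <- patients$values[g, ]
    y <- normals$values[g, ]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    kt <- suppressWarnings(stats::ks.test(x, y))
    data.frame(gene = g, ks_statistic = unname(kt$statistic),
               p_value = kt$p.value,
               direction = if (median(x) >= median(y)) "up" else "down",
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1L)))
  if (dropped > 0L)
    warning("skipping ", dropped, " gene(s) with fewer than 2 finite values on a side")
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(gene = character(), ks_statistic = numeric(),
                      p_value = numeric(), direction = character(),
                      selected = logical(), stringsAsFactors = FALSE))
  n_tested <- nrow(res)
  eff_alpha <- if (correction == "bonferroni") alpha / n_tested else alpha
  res$selected <- res$p_value < eff_alpha
  res <- res[order(!res$selected, res$p_value, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  if (keep_all) res else res[res$selected, , drop = FALSE]
}

#' Read or write a differential-expression gene list
#'
#' The pipeline accepts either internally computed DE genes or an external
#' one-gene-per-line list, mutually exclusively.
#'
#' @param path One gene id per line.  Duplicates are removed with a
#'   warning; an empty list aborts.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  g <- trimws(readLines(path))
  g <- g[nzchar(g)]
  if (length(g) == 0L) stop("gene list ", path, " is empty")
  if (anyDuplicated(g)) {
    warning("removed ", sum(duplicated(g)), " duplicate gene id(s)")
    g <- unique(g)
  }
  g
}

#' @rdname read_gene_list
#' @param genes Gene ids to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
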