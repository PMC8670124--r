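# Core domain objects: count matrices, design matrices, analysis
# configuration, DE result tables, and their TSV readers/writers.
# All files are tab-separated UTF-8 with '.' decimal separator.

#' Validate a gene x sample count matrix
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids); entries must be
#'   finite non-negative integers.
#' @return the validated matrix (invisibly the same object).
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene id: ", rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample id: ", colnames(counts)[duplicated(colnames(counts))][1])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stop(sprintf("invalid count for gene '%s', sample '%s': must be a non-negative integer",
                 rownames(counts)[i[1]], colnames(counts)[i[2]]))
  }
  counts
}

#' Validate a sample x covariate design matrix
#'
#' The intercept column must be supplied explicitly; it is never auto-added,
#' so the pooled model is unambiguous across clients. Group (target-class)
#' indicator columns must be 0/1.
#'
#' @param design numeric matrix, samples in rows (rownames = sample ids),
#'   covariates in columns.
#' @param group_columns character vector of column names marking target-class
#'   indicator columns.
#' @return the design matrix with attribute `group_columns`.
#' @export
validate_design <- function(design, group_columns = attr(design, "group_columns")) {
  if (!is.matrix(design) || !is.numeric(design)) stop("design must be a numeric matrix")
  if (is.null(rownames(design)) || is.null(colnames(design)))
    stop("design must carry sample ids as rownames and covariate names as colnames")
  if (anyDuplicated(rownames(design))) stop("duplicated sample id in design")
  if (ncol(design) < 1L) stop("design needs at least one column")
  if (any(!is.finite(design))) stop("non-finite value in design matrix")
  if (is.null(group_columns) || length(group_columns) == 0L)
    stop("at least one group column must be named")
  missing_gc <- setdiff(group_columns, colnames(design))
  if (length(missing_gc))
    stop("group column(s) not present in design: ", paste(missing_gc, collapse = ", "))
  for (gc in group_columns) {
    if (!all(design[, gc] %in% c(0, 1)))
      stop("group column '", gc, "' must contain only 0/1 values")
  }
  attr(design, "group_columns") <- group_columns
  design
}

#' One client of the federated study
#'
#' Pairs a private count matrix with its design matrix and checks that sample
#' ids match in content and order.
#'
#' @param counts validated count matrix (see [validate_counts()]).
#' @param design validated design matrix (see [validate_design()]).
#' @param group_columns group indicator column names (defaults to the
#'   attribute already on `design`).
#' @return object of class `fv_client`.
#' @export
fv_client <- function(counts, design, group_columns = attr(design, "group_columns")) {
  counts <- validate_counts(counts)
  design <- validate_design(design, group_columns)
  if (!identical(colnames(counts), rownames(design)))
    stop("sample ids of counts and design differ in content or order")
  structure(list(counts = counts, design = design), class = "fv_client")
}

#' Analysis configuration
#'
#' @param coefficient name of the tested design column (its estimate is the
#'   reported log2 fold change).
#' @param min_count minimum count used for the CPM cutoff of the expression
#'   filter (default 10).
#' @param min_total_count genes whose pooled total count does not exceed this
#'   are removed (strict `>` to keep; default 15).
#' @param alpha BH-adjusted significance level for DE calls (default 0.05).
#' @param lfc_threshold absolute log2-fold-change threshold for DE calls
#'   (default 1).
#' @param modulus prime modulus of the integer masking scheme
#'   ([fv_modulus()]; default 2^54 - 33).
#' @param gauss_var variance of the Gaussian masking noise (default 1e12).
#' @param masking logical; FALSE runs the identical protocol with zero noise
#'   (for the masked-vs-unmasked comparison).
#' @param seed integer seed from which all per-client, per-round noise
#'   streams are derived.
#' @return object of class `fv_config`.
#' @export
fv_config <- function(coefficient,
                      min_count = 10, min_total_count = 15,
                      alpha = 0.05, lfc_threshold = 1,
                      modulus = fv_modulus(), gauss_var = 1e12,
                      masking = TRUE, seed = 1L) {
  stopifnot(is.character(coefficient), length(coefficient) == 1L)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (gauss_var <= 0) stop("gauss_var must be positive")
  if (!inherits(modulus, "fv_modulus")) modulus <- fv_modulus(modulus)
  structure(list(coefficient = coefficient,
                 min_count = min_count, min_total_count = min_total_count,
                 alpha = alpha, lfc_threshold = lfc_threshold,
                 modulus = modulus, gauss_var = gauss_var,
                 masking = isTRUE(masking), seed = as.integer(seed)),
            class = "fv_config")
}

## ---- TSV readers/writers -------------------------------------------------

#' Read a count matrix from TSV
#'
#' Expected layout: header row of sample ids, first column gene ids, integer
#' body. Row and column order of the file are preserved.
#'
#' @param path file path.
#' @return validated count matrix.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("counts file needs a gene-id column plus at least one sample")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entry in counts body of ", path)
  storage.mode(m) <- "double"
  rownames(m) <- genes
  validate_counts(m)
}

#' Write a count matrix to TSV
#' @param counts validated count matrix.
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a design matrix from TSV
#'
#' First column sample ids, remaining columns numeric covariates.
#'
#' @param path file path.
#' @param group_columns names of the target-class indicator columns; must be
#'   among the file's headers.
#' @return validated design matrix with `group_columns` attribute.
#' @export
read_design <- function(path, group_columns) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("design file needs a sample-id column plus at least one covariate")
  samples <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric covariate cell in ", path)
  rownames(m) <- samples
  validate_design(m, group_columns)
}

#' Write a design matrix to TSV
#' @param design validated design matrix.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  df <- data.frame(sample = rownames(design), design, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Assemble and order a DE result table
#'
#' Rows are sorted by raw p-value ascending with ties broken by gene id, the
#' same presentation as limma's topTable.
#'
#' @param gene,logFC,AveExpr,t,P.Value,adj.P.Val per-gene columns.
#' @return `data.frame` of class `fv_results`.
#' @keywords internal
new_results_table <- function(gene, logFC, AveExpr, t, P.Value, adj.P.Val) {
  stopifnot(all(P.Value >= 0 & P.Value <= 1), all(adj.P.Val >= 0 & adj.P.Val <= 1))
  ord <- order(P.Value, gene)
  out <- data.frame(gene = gene, logFC = logFC, AveExpr = AveExpr, t = t,
                    P.Value = P.Value, adj.P.Val = adj.P.Val,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fv_results", "data.frame")
  out
}

#' Write a DE result table to TSV
#'
#' Columns `gene, logFC, AveExpr, t, P.Value, adj.P.Val` in that order, full
#' double precision (17 significant digits), rows sorted by p-value.
#'
#' @param table result table as returned by [run_fedvoom()].
#' @param path file path.
#' @export
write_results <- function(table, path) {
  cols <- c("gene", "logFC", "AveExpr", "t", "P.Value", "adj.P.Val")
  stopifnot(all(cols %in% names(table)))
  df <- table[, cols, drop = FALSE]
  for (j in 2:6) df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a DE result table written by [write_results()]
#' @param path file path.
#' @return `fv_results` data frame.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "gene"
  new_results_table(df$gene, df$logFC, df$AveExpr, df$t, df$P.Value, df$adj.P.Val)
}
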