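#' Construct an expression matrix
#'
#' A thin container around a numeric genes-by-samples matrix carrying a
#' scale flag (`"counts"` for non-negative count data, `"log2"` for
#' log-scale values) and optional per-sample metadata (a condition label and
#' numeric covariates). Row and column names must be unique and no value may
#' be missing.
#'
#' @param values Numeric matrix with gene row names and sample column names.
#' @param scale `"counts"` or `"log2"`.
#' @param sample_meta Optional data.frame; either row names or a
#'   `sample_id` column must match the matrix columns. A `condition` column,
#'   if present, labels experimental arms.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale = c("counts", "log2"), sample_meta = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) pls_error("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    pls_error("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values))) pls_error("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) pls_error("duplicate sample identifiers")
  if (anyNA(values) || any(!is.finite(values)))
    pls_error("expression matrix contains missing or non-finite values")
  if (scale == "counts" && any(values < 0))
    pls_error("scale 'counts' declared but negative values present")
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if ("sample_id" %in% names(sample_meta)) rownames(sample_meta) <- sample_meta$sample_id
    missing <- setdiff(colnames(values), rownames(sample_meta))
    if (length(missing))
      pls_error(sprintf("sample metadata missing for: %s", paste(missing, collapse = ", ")))
    sample_meta <- sample_meta[colnames(values), , drop = FALSE]
  }
  structure(list(values = values, scale = scale, sample_meta = sample_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$sample_meta) && "condition" %in% names(x$sample_meta)) {
    tab <- table(x$sample_meta$condition)
    cat("  conditions:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Subset an expression matrix
#'
#' @param x An `expr_matrix`.
#' @param i,j Gene and sample indices (names, logicals or integers).
#' @param ... Ignored.
#' @return An `expr_matrix` with sample metadata subset accordingly.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  meta <- if (!is.null(x$sample_meta)) x$sample_meta[colnames(v), , drop = FALSE]
  expr_matrix(v, scale = x$scale, sample_meta = meta)
}

# merge two arms on their shared gene space; sample ids prefixed on clash
merge_arms <- function(case, ref, case_prefix = "case.", ref_prefix = "ref.") {
  shared <- intersect(gene_ids(case), gene_ids(ref))
  if (length(shared) < 2L)
    pls_error("case and reference matrices share fewer than 2 genes",
              "plsassay_input_error")
  if (case$scale != ref$scale)
    pls_error("case and reference matrices are on different scales")
  cv <- case$values[shared, , drop = FALSE]
  rv <- ref$values[shared, , drop = FALSE]
  if (length(intersect(colnames(cv), colnames(rv)))) {
    colnames(cv) <- paste0(case_prefix, colnames(cv))
    colnames(rv) <- paste0(ref_prefix, colnames(rv))
  }
  meta <- data.frame(sample_id = c(colnames(cv), colnames(rv)),
                     condition = rep(c("case", "reference"),
                                     c(ncol(cv), ncol(rv))),
                     stringsAsFactors = FALSE)
  list(matrix = expr_matrix(cbind(cv, rv), scale = case$scale, sample_meta = meta),
       case_ids = colnames(cv), ref_ids = colnames(rv))
}

#' Read / write expression matrices as TSV or CSV
#'
#' The first column holds gene identifiers; the header row holds sample
#' identifiers. An optional sidecar metadata TSV has columns
#' `sample_id`, `condition`, and further covariates.
#'
#' @param path Matrix file (`.tsv`/`.txt` tab-separated, `.csv` comma).
#' @param scale Scale flag to attach (`"counts"` or `"log2"`).
#' @param meta_path Optional sidecar metadata TSV.
#' @return An [expr_matrix].
#' @export
read_expression <- function(path, scale = c("counts", "log2"), meta_path = NULL) {
  scale <- match.arg(scale)
  if (!file.exists(path))
    pls_error(sprintf("expression file not found: %s", path), "plsassay_input_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  genes <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- genes
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(meta))
      pls_error("sample metadata must have a 'sample_id' column", "plsassay_parse_error")
  }
  expr_matrix(vals, scale = scale, sample_meta = meta)
}

#' @rdname read_expression
#' @param m An `expr_matrix` to write.
#' @param gene_col Name of the gene identifier column in the output.
#' @export
write_expression <- function(m, path, gene_col = "gene") {
  df <- data.frame(rownames(m$values), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
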