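#' Housekeeping-gene normalization of a count matrix
#'
#' Computes one positive scale factor per sample as the geometric mean of
#' its housekeeping-gene counts (plus a pseudocount guarding zeros), then
#' rescales every sample by `reference / factor`, where the reference is the
#' geometric mean of all factors. The grand scale of the matrix is thereby
#' preserved, and multiplying any single sample's counts by a constant is
#' exactly undone.
#'
#' @param m An [expr_matrix] with `scale = "counts"`.
#' @param hk Housekeeping [gene_set] (or character vector); at least one
#'   gene must be present in the matrix.
#' @param pseudocount Non-negative value added to housekeeping counts before
#'   the geometric mean (default 0.5, so zero counts cannot produce a zero
#'   factor).
#' @return A list of class `normalization_result` with `matrix` (normalized
#'   `expr_matrix`, still on the counts scale), `factors` (named per-sample
#'   factors), `reference`, and `method`.
#' @export
housekeeping_normalize <- function(m, hk, pseudocount = 0.5) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "counts")
    pls_error("housekeeping normalization expects a counts-scale matrix")
  if (pseudocount < 0) pls_error("pseudocount must be non-negative")
  hk_genes <- as_gene_vector(hk)
  present <- intersect(hk_genes, gene_ids(m))
  if (length(present) == 0L)
    pls_error("no housekeeping gene found in the matrix", "plsassay_coverage_error")
  hk_counts <- m$values[present, , drop = FALSE] + pseudocount
  factors <- apply(hk_counts, 2, geo_mean)
  if (any(factors <= 0))
    pls_error("non-positive housekeeping factor; increase the pseudocount")
  reference <- geo_mean(factors)
  scaled <- sweep(m$values, 2, reference / factors, `*`)
  structure(list(matrix = expr_matrix(scaled, scale = "counts",
                                      sample_meta = m$sample_meta),
                 factors = factors, reference = reference,
                 hk_used = present, method = "housekeeping_geometric_mean"),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("<normalization_result> %s over %d housekeeping genes\n",
              x$method, length(x$hk_used)))
  cat(sprintf("  reference %.4g; factor range [%.4g, %.4g]\n",
              x$reference, min(x$factors), max(x$factors)))
  invisible(x)
}

#' Write per-sample normalization factors as a two-column TSV
#' @param x A `normalization_result`.
#' @param path Output path.
#' @export
write_factors <- function(x, path) {
  utils::write.table(data.frame(sample_id = names(x$factors), factor = x$factors),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform a count matrix with a pseudocount
#'
#' @param m A counts-scale [expr_matrix].
#' @param c Positive pseudocount (default 1); `log2(value + c)`.
#' @return An `expr_matrix` with `scale = "log2"`.
#' @export
log2_with_pseudocount <- function(m, c = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "counts") pls_error("log2 transform expects a counts-scale matrix")
  if (!is.numeric(c) || length(c) != 1L || c <= 0)
    pls_error("pseudocount must be a single positive number")
  expr_matrix(log2(m$values + c), scale = "log2", sample_meta = m$sample_meta)
}

#' Row-wise z-scores of a log-scale matrix
#'
#' Each gene is centred to mean 0 and scaled to sample standard deviation 1
#' (n-1 denominator). Constant rows map to all-zero rows rather than NaN.
#' This is the display transform behind signature heatmaps (z-scores of
#' log2-normalized data).
#'
#' @param m An [expr_matrix] with at least 2 samples.
#' @return An `expr_matrix` on the same scale flag.
#' @export
row_zscore <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 2L)
    pls_error("row z-scores need at least 2 samples")
  mu <- rowMeans(m$values)
  sd <- row_sds(m$values)
  z <- (m$values - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  # z-scores are real-valued, so the flag is "log2" (the real-scale flag)
  expr_matrix(z, scale = "log2", sample_meta = m$sample_meta)
}
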