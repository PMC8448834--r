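#' Construct a ranked gene list
#'
#' Genes are ordered by metric descending with ties broken by gene
#' identifier ascending, a deterministic order required for reproducible
#' enrichment scores.
#'
#' @param gene_ids Character vector of unique gene identifiers.
#' @param metric Numeric ranking metric, one value per gene.
#' @param metric_name Label for the metric.
#' @return An object of class `ranked_list` with `genes` (ordered), `metric`
#'   (named, in the same order), and `metric_name`.
#' @export
ranked_list <- function(gene_ids, metric, metric_name = "metric") {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != length(metric))
    pls_error("gene_ids and metric lengths differ")
  if (anyDuplicated(gene_ids)) pls_error("duplicate genes in ranked list")
  if (length(gene_ids) < 2L) pls_error("ranked list needs at least 2 genes")
  if (anyNA(metric) || any(!is.finite(metric)))
    pls_error("ranking metric contains missing or non-finite values")
  ord <- order(-metric, gene_ids, method = "radix")
  metric <- metric[ord]
  names(metric) <- gene_ids[ord]
  structure(list(genes = gene_ids[ord], metric = metric,
                 metric_name = metric_name),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> %d genes ranked by %s\n", length(x$genes), x$metric_name))
  cat(sprintf("  top: %s (%.3g) ... bottom: %s (%.3g)\n",
              x$genes[1], x$metric[1],
              x$genes[length(x$genes)], x$metric[length(x$metric)]))
  invisible(x)
}

#' @export
length.ranked_list <- function(x) length(x$genes)

#' Rank genes by a two-group phenotype contrast
#'
#' Computes a per-gene case-versus-reference metric and returns the ranked
#' list. `signal2noise` is \eqn{(\mu_1-\mu_0)/(\sigma_1+\sigma_0)} with each
#' group standard deviation floored at \eqn{\max(0.2|\mu|, 0.2)} (so small
#' replicate groups cannot produce explosive scores); `log2fc` is the
#' difference of group means on a log2-scale matrix.
#'
#' @param m An [expr_matrix] (log2 scale recommended).
#' @param case,ref Sample identifiers (columns of `m`) or condition labels
#'   looked up in the sample metadata; the groups must be disjoint.
#' @param metric `"log2fc"` (needs >= 1 replicate per group, the default)
#'   or `"signal2noise"` (>= 2).
#' @return A [ranked_list].
#' @export
rank_by_phenotype <- function(m, case, ref, metric = c("log2fc", "signal2noise")) {
  stopifnot(inherits(m, "expr_matrix"))
  metric <- match.arg(metric)
  case_ids <- resolve_samples(m, case)
  ref_ids <- resolve_samples(m, ref)
  if (length(intersect(case_ids, ref_ids)))
    pls_error("case and reference groups overlap")
  need <- if (metric == "signal2noise") 2L else 1L
  if (length(case_ids) < need || length(ref_ids) < need)
    pls_error(sprintf("metric '%s' needs at least %d samples per group", metric, need))
  vals <- ranking_metric(m$values, match(case_ids, sample_ids(m)),
                         match(ref_ids, sample_ids(m)), metric)
  ranked_list(gene_ids(m), vals, metric_name = metric)
}

# map sample ids or condition labels to column ids
resolve_samples <- function(m, x) {
  x <- as.character(x)
  ids <- sample_ids(m)
  if (all(x %in% ids)) return(x)
  if (!is.null(m$sample_meta) && "condition" %in% names(m$sample_meta)) {
    hit <- ids[m$sample_meta$condition %in% x]
    if (length(hit)) return(hit)
  }
  pls_error(sprintf("unknown sample id(s) or condition label(s): %s",
                    paste(setdiff(x, ids), collapse = ", ")),
            "plsassay_input_error")
}

# vectorized two-group metric on a plain matrix; i1/i0 are column indices
ranking_metric <- function(v, i1, i0, metric) {
  m1 <- rowMeans(v[, i1, drop = FALSE])
  m0 <- rowMeans(v[, i0, drop = FALSE])
  if (metric == "log2fc") return(m1 - m0)
  s1 <- row_sds(v[, i1, drop = FALSE])
  s0 <- row_sds(v[, i0, drop = FALSE])
  s1 <- pmax(s1, 0.2 * abs(m1), 0.2)
  s0 <- pmax(s0, 0.2 * abs(m0), 0.2)
  (m1 - m0) / (s1 + s0)
}

#' Rank genes by Pearson correlation with a per-sample covariate
#'
#' The preranked metric used in the single-cell viral-load analysis: each
#' gene's Pearson correlation with the covariate. Zero-variance genes have
#' no defined correlation and are excluded with a message.
#'
#' @param m An [expr_matrix] with >= 3 samples.
#' @param covariate Numeric vector, one value per sample (optionally named
#'   by sample id).
#' @return A [ranked_list] with metric name `"pearson"`.
#' @export
rank_by_correlation <- function(m, covariate) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 3L) pls_error("correlation ranking needs >= 3 samples")
  if (!is.null(names(covariate))) {
    missing <- setdiff(sample_ids(m), names(covariate))
    if (length(missing))
      pls_error(sprintf("covariate missing for sample(s): %s",
                        paste(missing, collapse = ", ")))
    covariate <- covariate[sample_ids(m)]
  }
  if (length(covariate) != ncol(m$values))
    pls_error("covariate length must equal the number of samples")
  if (anyNA(covariate)) pls_error("covariate contains missing values")
  if (stats::sd(covariate) == 0)
    pls_error("covariate is constant; correlation is undefined")
  sds <- row_sds(m$values)
  keep <- sds > 0
  if (any(!keep))
    message(sum(!keep), " zero-variance gene(s) excluded from the correlation ranking")
  if (sum(keep) < 2L) pls_error("fewer than 2 genes with non-zero variance")
  r <- as.vector(stats::cor(t(m$values[keep, , drop = FALSE]), covariate))
  ranked_list(gene_ids(m)[keep], r, metric_name = "pearson")
}

#' Read / write RNK ranked-list files
#'
#' RNK is a two-column tab-separated format (gene, metric), no header.
#'
#' @param path File path.
#' @param metric_name Label attached to the loaded metric.
#' @return [read_rnk()] returns a [ranked_list]; [write_rnk()] its path.
#' @export
read_rnk <- function(path, metric_name = "rnk") {
  if (!file.exists(path))
    pls_error(sprintf("RNK file not found: %s", path), "plsassay_input_error")
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) pls_error("RNK file needs two columns", "plsassay_parse_error")
  ranked_list(tab[[1]], as.numeric(tab[[2]]), metric_name = metric_name)
}

#' @rdname read_rnk
#' @param rl A `ranked_list`.
#' @export
write_rnk <- function(rl, path) {
  utils::write.table(data.frame(gene = rl$genes, metric = unname(rl$metric)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
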