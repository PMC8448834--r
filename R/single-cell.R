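#' Single-cell quality-control parameters
#'
#' Defaults follow the published filters: cells need a read alignment rate
#' of at least 50% (inclusive) and at least 100,000 aligned read pairs
#' (inclusive); cells with >80% mitochondrial transcripts (strict) or
#' <1500 total transcripts (strict) are removed; genes whose Pearson
#' correlation with the artifact transcript KCNQ1OT1 exceeds 0.4 are
#' removed; genes must reach at least `minexpr` counts in at least
#' `minnumber` cells.
#'
#' @param mintotal Minimum transcript total per cell (cells strictly below
#'   are removed).
#' @param mito_max Maximum mitochondrial fraction (cells strictly above are
#'   removed).
#' @param artifact_gene Artifact transcript identifier.
#' @param artifact_r Pearson correlation threshold (genes strictly above
#'   are removed).
#' @param minexpr,minnumber Gene expression filter: keep genes with value
#'   >= `minexpr` in >= `minnumber` cells.
#' @param align_rate_min Minimum alignment rate (inclusive).
#' @param aligned_pairs_min Minimum aligned read pairs (inclusive).
#' @param mito_prefix Prefix identifying mitochondrial genes.
#' @return An object of class `cell_qc_params`.
#' @export
cell_qc_params <- function(mintotal = 1500, mito_max = 0.80,
                           artifact_gene = "KCNQ1OT1", artifact_r = 0.4,
                           minexpr = 2, minnumber = 5,
                           align_rate_min = 0.50, aligned_pairs_min = 100000,
                           mito_prefix = "MT-") {
  stopifnot(mintotal >= 0, mito_max >= 0, mito_max <= 1, artifact_r >= -1,
            minexpr >= 0, minnumber >= 0,
            align_rate_min >= 0, align_rate_min <= 1, aligned_pairs_min >= 0)
  structure(list(mintotal = mintotal, mito_max = mito_max,
                 artifact_gene = artifact_gene, artifact_r = artifact_r,
                 minexpr = minexpr, minnumber = minnumber,
                 align_rate_min = align_rate_min,
                 aligned_pairs_min = aligned_pairs_min,
                 mito_prefix = mito_prefix),
            class = "cell_qc_params")
}

#' Filter cells on alignment statistics
#'
#' Keeps cells with `align_rate >= align_rate_min` and
#' `aligned_pairs >= aligned_pairs_min` (both inclusive, per the "at least"
#' wording of the protocol).
#'
#' @param stats A data.frame with columns `cell`, `align_rate`,
#'   `aligned_pairs`.
#' @param p A [cell_qc_params].
#' @return Character vector of kept cell ids, with attribute `removed`.
#' @export
filter_cells_alignment <- function(stats, p = cell_qc_params()) {
  stats <- as.data.frame(stats)
  need <- c("cell", "align_rate", "aligned_pairs")
  miss <- setdiff(need, names(stats))
  if (length(miss))
    pls_error(sprintf("alignment stats missing column(s): %s",
                      paste(miss, collapse = ", ")))
  if (anyNA(stats$align_rate) || anyNA(stats$aligned_pairs))
    pls_error("alignment stats contain missing values")
  keep <- stats$align_rate >= p$align_rate_min &
          stats$aligned_pairs >= p$aligned_pairs_min
  out <- as.character(stats$cell[keep])
  attr(out, "removed") <- as.character(stats$cell[!keep])
  out
}

#' Filter cells on transcript totals and mitochondrial fraction
#'
#' Removes cells whose mitochondrial transcript fraction is strictly above
#' `mito_max` (">80%") or whose transcript total is strictly below
#' `mintotal` ("<1500"). Mitochondrial genes are identified by the
#' configured row-name prefix.
#'
#' @param counts A counts-scale [expr_matrix] (genes x cells).
#' @param p A [cell_qc_params].
#' @return The filtered `expr_matrix` with attribute `removed`, a list with
#'   elements `high_mito` and `low_total`.
#' @export
filter_cells_counts <- function(counts, p = cell_qc_params()) {
  stopifnot(inherits(counts, "expr_matrix"))
  totals <- colSums(counts$values)
  mito <- startsWith(gene_ids(counts), p$mito_prefix)
  mito_frac <- if (any(mito))
    colSums(counts$values[mito, , drop = FALSE]) / pmax(totals, 1) else rep(0, length(totals))
  high_mito <- mito_frac > p$mito_max        # strict: ">80%"
  low_total <- totals < p$mintotal           # strict: "<1500"
  keep <- !(high_mito | low_total)
  out <- counts[, keep]
  attr(out, "removed") <- list(high_mito = sample_ids(counts)[high_mito],
                               low_total = sample_ids(counts)[low_total])
  out
}

#' Remove artifact-correlated and rarely expressed genes
#'
#' If the artifact transcript is present, every gene whose Pearson
#' correlation with it across cells exceeds `artifact_r` is removed
#' (including the artifact transcript itself, which correlates perfectly
#' with itself); otherwise the rule is skipped with a warning. Genes must
#' then reach at least `minexpr` counts in at least `minnumber` cells.
#'
#' @param counts A counts-scale [expr_matrix] (genes x cells).
#' @param p A [cell_qc_params].
#' @return The filtered `expr_matrix` with attribute `removed`, a list with
#'   elements `artifact_correlated` and `rare`.
#' @export
filter_artifact_and_rare_genes <- function(counts, p = cell_qc_params()) {
  stopifnot(inherits(counts, "expr_matrix"))
  v <- counts$values
  artifact_removed <- character(0)
  if (p$artifact_gene %in% rownames(v)) {
    a <- v[p$artifact_gene, ]
    if (stats::sd(a) > 0) {
      sds <- row_sds(v)
      r <- rep(NA_real_, nrow(v))
      r[sds > 0] <- as.vector(stats::cor(t(v[sds > 0, , drop = FALSE]), a))
      artifact_removed <- rownames(v)[!is.na(r) & r > p$artifact_r]
    } else warning("artifact gene is constant; correlation rule skipped",
                   call. = FALSE)
  } else warning(sprintf("artifact gene '%s' absent; correlation rule skipped",
                         p$artifact_gene), call. = FALSE)
  v <- v[setdiff(rownames(v), artifact_removed), , drop = FALSE]
  expressed <- rowSums(v >= p$minexpr) >= p$minnumber
  rare <- rownames(v)[!expressed]
  out <- expr_matrix(v[expressed, , drop = FALSE], scale = counts$scale,
                     sample_meta = counts$sample_meta)
  attr(out, "removed") <- list(artifact_correlated = artifact_removed, rare = rare)
  out
}

#' Per-cell total-count normalization
#'
#' Normalizes each cell's total transcript count to 1 and multiplies by the
#' minimum total across the (QC-passing) cells, so every column sum equals
#' that minimum and within-cell proportions are preserved exactly.
#'
#' @param counts A counts-scale [expr_matrix] with >= 1 cell.
#' @return An `expr_matrix` with equalized column sums and attribute
#'   `target_total`.
#' @export
sc_normalize <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"))
  totals <- colSums(counts$values)
  if (any(totals == 0)) pls_error("cell(s) with zero total transcript count")
  target <- min(totals)
  out <- expr_matrix(sweep(counts$values, 2, target / totals, `*`),
                     scale = "counts", sample_meta = counts$sample_meta)
  attr(out, "target_total") <- target
  out
}

#' Viral-load correlation enrichment of the prognostic signature
#'
#' Ranks genes by their Pearson correlation with the per-cell viral load,
#' runs preranked enrichment of the poor- and good-prognosis sets on that
#' ranking, and additionally reports the Pearson correlation between each
#' set's mean expression and the viral load (both aggregates, since either
#' may be the published summary).
#'
#' @param counts An [expr_matrix] of cells (counts are log2-transformed
#'   with pseudocount 1 before correlation; a log2 matrix is used as is).
#' @param viral_load Non-negative numeric vector, one value per cell
#'   (optionally named by cell id); must not be constant.
#' @param sig A [build_signature] result.
#' @param params An [enrichment_params] (preranked; `perm_mode` gene_set).
#' @param alpha FDR threshold used for the reported status gate.
#' @return A list of class `viral_load_enrichment`: `poor` and `good`
#'   result rows, the full `pls_gsea` table, `cor_poor`, `cor_good` (mean
#'   set expression vs viral load), `label`, and the ranking.
#' @export
viral_load_enrichment <- function(counts, viral_load, sig,
                                  params = enrichment_params(), alpha = 0.25) {
  stopifnot(inherits(counts, "expr_matrix"), inherits(sig, "prognostic_signature"))
  if (ncol(counts$values) < 3L) pls_error("need >= 3 cells")
  m <- if (counts$scale == "counts") log2_with_pseudocount(counts, 1) else counts
  rl <- rank_by_correlation(m, viral_load)
  res <- gsea(rl, list(poor = sig$poor, good = sig$good), params = params)
  if (!is.null(names(viral_load))) viral_load <- viral_load[sample_ids(m)]
  set_cor <- function(s) {
    g <- intersect(s$genes, gene_ids(m))
    if (length(g) < 1L) return(NA_real_)
    stats::cor(colMeans(m$values[g, , drop = FALSE]), viral_load)
  }
  poor <- res[res$set == "poor", ]; good <- res[res$set == "good", ]
  structure(list(poor = poor, good = good, results = res,
                 cor_poor = set_cor(sig$poor), cor_good = set_cor(sig$good),
                 label = global_status(poor, good, alpha)$label,
                 ranking = rl, alpha = alpha),
            class = "viral_load_enrichment")
}

#' @export
print.viral_load_enrichment <- function(x, ...) {
  cat("<viral_load_enrichment>\n")
  cat(sprintf("  poor set: NES %.3f, q %.3g | good set: NES %.3f, q %.3g\n",
              x$poor$NES, x$poor$fdr_q, x$good$NES, x$good$fdr_q))
  cat(sprintf("  mean-set-expression correlation with viral load: poor %.3f, good %.3f\n",
              x$cor_poor, x$cor_good))
  invisible(x)
}
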