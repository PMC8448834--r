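#' Classify global signature status from the paired enrichment results
#'
#' The induction score is `delta = NES_poor - NES_good`. The global label is
#' `"poor"` when `delta > 0` and at least one of the two sets is significant
#' (`min(q) < alpha`), `"good"` when `delta < 0` under the same gate, and
#' `"indeterminate"` otherwise. The significance convention is the GSEA one
#' (q < 0.25 by default).
#'
#' @param poor,good Single-row results (lists or `pls_gsea` rows) carrying
#'   `NES` and `fdr_q`, both computed from the same ranking.
#' @param alpha Significance threshold on the FDR q-value (default 0.25).
#' @return A list with `label` and `delta`.
#' @export
global_status <- function(poor, good, alpha = 0.25) {
  np <- as.numeric(poor$NES); ng <- as.numeric(good$NES)
  qp <- as.numeric(poor$fdr_q); qg <- as.numeric(good$fdr_q)
  if (is.na(np) || is.na(ng)) return(list(label = "indeterminate", delta = NA_real_))
  delta <- np - ng
  label <- if (min(qp, qg) >= alpha || delta == 0) "indeterminate"
           else if (delta > 0) "poor" else "good"
  list(label = label, delta = delta)
}

#' Signed significance encoding for simplified heatmaps
#'
#' Encodes an enrichment result as
#' `sign(NES) * (-log10(max(q, floor)))`, the signed log10-FDR convention
#' of the simplified status heatmaps.
#'
#' @param r A result carrying `NES` and `fdr_q`.
#' @param floor Lower clamp for the q-value (typically `1/(n_perm+1)`).
#' @return A single signed value.
#' @export
heatmap_encode <- function(r, floor = 1e-4) {
  q <- max(as.numeric(r$fdr_q), floor)
  nes <- as.numeric(r$NES)
  if (is.na(nes)) return(0)
  sign(nes) * (-log10(q))
}

#' Assess prognostic-signature status of a case versus a reference arm
#'
#' The assay pipeline: the two arms are merged on their shared gene space,
#' jointly housekeeping-normalized (counts input), log2-transformed, ranked
#' case-versus-reference, and the poor- and good-prognosis sets are scored
#' by the enrichment engine with a pooled permutation FDR. The global label
#' then follows [global_status].
#'
#' @param case,reference [expr_matrix] arms on a shared gene space and the
#'   same scale. Counts matrices are normalized and log2-transformed;
#'   log2 matrices are ranked directly.
#' @param sig A [build_signature] result.
#' @param params An [enrichment_params].
#' @param alpha FDR significance threshold (default 0.25).
#' @param coverage_min Minimum fraction of each prognosis set that must be
#'   present in the shared gene space (default 0.5).
#' @param pseudocount Pseudocount for normalization and log2 transform.
#' @return An object of class `pls_status`: the per-set results, induction
#'   score `delta`, `global_label`, signed heatmap encodings, and the
#'   ranking used.
#' @export
assess_pls <- function(case, reference, sig, params = enrichment_params(),
                       alpha = 0.25, coverage_min = 0.5, pseudocount = 0.5) {
  stopifnot(inherits(sig, "prognostic_signature"))
  merged <- merge_arms(case, reference)
  m <- merged$matrix
  cov <- match_matrix(sig, m)
  for (nm in c("poor", "good")) {
    if (cov[[nm]]$coverage < coverage_min)
      pls_error(sprintf(
        "%s-prognosis set coverage %.2f below %.2f; missing: %s",
        nm, cov[[nm]]$coverage, coverage_min,
        paste(utils::head(cov[[nm]]$missing, 10), collapse = ", ")),
        "plsassay_coverage_error")
  }
  if (m$scale == "counts") {
    norm <- housekeeping_normalize(m, sig$housekeeping, pseudocount = pseudocount)
    m <- log2_with_pseudocount(norm$matrix, c = max(pseudocount, 1e-6))
  } else norm <- NULL
  rl <- rank_by_phenotype(m, merged$case_ids, merged$ref_ids,
                          metric = params$metric)
  if (all(abs(rl$metric) < 1e-12)) {
    # degenerate contrast (e.g. case identical to reference): every metric
    # is zero, so enrichment is meaningless and the status is indeterminate
    row0 <- data.frame(set = c("poor", "good"), ES = 0, NES = NA_real_,
                       p_nominal = 1, fdr_q = 1,
                       n_hits = c(length(intersect(sig$poor$genes, gene_ids(m))),
                                  length(intersect(sig$good$genes, gene_ids(m)))),
                       null_mean = NA_real_, null_sd = NA_real_,
                       degenerate = TRUE, stringsAsFactors = FALSE)
    row0$leading_edge <- I(list(character(0), character(0)))
    class(row0) <- c("pls_gsea", "data.frame")
    res <- row0
  } else {
    res <- gsea(m, list(poor = sig$poor, good = sig$good), params = params,
                case = merged$case_ids, ref = merged$ref_ids)
  }
  poor <- res[res$set == "poor", ]; good <- res[res$set == "good", ]
  gs <- global_status(poor, good, alpha = alpha)
  floor_q <- 1 / (params$n_perm + 1)
  hm <- c(poor = heatmap_encode(poor, floor_q),
          good = heatmap_encode(good, floor_q),
          global = if (gs$label == "indeterminate") 0
                   else sign(gs$delta) * -log10(max(min(poor$fdr_q, good$fdr_q), floor_q)))
  structure(list(poor = poor, good = good, results = res,
                 delta = gs$delta, global_label = gs$label, heatmap = hm,
                 alpha = alpha, params = params, coverage = cov,
                 normalization = norm),
            class = "pls_status")
}

#' @export
print.pls_status <- function(x, ...) {
  cat(sprintf("<pls_status> global label: %s (delta = %.3f, alpha = %.2f)\n",
              x$global_label, x$delta, x$alpha))
  print(x$results)
  invisible(x)
}

#' @export
summary.pls_status <- function(object, ...) {
  cat("Prognostic signature status assay\n")
  cat(sprintf("  global label : %s\n", object$global_label))
  cat(sprintf("  delta (NES_poor - NES_good): %.3f\n", object$delta))
  cat(sprintf("  poor set: NES %.3f, q %.3g | good set: NES %.3f, q %.3g\n",
              object$poor$NES, object$poor$fdr_q,
              object$good$NES, object$good$fdr_q))
  cat(sprintf("  heatmap encodings: poor %+.2f, good %+.2f, global %+.2f\n",
              object$heatmap["poor"], object$heatmap["good"],
              object$heatmap["global"]))
  if (!is.null(object$reversal))
    cat(sprintf("  reversal significant: %s\n", object$reversal))
  invisible(object)
}

#' Assess signature reversal of a treated arm versus an injured control
#'
#' Runs the same pipeline as [assess_pls] with the treated arm as case and
#' the injured control as reference, then applies the one-sided reversal
#' rule: the reversal is significant iff the poor-prognosis set is
#' suppressed (`q_poor < alpha` and `NES_poor < 0`) or the good-prognosis
#' set is induced (`q_good < alpha` and `NES_good > 0`).
#'
#' @inheritParams assess_pls
#' @param treated Treated (compound) arm.
#' @param control Injured control arm (reference).
#' @return A `pls_status` with additional class `pls_reversal` and element
#'   `reversal` (logical).
#' @export
assess_reversal <- function(treated, control, sig, params = enrichment_params(),
                            alpha = 0.25, coverage_min = 0.5, pseudocount = 0.5) {
  st <- assess_pls(treated, control, sig, params = params, alpha = alpha,
                   coverage_min = coverage_min, pseudocount = pseudocount)
  st$reversal <- isTRUE(st$poor$fdr_q < alpha && st$poor$NES < 0) ||
                 isTRUE(st$good$fdr_q < alpha && st$good$NES > 0)
  class(st) <- c("pls_reversal", class(st))
  st
}

#' Run a signature-reversal compound screen
#'
#' Assesses every compound arm against the shared injured control with
#' [assess_reversal], then ranks compounds by the smallest FDR q among
#' their reversal-direction sets (ascending), breaking ties by `|delta|`
#' descending and then compound id. A compound is a hit iff its reversal is
#' significant at `alpha`.
#'
#' @param arms Named list of treated [expr_matrix] arms (names are compound
#'   ids).
#' @param control Injured control [expr_matrix].
#' @inheritParams assess_pls
#' @return An object of class `pls_screen`: a ranked data.frame
#'   (`compound`, `q_poor`, `q_good`, `NES_poor`, `NES_good`, `delta`,
#'   `rank_key`, `hit`, `rank`) plus `summary` (`n_hits`, `n_compounds`,
#'   `hit_rate`) and the per-compound `pls_status` objects.
#' @export
run_screen <- function(arms, control, sig, params = enrichment_params(),
                       alpha = 0.25, coverage_min = 0.5, pseudocount = 0.5) {
  if (length(arms) < 1L) pls_error("screen needs at least one compound arm")
  if (is.null(names(arms)) || any(!nzchar(names(arms))))
    pls_error("compound arms must be named")
  statuses <- lapply(arms, assess_reversal, control = control, sig = sig,
                     params = params, alpha = alpha,
                     coverage_min = coverage_min, pseudocount = pseudocount)
  key <- vapply(statuses, function(st) {
    dirq <- c(if (st$poor$NES < 0) st$poor$fdr_q,
              if (st$good$NES > 0) st$good$fdr_q)
    if (length(dirq)) min(dirq) else 1
  }, numeric(1))
  tab <- data.frame(compound = names(arms),
                    q_poor = vapply(statuses, function(s) s$poor$fdr_q, 0),
                    q_good = vapply(statuses, function(s) s$good$fdr_q, 0),
                    NES_poor = vapply(statuses, function(s) s$poor$NES, 0),
                    NES_good = vapply(statuses, function(s) s$good$NES, 0),
                    delta = vapply(statuses, function(s) s$delta, 0),
                    rank_key = key,
                    hit = vapply(statuses, function(s) isTRUE(s$reversal), TRUE),
                    stringsAsFactors = FALSE)
  ord <- order(tab$rank_key, -abs(tab$delta), tab$compound, method = "radix")
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 summary = list(n_hits = sum(tab$hit),
                                n_compounds = nrow(tab),
                                hit_rate = mean(tab$hit)),
                 statuses = statuses, alpha = alpha),
            class = "pls_screen")
}

#' @export
print.pls_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pls_screen> %d compounds, %d hits (hit rate %.2f) at alpha %.2f\n",
              s$n_compounds, s$n_hits, s$hit_rate, x$alpha))
  df <- x$table
  df$delta <- round(df$delta, 2)
  df$q_poor <- signif(df$q_poor, 3); df$q_good <- signif(df$q_good, 3)
  df$NES_poor <- round(df$NES_poor, 2); df$NES_good <- round(df$NES_good, 2)
  print(utils::head(df[, c("rank", "compound", "q_poor", "q_good",
                           "NES_poor", "NES_good", "delta", "hit")], 10),
        row.names = FALSE)
  if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more\n")
  invisible(x)
}

#' @export
summary.pls_screen <- function(object, ...) {
  print(object)
  invisible(object$summary)
}

#' Write a screen result table as TSV
#' @param x A `pls_screen`.
#' @param path Output path.
#' @export
write_screen_tsv <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
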