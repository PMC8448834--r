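#' Enrichment analysis parameters
#'
#' Bundles the knobs of the weighted running-sum enrichment engine. The
#' weighting exponent applies `|metric|^weight_p` increments at gene-set
#' hits; `weight_p = 0` gives the classical unweighted Kolmogorov-Smirnov
#' statistic, `1` (the default) the standard weighted statistic.
#' Permutation nulls are drawn either as random same-size gene sets on the
#' fixed ranking (`"gene_set"`, the default: with ~3 replicates per arm,
#' phenotype permutation is degenerate) or as phenotype label shuffles with
#' re-ranking (`"phenotype"`).
#'
#' @param weight_p Weighting exponent, one of 0, 1, 2.
#' @param n_perm Number of permutations (>= 100 recommended for FDR
#'   reporting; a warning is emitted below that).
#' @param perm_mode `"gene_set"` or `"phenotype"`.
#' @param seed Integer seed governing the permutation stream.
#' @param metric Phenotype ranking metric. The default `"log2fc"` is
#'   level-independent; `"signal2noise"` applies the classical floored
#'   sigma denominator, which couples metric magnitude to expression level
#'   and can bias gene-set-permutation nulls when arms differ in baseline
#'   (see the methods vignette).
#' @return An object of class `enrichment_params`.
#' @export
enrichment_params <- function(weight_p = 1, n_perm = 1000,
                              perm_mode = c("gene_set", "phenotype"),
                              seed = 1,
                              metric = c("log2fc", "signal2noise", "pearson")) {
  perm_mode <- match.arg(perm_mode)
  metric <- match.arg(metric)
  if (!weight_p %in% c(0, 1, 2)) pls_error("weight_p must be 0, 1 or 2")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) pls_error("n_perm must be a positive integer")
  if (n_perm < 100L)
    warning("n_perm < 100: FDR estimates will be coarse", call. = FALSE)
  structure(list(weight_p = weight_p, n_perm = n_perm, perm_mode = perm_mode,
                 seed = as.integer(seed), metric = metric),
            class = "enrichment_params")
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom, incrementing by
#' \eqn{|r_j|^p / N_R} at gene-set hits (with \eqn{N_R} the sum of hit
#' weights) and decrementing by \eqn{1/(N - N_H)} at misses. The enrichment
#' score is the maximal signed deviation of this running sum from zero; on
#' an exact magnitude tie the positive extreme is reported. The leading
#' edge is the hits at or before the maximum (positive ES) or at or after
#' the minimum (negative ES).
#'
#' @param rl A [ranked_list].
#' @param s A [gene_set] or character vector; must intersect the list but
#'   not cover it entirely.
#' @param weight_p Weighting exponent (0, 1 or 2).
#' @return A list of class `enrichment_curve`: `ES`, `running_sum` (length
#'   N), `leading_edge`, `n_hits`, `hit_positions`.
#' @export
enrichment_score <- function(rl, s, weight_p = 1) {
  stopifnot(inherits(rl, "ranked_list"))
  set_genes <- as_gene_vector(s)
  N <- length(rl$genes)
  hit <- rl$genes %in% set_genes
  NH <- sum(hit)
  if (NH == 0L)
    pls_error("gene set has no gene in the ranked list", "plsassay_coverage_error")
  if (NH == N) pls_error("gene set covers the whole ranked list")
  w <- abs(rl$metric)^weight_p
  NR <- sum(w[hit])
  inc <- numeric(N)
  if (NR > 0) inc[hit] <- w[hit] / NR
  else {
    warning("all hit weights are zero; falling back to unweighted increments",
            call. = FALSE)
    inc[hit] <- 1 / NH
  }
  inc[!hit] <- -1 / (N - NH)
  rs <- cumsum(inc)
  mx <- max(rs); mn <- min(rs)
  # magnitude ties (within 1e-9) resolve to the positive extreme so the
  # choice is immune to accumulation-order floating-point noise
  ES <- if (mx >= -mn - 1e-9) mx else mn
  if (ES >= 0) {
    cut <- which.max(rs)
    le <- rl$genes[hit & seq_len(N) <= cut]
  } else {
    cut <- which.min(rs)
    le <- rl$genes[hit & seq_len(N) >= cut]
  }
  structure(list(ES = ES, running_sum = rs, leading_edge = le,
                 n_hits = NH, hit_positions = which(hit)),
            class = "enrichment_curve")
}

# O(n_hits) extremum of the running sum from sorted hit positions.
# The running sum only peaks at hits and only bottoms out just before hits
# (or at the final position, where it returns exactly to 0), so the full
# cumulative walk is unnecessary inside permutation loops.
es_from_positions <- function(pos, w, N) {
  NH <- length(pos)
  Nm <- N - NH
  NR <- sum(w)
  ph <- if (NR > 0) cumsum(w) / NR else seq_len(NH) / NH
  miss_before <- (pos - seq_len(NH)) / Nm
  top <- ph - miss_before
  bottom <- c(0, ph[-NH]) - miss_before
  mx <- max(top)
  mn <- min(bottom, 0)
  if (mx >= -mn - 1e-9) mx else mn
}

#' Permutation null distribution of enrichment scores
#'
#' In `gene_set` mode, draws `n_perm` random same-size gene sets from the
#' ranked list and scores each. In `phenotype` mode, shuffles the sample
#' labels of the supplied expression context, re-ranks, and scores the
#' supplied gene set on each re-ranking. Reproducible given
#' `params$seed`.
#'
#' @param rl A [ranked_list].
#' @param set_size Number of genes in the null sets (gene_set mode).
#' @param params An [enrichment_params].
#' @param rerank Phenotype-mode context: a list with `matrix`
#'   ([expr_matrix]), `case`, `ref` (sample ids), and `genes` (the gene set
#'   being tested, whose positions move as the ranking changes).
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
null_distribution <- function(rl, set_size, params, rerank = NULL) {
  stopifnot(inherits(rl, "ranked_list"), inherits(params, "enrichment_params"))
  N <- length(rl$genes)
  if (params$perm_mode == "gene_set") {
    if (set_size < 1L || set_size >= N) pls_error("invalid null set size")
    w_all <- abs(rl$metric)^params$weight_p
    with_seed(params$seed, vapply(seq_len(params$n_perm), function(b) {
      pos <- sort.int(sample.int(N, set_size))
      es_from_positions(pos, w_all[pos], N)
    }, numeric(1)))
  } else {
    if (is.null(rerank) || is.null(rerank$matrix) || is.null(rerank$genes))
      pls_error("phenotype-mode nulls need a rerank context (matrix, case, ref, genes)")
    m <- rerank$matrix
    all_idx <- match(c(resolve_samples(m, rerank$case),
                       resolve_samples(m, rerank$ref)),
                     sample_ids(m))
    n1 <- length(resolve_samples(m, rerank$case))
    genes <- as_gene_vector(rerank$genes)
    with_seed(params$seed, vapply(seq_len(params$n_perm), function(b) {
      sh <- sample(all_idx)
      vals <- ranking_metric(m$values, sh[seq_len(n1)], sh[-seq_len(n1)],
                             params$metric)
      prl <- ranked_list(gene_ids(m), vals, metric_name = params$metric)
      pos <- which(prl$genes %in% genes)
      es_from_positions(pos, abs(prl$metric[pos])^params$weight_p,
                        length(prl$genes))
    }, numeric(1)))
  }
}

#' Normalized enrichment scores and pooled permutation FDR
#'
#' Completes draft enrichment results with NES, nominal p, and FDR q. NES
#' divides the observed ES by the mean magnitude of same-sign null scores;
#' nominal p uses the add-one convention on same-sign nulls. FDR q follows
#' the pooled-null NES procedure: every null ES is normalized by its own
#' set's same-sign null mean, nulls are pooled across all queried sets, and
#' q is the ratio of the null tail fraction to the observed tail fraction at
#' the observed NES, clamped to `[1/(n_perm+1), 1]`. A set with no same-sign
#' nulls is flagged degenerate (NES `NA`, p 1, q 1).
#'
#' @param observed A list of draft results (each with `set_name`, `ES`,
#'   `leading_edge`, `n_hits`) or a list of [enrichment_score] curves with
#'   names.
#' @param nulls A list of numeric null ES vectors, parallel to `observed`.
#' @return A data.frame of class `pls_gsea` with one row per set: `set`,
#'   `ES`, `NES`, `p_nominal`, `fdr_q`, `n_hits`, `null_mean`, `null_sd`,
#'   `degenerate`, and a `leading_edge` list column.
#' @export
nes_and_fdr <- function(observed, nulls) {
  if (length(observed) != length(nulls))
    pls_error("observed and nulls must be parallel lists")
  n_sets <- length(observed)
  es <- numeric(n_sets); nes <- numeric(n_sets)
  p_nom <- numeric(n_sets); nmean <- numeric(n_sets); nsd <- numeric(n_sets)
  degen <- logical(n_sets)
  null_nes <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    e <- observed[[i]]$ES
    nv <- nulls[[i]]
    pos <- nv[nv >= 0]; neg <- nv[nv < 0]
    same <- if (e >= 0) pos else neg
    denom <- if (e >= 0) mean(pos) else mean(abs(neg))
    es[i] <- e
    # each side of the null is normalized by its own mean magnitude
    null_nes[[i]] <- c(if (length(pos) && mean(pos) > 0) pos / mean(pos),
                       if (length(neg)) neg / mean(abs(neg)))
    if (length(same) == 0L || !is.finite(denom) || denom == 0) {
      degen[i] <- TRUE
      nes[i] <- NA_real_; p_nom[i] <- 1
      nmean[i] <- NA_real_; nsd[i] <- NA_real_
    } else {
      nes[i] <- e / denom
      p_nom[i] <- (1 + sum(abs(same) >= abs(e))) / (1 + length(same))
      nmean[i] <- mean(same); nsd[i] <- stats::sd(same)
    }
  }
  pooled <- unlist(null_nes)
  fdr <- rep(1, n_sets)
  obs_ok <- nes[!degen]
  for (i in seq_len(n_sets)) {
    if (degen[i]) next
    floor_q <- 1 / (length(nulls[[i]]) + 1)
    if (nes[i] >= 0) {
      num <- if (sum(pooled >= 0)) sum(pooled >= nes[i]) / sum(pooled >= 0) else 1
      den <- sum(obs_ok >= nes[i]) / max(1, sum(obs_ok >= 0))
    } else {
      num <- if (sum(pooled < 0)) sum(pooled <= nes[i]) / sum(pooled < 0) else 1
      den <- sum(obs_ok <= nes[i]) / max(1, sum(obs_ok < 0))
    }
    q <- if (is.finite(den) && den > 0) num / den else 1
    fdr[i] <- min(1, max(q, floor_q))
  }
  set_names <- vapply(seq_len(n_sets), function(i)
    observed[[i]]$set_name %||% names(observed)[i] %||% paste0("set", i), "")
  res <- data.frame(set = set_names, ES = es, NES = nes, p_nominal = p_nom,
                    fdr_q = fdr,
                    n_hits = vapply(observed, function(o) as.integer(o$n_hits), 1L),
                    null_mean = nmean, null_sd = nsd, degenerate = degen,
                    stringsAsFactors = FALSE)
  res$leading_edge <- I(lapply(observed, `[[`, "leading_edge"))
  class(res) <- c("pls_gsea", "data.frame")
  res
}

#' Gene-set enrichment analysis
#'
#' Orchestrates ranking (for a matrix input), enrichment scoring,
#' permutation nulls, and NES/FDR completion. Deterministic given
#' `params$seed`.
#'
#' @param input An [expr_matrix] (with `case`/`ref` supplied) or a
#'   [ranked_list] for preranked mode.
#' @param sets A [gene_set], a list of them, or a named list of character
#'   vectors.
#' @param params An [enrichment_params].
#' @param case,ref Sample ids or condition labels (matrix mode only).
#' @return A `pls_gsea` data.frame (see [nes_and_fdr]), with the ranked list
#'   and parameters in attributes `ranked_list` and `params`.
#' @export
gsea <- function(input, sets, params = enrichment_params(), case = NULL, ref = NULL) {
  stopifnot(inherits(params, "enrichment_params"))
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (is.null(names(sets)))
    names(sets) <- vapply(seq_along(sets), function(i) {
      s <- sets[[i]]
      if (inherits(s, "gene_set")) s$name else paste0("set", i)
    }, "")
  if (inherits(input, "ranked_list")) {
    rl <- input
    pheno_ctx <- NULL
  } else if (inherits(input, "expr_matrix")) {
    if (is.null(case) || is.null(ref))
      pls_error("matrix-mode gsea needs case and ref sample groups")
    rl <- rank_by_phenotype(input, case, ref, metric = params$metric)
    pheno_ctx <- list(matrix = input, case = case, ref = ref)
  } else pls_error("input must be an expr_matrix or a ranked_list")
  obs <- lapply(names(sets), function(nm) {
    curve <- enrichment_score(rl, sets[[nm]], weight_p = params$weight_p)
    list(set_name = nm, ES = curve$ES, leading_edge = curve$leading_edge,
         n_hits = curve$n_hits)
  })
  if (params$perm_mode == "phenotype" && is.null(pheno_ctx))
    pls_error("phenotype permutation requires a matrix input")
  null_cache <- new.env(parent = emptyenv())
  nulls <- lapply(seq_along(obs), function(i) {
    if (params$perm_mode == "gene_set") {
      key <- as.character(obs[[i]]$n_hits)
      if (is.null(null_cache[[key]]))
        null_cache[[key]] <- null_distribution(rl, obs[[i]]$n_hits, params)
      null_cache[[key]]
    } else {
      null_distribution(rl, obs[[i]]$n_hits, params,
                        rerank = c(pheno_ctx, list(genes = sets[[i]])))
    }
  })
  res <- nes_and_fdr(obs, nulls)
  attr(res, "ranked_list") <- rl
  attr(res, "params") <- params
  res
}

#' @export
print.pls_gsea <- function(x, ...) {
  cat(sprintf("<pls_gsea> %d gene set(s)\n", nrow(x)))
  df <- as.data.frame(x)[, c("set", "ES", "NES", "p_nominal", "fdr_q", "n_hits")]
  df$ES <- round(df$ES, 3); df$NES <- round(df$NES, 3)
  df$p_nominal <- signif(df$p_nominal, 3); df$fdr_q <- signif(df$fdr_q, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an enrichment result table as TSV
#'
#' Columns: set, ES, NES, p_nominal, fdr_q, n_hits, leading_edge
#' (comma-joined).
#'
#' @param x A `pls_gsea` data.frame.
#' @param path Output path.
#' @export
write_gsea_tsv <- function(x, path) {
  df <- as.data.frame(x)[, c("set", "ES", "NES", "p_nominal", "fdr_q", "n_hits")]
  df$leading_edge <- vapply(x$leading_edge, join_genes, "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
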