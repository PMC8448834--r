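#' Construct a perturbation profile
#'
#' One compound's differential-expression profile: per probe a gene
#' identifier, a z-score, and a probe class (`landmark` = directly
#' measured, `inferred` = imputed). Probe ids must be unique within a
#' profile and z-scores finite.
#'
#' @param id Perturbagen identifier.
#' @param probes A data.frame with columns `probe`, `gene`, `z`,
#'   `probe_class`.
#' @return An object of class `perturbation_profile`.
#' @export
perturbation_profile <- function(id, probes) {
  probes <- as.data.frame(probes)
  need <- c("probe", "gene", "z", "probe_class")
  if (!all(need %in% names(probes)))
    pls_error(sprintf("probe table needs columns: %s", paste(need, collapse = ", ")))
  if (anyDuplicated(probes$probe)) pls_error("duplicate probe ids in profile")
  if (anyNA(probes$z) || any(!is.finite(probes$z)))
    pls_error("non-finite z-scores in profile")
  if (!all(probes$probe_class %in% c("landmark", "inferred")))
    pls_error("probe_class must be 'landmark' or 'inferred'")
  structure(list(id = id, probes = probes), class = "perturbation_profile")
}

#' @export
print.perturbation_profile <- function(x, ...) {
  cat(sprintf("<perturbation_profile> %s: %d probes (%d landmark), %d genes\n",
              x$id, nrow(x$probes), sum(x$probes$probe_class == "landmark"),
              length(unique(x$probes$gene))))
  invisible(x)
}

#' Collapse probes to unique genes
#'
#' For each gene, landmark probes take priority over inferred ones; among
#' the prioritized probes the one with the highest absolute z-score is
#' kept, with ties broken by probe id ascending.
#'
#' @param p A [perturbation_profile].
#' @return A data.frame (`gene`, `z`, `probe`, `probe_class`), one row per
#'   gene, with attribute `perturbagen`.
#' @export
collapse_probes <- function(p) {
  stopifnot(inherits(p, "perturbation_profile"))
  pr <- p$probes
  # order so that the preferred probe comes first within each gene:
  # landmark before inferred, then |z| descending, then probe id
  ord <- order(pr$gene, pr$probe_class != "landmark", -abs(pr$z), pr$probe,
               method = "radix")
  pr <- pr[ord, ]
  out <- pr[!duplicated(pr$gene), c("gene", "z", "probe", "probe_class")]
  rownames(out) <- NULL
  attr(out, "perturbagen") <- p$id
  out
}

#' Extract an up/down target signature from a gene-level profile
#'
#' Takes the top `k` genes by z descending as the up set and the bottom `k`
#' as the down set (the "top 100 up / top 100 down" convention). When the
#' profile has fewer than `2k` genes, `k` is reduced to `floor(n/2)` so the
#' sets never overlap. Ties in z are broken by gene id for determinism.
#'
#' @param p A gene-level profile (from [collapse_probes]) or any data.frame
#'   with `gene` and `z` columns.
#' @param k Set size (default 100).
#' @return A list of class `query_signature` with [gene_set]s `up` and
#'   `down`.
#' @export
extract_target_signature <- function(p, k = 100) {
  p <- as.data.frame(p)
  n <- nrow(p)
  if (n < 2L) pls_error("profile needs at least 2 genes")
  k <- min(as.integer(k), n %/% 2L)
  if (k < 1L) pls_error("profile too small for a non-empty signature")
  ord <- order(-p$z, p$gene, method = "radix")
  g <- p$gene[ord]
  query_signature(up = g[seq_len(k)], down = rev(g)[seq_len(k)])
}

#' Construct an up/down query signature
#'
#' @param up,down [gene_set]s or character vectors; disjoint and non-empty.
#' @return An object of class `query_signature`.
#' @export
query_signature <- function(up, down) {
  up <- if (inherits(up, "gene_set")) up else gene_set("up", up)
  down <- if (inherits(down, "gene_set")) down else gene_set("down", down)
  ov <- intersect(up$genes, down$genes)
  if (length(ov))
    pls_error(sprintf("up and down query sets overlap: %s",
                      paste(utils::head(ov, 5), collapse = ", ")))
  structure(list(up = up, down = down), class = "query_signature")
}

#' Connectivity-map KS statistic for a tag set
#'
#' The classical two-sided Kolmogorov-Smirnov statistic of a tag set's
#' positions within a ranked profile of length `n`:
#' `a = max_j (j/t - V_j/n)`, `b = max_j (V_j/n - (j-1)/t)`, and
#' `ks = a` if `a >= b` else `-b`.
#'
#' @param n Profile length.
#' @param V Strictly increasing tag positions in `1..n`.
#' @param t Tag count (defaults to `length(V)`).
#' @return The signed KS statistic.
#' @export
ks_tag <- function(n, V, t = length(V)) {
  if (t != length(V)) pls_error("t must equal the number of tag positions")
  if (t < 1L || t >= n) pls_error("need 1 <= t < n tags")
  if (any(V < 1L) || any(V > n) || is.unsorted(V, strictly = TRUE))
    pls_error("tag positions must be strictly increasing within 1..n")
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  if (a >= b) a else -b
}

#' Score perturbation profiles against an up/down query signature
#'
#' For each profile, genes are ordered by z descending (ties by gene id);
#' the up and down query sets give two tag-position vectors and two KS
#' statistics. The raw connectivity `s_raw = ks_up - ks_down` when the two
#' statistics have opposite (or zero) signs, else 0. Scores are scaled by
#' the collection extremes (`s/p_max` for positives, `s/|q_min|` for
#' negatives) into `[-1, 1]`. A permutation p-value and a tau percentile
#' are computed from random tag-position pairs of matched sizes (equivalent
#' to random query signatures of matched sizes), using the add-one
#' convention.
#'
#' @param profiles List of [perturbation_profile]s (or gene-level profile
#'   data.frames).
#' @param q A [query_signature].
#' @param n_perm Number of random queries for p/tau (default 1000).
#' @param seed Integer seed.
#' @return A data.frame of class `connectivity_result` with one row per
#'   scored profile: `perturbagen`, `n_genes`, `n_up`, `n_down`, `ks_up`,
#'   `ks_down`, `s_raw`, `score`, `p_perm`, `tau`.
#' @export
connectivity_score <- function(profiles, q, n_perm = 1000, seed = 1) {
  stopifnot(inherits(q, "query_signature"))
  if (inherits(profiles, "perturbation_profile")) profiles <- list(profiles)
  rows <- list()
  null_cache <- list()
  for (p in profiles) {
    gp <- if (inherits(p, "perturbation_profile")) collapse_probes(p) else as.data.frame(p)
    id <- attr(gp, "perturbagen") %||% (if (inherits(p, "perturbation_profile")) p$id else "profile")
    ord <- order(-gp$z, gp$gene, method = "radix")
    genes <- gp$gene[ord]
    n <- length(genes)
    up_pos <- which(genes %in% q$up$genes)
    down_pos <- which(genes %in% q$down$genes)
    if (length(up_pos) == 0L || length(down_pos) == 0L) {
      warning(sprintf("profile '%s' shares no gene with a query set; skipped", id),
              call. = FALSE)
      next
    }
    ks_up <- ks_tag(n, up_pos)
    ks_down <- ks_tag(n, down_pos)
    s_raw <- if (sign(ks_up) != sign(ks_down) || ks_up == 0 || ks_down == 0)
      ks_up - ks_down else 0
    ckey <- paste(n, length(up_pos), length(down_pos))
    if (is.null(null_cache[[ckey]]))
      null_cache[[ckey]] <- connectivity_null(n, length(up_pos), length(down_pos),
                                              n_perm, seed)
    nulls <- null_cache[[ckey]]
    p_perm <- (1 + sum(abs(nulls) >= abs(s_raw))) / (1 + length(nulls))
    tau <- tau_percentile(s_raw, nulls)
    rows[[length(rows) + 1L]] <- data.frame(
      perturbagen = id, n_genes = n,
      n_up = length(up_pos), n_down = length(down_pos),
      ks_up = ks_up, ks_down = ks_down, s_raw = s_raw,
      p_perm = p_perm, tau = tau, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    pls_error("no profile shared genes with the query signature",
              "plsassay_coverage_error")
  res <- do.call(rbind, rows)
  p_max <- max(res$s_raw); q_min <- min(res$s_raw)
  res$score <- ifelse(res$s_raw > 0 & p_max > 0, res$s_raw / p_max,
               ifelse(res$s_raw < 0 & q_min < 0, res$s_raw / abs(q_min), 0))
  res <- res[, c("perturbagen", "n_genes", "n_up", "n_down", "ks_up",
                 "ks_down", "s_raw", "score", "p_perm", "tau")]
  class(res) <- c("connectivity_result", "data.frame")
  res
}

# null raw connectivity scores for random disjoint tag-position pairs
connectivity_null <- function(n, t_up, t_down, n_perm, seed) {
  with_seed(seed, vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n, t_up + t_down)
    ku <- ks_tag(n, sort.int(idx[seq_len(t_up)]))
    kd <- ks_tag(n, sort.int(idx[-seq_len(t_up)]))
    if (sign(ku) != sign(kd) || ku == 0 || kd == 0) ku - kd else 0
  }, numeric(1)))
}

#' Tau percentile of a connectivity score against a background
#'
#' `tau = sign(score) * 100 * rank(|score| among background |scores|) /
#' |background|`, a signed percentile on the -100..100 scale. A score whose
#' magnitude beats the whole background reaches +/-100.
#'
#' @param score A raw or scaled connectivity score.
#' @param background Numeric vector of background scores (non-empty).
#' @return The tau percentile.
#' @export
tau_percentile <- function(score, background) {
  if (!length(background)) pls_error("empty tau background")
  sign(score) * 100 * sum(abs(background) <= abs(score)) / length(background)
}

#' Select candidate perturbagens by the published criteria
#'
#' `cmap`: negative score and permutation p-value < 0.05.
#' `lincs`: tau < -90.
#'
#' @param results A [connectivity_score] result table.
#' @param criterion `"cmap"` or `"lincs"`.
#' @param p_max,tau_max The thresholds (defaults 0.05 and -90).
#' @return Character vector of selected perturbagen ids.
#' @export
select_candidates <- function(results, criterion = c("cmap", "lincs"),
                              p_max = 0.05, tau_max = -90) {
  criterion <- match.arg(criterion)
  sel <- if (criterion == "cmap") results$score < 0 & results$p_perm < p_max
         else results$tau < tau_max
  results$perturbagen[sel]
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> %d profile(s)\n", nrow(x)))
  df <- as.data.frame(x)
  df$ks_up <- round(df$ks_up, 3); df$ks_down <- round(df$ks_down, 3)
  df$score <- round(df$score, 3); df$tau <- round(df$tau, 1)
  df$p_perm <- signif(df$p_perm, 3)
  print(utils::head(df[order(df$tau), c("perturbagen", "ks_up", "ks_down",
                                        "score", "p_perm", "tau")], 10),
        row.names = FALSE)
  invisible(x)
}

#' Read / write perturbation profile collections as TSV
#'
#' The TSV has columns `perturbagen`, `probe`, `gene`, `z`, `probe_class`;
#' one collection file holds many profiles.
#'
#' @param path File path.
#' @return [read_profiles()] returns a named list of
#'   [perturbation_profile]s.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path))
    pls_error(sprintf("profile file not found: %s", path), "plsassay_input_error")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("perturbagen", "probe", "gene", "z", "probe_class")
  if (!all(need %in% names(tab)))
    pls_error(sprintf("profile TSV needs columns: %s", paste(need, collapse = ", ")),
              "plsassay_parse_error")
  ids <- unique(tab$perturbagen)
  out <- lapply(ids, function(id)
    perturbation_profile(id, tab[tab$perturbagen == id,
                                 c("probe", "gene", "z", "probe_class")]))
  names(out) <- ids
  out
}

#' @rdname read_profiles
#' @param profiles Named list of `perturbation_profile`s.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "perturbation_profile")) profiles <- list(profiles)
  tabs <- lapply(profiles, function(p)
    data.frame(perturbagen = p$id, p$probes, stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
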