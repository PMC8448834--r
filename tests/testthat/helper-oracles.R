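# Independent brute-force oracles, deliberately written as slow,
# position-by-position re-derivations so they share no code path with the
# package internals they check.

# Running-sum enrichment score: walk every rank, accumulate, take the
# extreme of largest magnitude (positive wins ties).
oracle_es <- function(ranked_genes, metric, set_genes, weight_p) {
  N <- length(ranked_genes)
  hits <- ranked_genes %in% set_genes
  NR <- sum(abs(metric[hits])^weight_p)
  NH <- sum(hits)
  rs <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- if (hits[i]) {
      if (NR > 0) acc + abs(metric[i])^weight_p / NR else acc + 1 / NH
    } else acc - 1 / (N - NH)
    rs[i] <- acc
  }
  mx <- max(rs); mn <- min(rs)
  if (mx >= -mn - 1e-9) mx else mn   # positive wins magnitude ties
}

# Connectivity-map KS statistic by explicit loops over j.
oracle_ks <- function(n, V) {
  t <- length(V)
  a <- -Inf; b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - V[j] / n)
    b <- max(b, V[j] / n - (j - 1) / t)
  }
  if (a >= b) a else -b
}

# Pooled-null FDR q for one observed NES, re-derived from the definition:
# every null ES normalized by its own set's same-sign null mean, pooled,
# then the ratio of null to observed tail fractions, clamped.
oracle_pooled_fdr <- function(obs_nes, nulls_list, idx) {
  pooled <- c()
  for (nv in nulls_list) {
    pos <- nv[nv >= 0]; neg <- nv[nv < 0]
    if (length(pos) && mean(pos) > 0) pooled <- c(pooled, pos / mean(pos))
    if (length(neg)) pooled <- c(pooled, neg / mean(abs(neg)))
  }
  nes <- obs_nes[idx]
  if (nes >= 0) {
    num <- sum(pooled >= nes) / sum(pooled >= 0)
    den <- sum(obs_nes >= nes) / max(1, sum(obs_nes >= 0))
  } else {
    num <- sum(pooled <= nes) / sum(pooled < 0)
    den <- sum(obs_nes <= nes) / max(1, sum(obs_nes < 0))
  }
  q <- if (is.finite(den) && den > 0) num / den else 1
  min(1, max(q, 1 / (length(nulls_list[[idx]]) + 1)))
}

# small deterministic count matrix with named conditions
toy_matrix <- function(values, genes, samples, scale = "counts",
                       condition = NULL) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  meta <- if (!is.null(condition))
    data.frame(sample_id = samples, condition = condition)
  expr_matrix(m, scale = scale, sample_meta = meta)
}

# a tiny disjoint signature over an alphabet universe
toy_signature <- function() {
  build_signature(gene_set("poor", c("P1", "P2", "P3")),
                  gene_set("good", c("G1", "G2", "G3")),
                  gene_set("housekeeping", c("H1", "H2")))
}

# random preranked list of size N over synthetic gene ids
random_ranked_list <- function(N) {
  ranked_list(sprintf("g%04d", seq_len(N)), stats::rnorm(N))
}
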