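test_that("top- and bottom-packed sets reach the analytic extremes at weight 0", {
  rl <- ranked_list(sprintf("g%02d", 1:20), seq(10, -9))
  top <- enrichment_score(rl, rl$genes[1:4], weight_p = 0)
  expect_equal(top$ES, 1)
  expect_equal(top$leading_edge, rl$genes[1:4])
  bottom <- enrichment_score(rl, rl$genes[17:20], weight_p = 0)
  expect_equal(bottom$ES, -1)
  expect_equal(sort(bottom$leading_edge), sort(rl$genes[17:20]))
})

test_that("a stated small instance matches the brute-force running-sum oracle", {
  metric <- c(5, 4, 3, 2.5, 2, 1.5, 1, 0.5, 0.25, 0.1)
  rl <- ranked_list(paste0("g", 1:10), metric)
  set <- c("g1", "g4")   # hits at ranks 1 and 4
  for (p in c(0, 1)) {
    got <- enrichment_score(rl, set, weight_p = p)
    expect_equal(got$ES, oracle_es(rl$genes, rl$metric, set, p),
                 tolerance = 1e-12)
    expect_length(got$running_sum, 10)
  }
})

test_that("the engine equals the brute-force oracle over random instances", {
  set.seed(42)
  worst <- 0
  for (i in 1:300) {
    N <- sample(10:200, 1)
    rl <- random_ranked_list(N)
    k <- sample(1:min(20, N - 1), 1)
    set <- sample(rl$genes, k)
    p <- sample(c(0, 1), 1)
    got <- enrichment_score(rl, set, weight_p = p)$ES
    worst <- max(worst, abs(got - oracle_es(rl$genes, rl$metric, set, p)))
  }
  expect_lt(worst, 1e-12)
})

test_that("the weighted statistic agrees with an established independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(7)
  for (i in 1:20) {
    rl <- random_ranked_list(80)
    set <- sample(rl$genes, 12)
    ours <- enrichment_score(rl, set, weight_p = 1)$ES
    ref <- fgsea::calcGseaStat(stats::setNames(unname(rl$metric), rl$genes),
                               selectedStats = which(rl$genes %in% set),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("ES shift invariance holds only for the unweighted statistic", {
  rl <- ranked_list(paste0("g", 1:30), seq(3, -2.8, length.out = 30))
  shifted <- ranked_list(paste0("g", 1:30), seq(3, -2.8, length.out = 30) + 10)
  set <- c("g2", "g7", "g8", "g20")
  expect_equal(enrichment_score(rl, set, 0)$ES,
               enrichment_score(shifted, set, 0)$ES, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(enrichment_score(rl, set, 1)$ES,
                                enrichment_score(shifted, set, 1)$ES)))
})

test_that("reversing the ranked list negates the unweighted ES", {
  set.seed(13)
  for (i in 1:25) {
    rl <- random_ranked_list(60)
    rev_rl <- ranked_list(rl$genes, -unname(rl$metric))
    set <- sample(rl$genes, 8)
    expect_equal(enrichment_score(rev_rl, set, 0)$ES,
                 -enrichment_score(rl, set, 0)$ES, tolerance = 1e-12)
  }
})

test_that("degenerate set overlaps are rejected", {
  rl <- ranked_list(paste0("g", 1:10), 10:1)
  expect_error(enrichment_score(rl, c("absent1", "absent2")),
               class = "plsassay_coverage_error")
  expect_error(enrichment_score(rl, rl$genes), "whole")
})

test_that("null distributions are seeded, sized, and centred", {
  rl <- ranked_list(paste0("g", 1:100), seq(2, -2, length.out = 100))
  p <- enrichment_params(n_perm = 1000, seed = 99)
  n1 <- null_distribution(rl, 10, p)
  n2 <- null_distribution(rl, 10, p)
  expect_identical(n1, n2)
  expect_length(n1, 1000)
  # symmetric metric: null ES mean within 3 standard errors of 0
  expect_lt(abs(mean(n1)), 3 * sd(n1) / sqrt(length(n1)))
})

test_that("phenotype-mode nulls require a context and are reproducible", {
  set.seed(21)
  v <- matrix(rnorm(50 * 6, 8), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  m <- expr_matrix(v, "log2")
  rl <- rank_by_phenotype(m, paste0("s", 1:3), paste0("s", 4:6))
  p <- enrichment_params(n_perm = 100, seed = 5, perm_mode = "phenotype")
  expect_error(null_distribution(rl, 5, p), "context")
  ctx <- list(matrix = m, case = paste0("s", 1:3), ref = paste0("s", 4:6),
              genes = paste0("g", 1:5))
  expect_identical(null_distribution(rl, 5, p, ctx),
                   null_distribution(rl, 5, p, ctx))
})

test_that("NES and nominal p follow their defining conventions", {
  obs <- list(list(set_name = "s", ES = 0.5, leading_edge = "a", n_hits = 3))
  res <- nes_and_fdr(obs, list(rep(0.5, 200)))
  expect_equal(res$NES, 1)
  expect_equal(res$p_nominal, 1)

  nulls <- list(c(runif(150, 0, 0.3), -runif(50, 0, 0.3)))
  res2 <- nes_and_fdr(list(list(set_name = "s", ES = 0.9, leading_edge = "a",
                                n_hits = 3)), nulls)
  expect_equal(res2$p_nominal, 1 / (1 + 150))   # exceeds every same-sign null
  expect_equal(res2$NES, 0.9 / mean(nulls[[1]][nulls[[1]] >= 0]))

  degen <- nes_and_fdr(list(list(set_name = "s", ES = -0.4, leading_edge = "a",
                                 n_hits = 2)), list(runif(100, 0, 1)))
  expect_true(degen$degenerate)
  expect_equal(degen$p_nominal, 1)
  expect_true(is.na(degen$NES))
})

test_that("pooled FDR equals an independently coded oracle on a two-set toy", {
  set.seed(31)
  obs <- list(list(set_name = "A", ES = 0.62, leading_edge = "a", n_hits = 5),
              list(set_name = "B", ES = -0.48, leading_edge = "b", n_hits = 7))
  nulls <- list(rnorm(200, 0, 0.25), rnorm(200, 0, 0.25))
  res <- nes_and_fdr(obs, nulls)
  for (i in 1:2)
    expect_equal(res$fdr_q[i], oracle_pooled_fdr(res$NES, nulls, i),
                 tolerance = 1e-12)
  expect_true(all(res$fdr_q >= 1 / 201 & res$fdr_q <= 1))
})

test_that("gsea recovers planted up- and down-shifted sets with correct signs", {
  set.seed(55)
  genes <- paste0("g", 1:300)
  up_set <- paste0("g", 1:15); down_set <- paste0("g", 286:300)
  metric <- rnorm(300, 0, 0.3)
  names(metric) <- genes
  metric[up_set] <- metric[up_set] + 2
  metric[down_set] <- metric[down_set] - 2
  rl <- ranked_list(genes, unname(metric))
  res <- gsea(rl, list(up = up_set, down = down_set),
              enrichment_params(n_perm = 200, seed = 2))
  expect_gt(res$NES[res$set == "up"], 0)
  expect_lt(res$NES[res$set == "down"], 0)
  expect_true(all(res$fdr_q < 0.25))
  # repeated run with the same seed is identical
  res2 <- gsea(rl, list(up = up_set, down = down_set),
               enrichment_params(n_perm = 200, seed = 2))
  expect_identical(as.data.frame(res), as.data.frame(res2))
  expect_error(gsea(rl, list(none = c("zz1", "zz2")),
                    enrichment_params(n_perm = 100, seed = 1)),
               class = "plsassay_coverage_error")
})

test_that("gsea under a permuted-label null is calibrated at the 0.25 convention", {
  set.seed(77)
  n_sig <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    v <- matrix(rnorm(120 * 6, 8, 1), 120, 6,
                dimnames = list(paste0("g", 1:120), paste0("x", 1:6)))
    m <- expr_matrix(v, "log2")
    res <- gsea(m, list(s1 = paste0("g", 1:12)),
                enrichment_params(n_perm = 100, seed = s),
                case = paste0("x", 1:3), ref = paste0("x", 4:6))
    if (res$fdr_q < 0.25) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / n_seeds, 0.35)
})

test_that("enrichment result tables serialize to TSV", {
  rl <- ranked_list(paste0("g", 1:50), seq(2, -2, length.out = 50))
  res <- gsea(rl, list(s = paste0("g", 1:5)),
              enrichment_params(n_perm = 100, seed = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gsea_tsv(res, path)
  back <- read.delim(path)
  expect_equal(back$set, "s")
  expect_equal(back$ES, res$ES, tolerance = 1e-6)
  expect_true(nzchar(back$leading_edge))
})
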