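test_that("global status applies the delta and alpha rules", {
  poor <- list(NES = 2.0, fdr_q = 0.01); good <- list(NES = -1.5, fdr_q = 0.02)
  gs <- global_status(poor, good, 0.25)
  expect_equal(gs$label, "poor")
  expect_equal(gs$delta, 3.5)

  mirrored <- global_status(list(NES = -1.5, fdr_q = 0.02),
                            list(NES = 2.0, fdr_q = 0.01), 0.25)
  expect_equal(mirrored$label, "good")
  expect_equal(mirrored$delta, -3.5)

  ns <- global_status(list(NES = 2.0, fdr_q = 0.5),
                      list(NES = -1.5, fdr_q = 0.5), 0.25)
  expect_equal(ns$label, "indeterminate")
})

test_that("heatmap encoding is the signed log10 FDR with clamping", {
  expect_equal(heatmap_encode(list(NES = 1.2, fdr_q = 0.01)), 2.0)
  expect_equal(heatmap_encode(list(NES = 0.8, fdr_q = 1)), 0)
  # q clamped at the permutation floor 1/1001
  enc <- heatmap_encode(list(NES = -2, fdr_q = 0), floor = 1 / 1001)
  expect_equal(enc, -log10(1 / 1001) * -1)
  expect_equal(enc, -3.000434, tolerance = 1e-6)
})

test_that("a simulated injury is classified poor and a null split indeterminate", {
  b <- simulate_bulk(sim_config(seed = 4, n_background = 300, n_poor = 40,
                                n_good = 40))
  p <- enrichment_params(n_perm = 200, seed = 2)
  st <- assess_pls(b$injured, b$mock, b$signature, params = p)
  expect_s3_class(st, "pls_status")
  expect_equal(st$global_label, "poor")
  expect_gt(st$delta, 0)
  expect_true(st$poor$fdr_q < 0.25 && st$good$fdr_q < 0.25)
  expect_equal(st$delta, st$poor$NES - st$good$NES)

  # reference = case: every metric is ~0, so the label must be indeterminate
  same <- assess_pls(b$mock, b$mock, b$signature, params = p)
  expect_equal(same$global_label, "indeterminate")
})

test_that("coverage below the threshold raises a coverage error", {
  b <- simulate_bulk(sim_config(seed = 4, n_background = 50, n_poor = 10,
                                n_good = 10))
  keep <- setdiff(gene_ids(b$injured), b$signature$poor$genes[1:8])
  expect_error(assess_pls(b$injured[keep, ], b$mock[keep, ], b$signature,
                          params = enrichment_params(n_perm = 100, seed = 1)),
               class = "plsassay_coverage_error")
})

test_that("swapping case and reference mirrors the unweighted classification", {
  b <- simulate_bulk(sim_config(seed = 8, n_background = 300, n_poor = 40,
                                n_good = 40))
  p <- enrichment_params(n_perm = 200, seed = 3, weight_p = 0)
  fwd <- assess_pls(b$injured, b$mock, b$signature, params = p)
  bwd <- assess_pls(b$mock, b$injured, b$signature, params = p)
  expect_equal(fwd$global_label, "poor")
  expect_equal(bwd$global_label, "good")
  expect_lt(bwd$delta, 0)
})

test_that("reversal assessment follows the one-sided direction rule", {
  cfg <- sim_config(seed = 12, n_background = 300, n_poor = 40, n_good = 40,
                    screen = list(n_compounds = 3, n_reversers = 1,
                                  reversal_strength = 1.5))
  scr <- simulate_screen(cfg)
  p <- enrichment_params(n_perm = 200, seed = 5)
  rev_st <- assess_reversal(scr$arms$cmpd01, scr$control, scr$signature, params = p)
  expect_true(rev_st$reversal)
  expect_true(rev_st$poor$NES < 0 || rev_st$good$NES > 0)

  null_st <- assess_reversal(scr$arms$cmpd03, scr$control, scr$signature, params = p)
  expect_false(isTRUE(null_st$reversal) &&
                 null_st$poor$fdr_q < 0.05 && null_st$good$fdr_q < 0.05)

  # treated arm identical to control replicates: never a hit
  same <- assess_reversal(scr$control, scr$control, scr$signature, params = p)
  expect_false(same$reversal)
})

test_that("screens rank planted reversers first and report the designed hit rate", {
  cfg <- sim_config(seed = 3, n_background = 200, n_poor = 30, n_good = 30,
                    screen = list(n_compounds = 8, n_reversers = 3,
                                  reversal_strength = 1.5))
  scr <- simulate_screen(cfg)
  p <- enrichment_params(n_perm = 200, seed = 7)
  res <- run_screen(scr$arms, scr$control, scr$signature, params = p)
  expect_s3_class(res, "pls_screen")
  expect_setequal(res$table$rank, seq_len(8))
  top3 <- res$table$compound[res$table$rank <= 3]
  expect_setequal(top3, scr$truth$reversers)
  expect_true(all(res$table$hit[res$table$compound %in% scr$truth$reversers]))
  expect_equal(res$summary$hit_rate,
               res$summary$n_hits / res$summary$n_compounds)
  # all hits are significant reversals by definition
  for (id in res$table$compound[res$table$hit])
    expect_true(res$statuses[[id]]$reversal)

  # determinism given seed and input order
  res2 <- run_screen(scr$arms, scr$control, scr$signature, params = p)
  expect_identical(res$table, res2$table)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen_tsv(res, path)
  expect_equal(nrow(read.delim(path)), 8)
})

test_that("hit sensitivity is monotone non-decreasing in reversal strength", {
  strengths <- c(0.3, 0.8, 1.5)
  hit_frac <- numeric(3)
  p <- enrichment_params(n_perm = 100, seed = 1)
  for (k in seq_along(strengths)) {
    hits <- 0; total <- 0
    for (s in 1:6) {
      cfg <- sim_config(seed = 1000 + s, n_background = 150, n_poor = 25,
                        n_good = 25,
                        screen = list(n_compounds = 2, n_reversers = 2,
                                      reversal_strength = strengths[k]))
      scr <- simulate_screen(cfg)
      res <- run_screen(scr$arms, scr$control, scr$signature, params = p)
      hits <- hits + sum(res$table$hit)
      total <- total + 2
    }
    hit_frac[k] <- hits / total
  }
  expect_true(all(diff(hit_frac) >= -1e-9))
  expect_gt(hit_frac[3], 0.9)
})
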