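test_that("generators are pure functions of the configuration seed", {
  cfg <- sim_config(seed = 5, n_background = 100, n_poor = 15, n_good = 15,
                    screen = list(n_compounds = 4, n_reversers = 2),
                    cells = list(n_cells = 12, n_cell_background = 20),
                    profiles = list(n_perturbagens = 4, n_genes = 80,
                                    n_multi_probe = 10))
  expect_identical(simulate_bulk(cfg)$matrix$values,
                   simulate_bulk(cfg)$matrix$values)
  expect_identical(simulate_screen(cfg)$arms$cmpd02$values,
                   simulate_screen(cfg)$arms$cmpd02$values)
  expect_identical(simulate_cells(cfg)$counts$values,
                   simulate_cells(cfg)$counts$values)
  expect_identical(simulate_perturbation_reference(cfg)$profiles$pert01$probes,
                   simulate_perturbation_reference(cfg)$profiles$pert01$probes)
  # and differ across seeds
  cfg2 <- sim_config(seed = 6, n_background = 100, n_poor = 15, n_good = 15)
  expect_false(identical(simulate_bulk(cfg)$matrix$values[1:5, 1],
                         simulate_bulk(cfg2)$matrix$values[1:5, 1]))
})

test_that("unknown nested configuration keys are rejected", {
  expect_error(sim_config(screen = list(n_compunds = 3)),
               "n_compunds", class = "plsassay_config_error")
  expect_error(sim_config(cells = list(nope = 1)),
               class = "plsassay_config_error")
})

test_that("bulk truth matches the construction and housekeeping genes carry no effect", {
  cfg <- sim_config(seed = 9, n_background = 150, n_poor = 20, n_good = 20)
  b <- simulate_bulk(cfg)
  expect_setequal(b$truth$affected$gene,
                  c(b$signature$poor$genes, b$signature$good$genes))
  expect_false(any(b$signature$housekeeping$genes %in% b$truth$affected$gene))
  lg <- log2(b$matrix$values + 0.5)
  shift <- rowMeans(lg[, 4:6]) - rowMeans(lg[, 1:3])
  # signature genes shift in the designed directions ...
  expect_gt(mean(shift[b$signature$poor$genes]), 1.0)
  expect_lt(mean(shift[b$signature$good$genes]), -1.0)
  # ... housekeeping genes do not (their shift is library noise only)
  expect_lt(abs(mean(shift[b$signature$housekeeping$genes])), 0.75)
})

test_that("a zero-effect design leaves signature genes centred at no change", {
  cfg <- sim_config(seed = 14, n_background = 150, n_poor = 25, n_good = 25,
                    delta_poor = 0, delta_good = 0, library_sd = 0)
  b <- simulate_bulk(cfg)
  lg <- log2(b$matrix$values + 0.5)
  shift <- rowMeans(lg[, 4:6]) - rowMeans(lg[, 1:3])
  sig_genes <- c(b$signature$poor$genes, b$signature$good$genes)
  se <- sd(shift[sig_genes]) / sqrt(length(sig_genes))
  expect_lt(abs(mean(shift[sig_genes])), 3 * se + 0.05)
})

test_that("screen arms realize the planted shifts and nulls match the control", {
  cfg <- sim_config(seed = 21, n_background = 150, n_poor = 25, n_good = 25,
                    screen = list(n_compounds = 4, n_reversers = 1,
                                  reversal_strength = 1.5))
  scr <- simulate_screen(cfg)
  lg <- function(m) log2(m$values + 0.5)
  rev_shift <- rowMeans(lg(scr$arms$cmpd01)) - rowMeans(lg(scr$control))
  expect_equal(mean(rev_shift[scr$signature$poor$genes]), -1.5, tolerance = 0.45)
  expect_equal(mean(rev_shift[scr$signature$good$genes]), 1.5, tolerance = 0.45)
  # non-reverser arms are distributionally identical to the control; the
  # pooled KS check is itself stochastic, so require it over most seeds
  nonsig <- 0
  for (s in 1:8) {
    sc <- simulate_screen(sim_config(seed = 500 + s, n_background = 150,
                                     n_poor = 25, n_good = 25,
                                     screen = list(n_compounds = 2,
                                                   n_reversers = 1)))
    pv <- suppressWarnings(ks.test(as.vector(lg(sc$arms$cmpd02)),
                                   as.vector(lg(sc$control)))$p.value)
    if (pv > 0.01) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 6)
})

test_that("simulated cells honour the infection design and correlation target", {
  cfg <- sim_config(seed = 2)
  sim <- simulate_cells(cfg)
  good_cells <- sprintf("cell%02d", 1:40)
  vl <- sim$viral_load[good_cells]
  expect_equal(sum(vl > 0), sim$truth$n_infected)
  expect_equal(sim$truth$n_infected, 23)  # 23/40 infected fraction
  uninfected <- setdiff(good_cells, sim$truth$infected)
  expect_true(all(sim$viral_load[uninfected] == 0))

  # realized mean poor-set expression correlation near the design target,
  # averaged over seeds to tame the n = 40 sampling noise of r
  rs <- vapply(1:8, function(s) {
    sc <- simulate_cells(sim_config(seed = 300 + s))
    g <- sprintf("cell%02d", 1:40)
    lg <- log2(sc$counts$values[sc$signature$poor$genes, g] + 1)
    cor(colMeans(lg), sc$viral_load[g])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.15)
})

test_that("planted QC failures are flagged in truth and removed by the filters", {
  sim <- simulate_cells(sim_config(seed = 11))
  p <- cell_qc_params()
  kept <- filter_cells_alignment(sim$stats, p)
  expect_false(sim$truth$qc_fail_cells$low_align %in% kept)
  filtered <- filter_cells_counts(sim$counts[, intersect(sample_ids(sim$counts),
                                                         kept)], p)
  rem <- attr(filtered, "removed")
  expect_true(sim$truth$qc_fail_cells$low_total %in% rem$low_total)
  expect_true(sim$truth$qc_fail_cells$high_mito %in% rem$high_mito)
  # no healthy cell is lost to the cell filters
  expect_setequal(sample_ids(filtered), sprintf("cell%02d", 1:40))

  gene_filtered <- filter_artifact_and_rare_genes(filtered, p)
  grem <- attr(gene_filtered, "removed")
  expect_true(all(sim$truth$qc_fail_genes$artifact_correlated %in%
                    grem$artifact_correlated))
  expect_true(all(sim$truth$qc_fail_genes$rare %in% grem$rare))
  # signature genes survive, allowing for the small chance-correlation
  # leakage inherent to a 0.4 Pearson cut at 40 cells
  planted <- unlist(sim$truth$qc_fail_genes)
  false_gene_removals <- setdiff(unlist(grem), planted)
  expect_lte(length(false_gene_removals), 6)
})

test_that("the perturbation reference plants a recoverable reverser", {
  recovered <- 0
  for (s in 1:5) {
    sim <- simulate_perturbation_reference(sim_config(seed = 400 + s))
    res <- connectivity_score(sim$profiles,
                              query_signature(sim$signature$poor,
                                              sim$signature$good),
                              n_perm = 300, seed = s)
    if (res$perturbagen[which.min(res$tau)] == sim$truth$reverser)
      recovered <- recovered + 1
    if (s == 1) {
      null_scores <- res$s_raw[res$perturbagen != sim$truth$reverser]
      expect_lt(abs(mean(null_scores)),
                3 * sd(null_scores) / sqrt(length(null_scores)) + 0.05)
    }
  }
  expect_gte(recovered, 4)
})
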