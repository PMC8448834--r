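test_that("probe collapse prioritizes landmark probes then absolute z", {
  p <- perturbation_profile("c1", data.frame(
    probe = c("p1", "p2", "p3", "p4", "p5", "p6"),
    gene = c("A", "A", "B", "B", "C", "D"),
    z = c(0.5, 3.0, -2.5, 1.0, 4.4, 0.1),
    probe_class = c("landmark", "inferred", "inferred", "inferred",
                    "landmark", "inferred")))
  g <- collapse_probes(p)
  expect_equal(g$z[g$gene == "A"], 0.5)      # landmark beats larger inferred z
  expect_equal(g$z[g$gene == "B"], -2.5)     # highest |z| among inferred
  expect_equal(g$z[g$gene == "C"], 4.4)      # single effective probe
  expect_equal(g$z[g$gene == "D"], 0.1)
  expect_equal(nrow(g), 4)

  # |z| ties break by probe id ascending
  tie <- collapse_probes(perturbation_profile("c2", data.frame(
    probe = c("pB", "pA"), gene = c("E", "E"), z = c(2, -2),
    probe_class = "inferred")))
  expect_equal(tie$probe, "pA")
})

test_that("target signatures use top/bottom k with the overlap guard", {
  prof <- data.frame(gene = sprintf("g%03d", 1:500), z = seq(5, -5, length.out = 500))
  q <- extract_target_signature(prof, k = 100)
  expect_length(q$up$genes, 100)
  expect_length(q$down$genes, 100)
  expect_equal(q$up$genes[1], "g001")

  small <- data.frame(gene = sprintf("g%03d", 1:150), z = rnorm(150))
  q2 <- extract_target_signature(small, k = 100)
  expect_length(q2$up$genes, 75)
  expect_length(q2$down$genes, 75)
  expect_length(intersect(q2$up$genes, q2$down$genes), 0)

  q3 <- extract_target_signature(prof, k = 1)
  expect_equal(q3$up$genes, prof$gene[which.max(prof$z)])
  expect_equal(q3$down$genes, prof$gene[which.min(prof$z)])
  expect_error(extract_target_signature(prof[1, , drop = FALSE]))
})

test_that("ks_tag matches its closed forms and the brute-force maximization", {
  for (n in c(20, 57)) for (t in c(3, 10)) {
    expect_equal(ks_tag(n, 1:t), 1 - t / n)  # tags packed on top
    # tags packed at the bottom: the statistic is asymmetric because the
    # down-step term uses (j-1)/t, so the mirror extreme is 1 - (t-1)/n
    expect_equal(ks_tag(n, (n - t + 1):n), -(1 - (t - 1) / n))
  }
  set.seed(17)
  for (i in 1:300) {
    n <- sample(5:100, 1)
    t <- sample(1:min(20, n - 1), 1)
    V <- sort(sample.int(n, t))
    expect_identical(ks_tag(n, V), oracle_ks(n, V))
  }
  expect_error(ks_tag(10, c(3, 3)))
  expect_error(ks_tag(10, 1:10))
})

test_that("self-query scores +1, the mirrored profile -1, and same-sign pairs 0", {
  set.seed(23)
  genes <- sprintf("g%03d", 1:200)
  z <- seq(4, -4, length.out = 200) + rnorm(200, 0, 0.1)
  mk <- function(id, zz) perturbation_profile(id, data.frame(
    probe = paste0(id, "_", seq_along(genes)), gene = genes, z = zz,
    probe_class = "landmark"))
  self <- mk("self", z)
  mirror <- mk("mirror", -z)
  rand <- lapply(1:5, function(i) mk(paste0("r", i), rnorm(200)))
  q <- extract_target_signature(collapse_probes(self), k = 20)
  res <- connectivity_score(c(list(self, mirror), rand), q,
                            n_perm = 200, seed = 9)
  expect_equal(res$score[res$perturbagen == "self"], 1)
  expect_equal(res$score[res$perturbagen == "mirror"], -1)
  expect_true(all(res$score >= -1 & res$score <= 1))
  # raw score is zero whenever both KS statistics share a sign
  expect_true(all(res$s_raw[sign(res$ks_up) == sign(res$ks_down) &
                              res$ks_up != 0 & res$ks_down != 0] == 0))
  expect_true(all(abs(res$tau) <= 100))
  expect_equal(res$tau[res$perturbagen == "self"], 100)
  expect_equal(res$tau[res$perturbagen == "mirror"], -100)
})

test_that("tau percentile follows the signed rank convention", {
  bg <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  expect_equal(tau_percentile(-2, bg), -100)
  expect_equal(tau_percentile(0, bg), 0)
  # |score| at the empirical median: |tau| = 50 within one rank unit
  expect_lt(abs(abs(tau_percentile(0.5, bg)) - 50), 100 / length(bg) + 1e-9)
  # antisymmetry under sign flip with a sign-symmetric background
  bg2 <- c(bg, -bg)
  expect_equal(tau_percentile(-0.45, bg2), -tau_percentile(0.45, bg2))
})

test_that("candidate selection applies the published thresholds", {
  res <- data.frame(perturbagen = c("a", "b", "c", "d"),
                    score = c(-0.8, -0.8, 0.5, -0.2),
                    p_perm = c(0.01, 0.2, 0.01, 0.04),
                    tau = c(-95, -50, 20, -91))
  expect_equal(select_candidates(res, "cmap"), c("a", "d"))
  expect_equal(select_candidates(res, "lincs"), c("a", "d"))
  expect_false("b" %in% select_candidates(res, "cmap"))   # p too large
  expect_false("b" %in% select_candidates(res, "lincs"))  # tau above -90
})

test_that("profile collections round-trip through TSV", {
  sim <- simulate_perturbation_reference(
    sim_config(seed = 2, n_poor = 10, n_good = 10,
               profiles = list(n_perturbagens = 3, n_genes = 60,
                               n_multi_probe = 10)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(sim$profiles, path)
  back <- read_profiles(path)
  expect_named(back, names(sim$profiles))
  expect_equal(back$pert01$probes$z, sim$profiles$pert01$probes$z)
})

test_that("profiles sharing no query genes are skipped with a warning", {
  p <- perturbation_profile("lonely", data.frame(
    probe = "p1", gene = "ZZZ", z = 1, probe_class = "landmark"))
  q <- query_signature(c("A", "B"), c("C", "D"))
  expect_error(expect_warning(connectivity_score(list(p), q, n_perm = 50),
                              "skipped"),
               class = "plsassay_coverage_error")
})
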