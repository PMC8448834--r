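#' Simulation configuration for the synthetic-data generators
#'
#' Bundles every knob of the seeded generators. Defaults mirror the
#' reference assay designs: a 186-gene prognostic signature split evenly
#' into poor- and good-prognosis halves, six housekeeping genes, three
#' replicates per arm, injury effects of 1.5 log2 units on the signature
#' genes, a 25-compound screen containing 11 planted reversers, 40 cells
#' with a 23/40 infected fraction, and a 20-compound perturbation reference
#' with one planted signature reverser. All generators are pure functions
#' of this configuration (including its seed).
#'
#' @param seed Integer seed; fully determines every generator's output.
#' @param n_background Number of unaffected background genes (bulk).
#' @param n_poor,n_good Prognosis set sizes.
#' @param n_housekeeping Housekeeping set size (default 6).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-gene
#'   baseline log2 expression.
#' @param hk_log2_mean,hk_log2_sd Housekeeping baseline distribution
#'   (higher and tighter, as for stable normalizer genes).
#' @param sigma_noise Replicate noise sd on the log2 scale.
#' @param library_sd Per-sample log2 library-size offset sd (what
#'   housekeeping normalization removes).
#' @param delta_poor,delta_good Injury effect sizes in log2 units: poor
#'   genes shift up by `delta_poor`, good genes down by `delta_good`.
#' @param n_replicates Replicates per arm.
#' @param count_model `"lognormal_rounded"` (NanoString-like) or
#'   `"negative_binomial"` for overdispersed counts.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param screen List: `n_compounds`, `n_reversers` (or explicit
#'   `reverser_ids`), `reversal_strength` (log2 units).
#' @param cells List: `n_cells`, `infected_fraction`, `viral_meanlog`,
#'   `viral_sdlog`, `coupling_beta` (log2 shift per sd of viral load;
#'   the default 0.18 puts the design correlation between mean poor-set
#'   expression and viral load near 0.5), `cell_library_sd`, `n_mito`,
#'   `n_cell_background`, `artifact_gene`, `plant_qc_failures`.
#' @param profiles List: `n_perturbagens`, `n_genes`, `frac_landmark`,
#'   `n_multi_probe`, `reverser_strength`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_background = 800, n_poor = 93, n_good = 93,
                       n_housekeeping = 6,
                       baseline_log2_mean = 7, baseline_log2_sd = 1.5,
                       hk_log2_mean = 10, hk_log2_sd = 0.5,
                       sigma_noise = 0.5, library_sd = 0.2,
                       delta_poor = 1.5, delta_good = 1.5,
                       n_replicates = 3,
                       count_model = c("lognormal_rounded", "negative_binomial"),
                       nb_dispersion = 0.1,
                       screen = list(), cells = list(), profiles = list()) {
  count_model <- match.arg(count_model)
  screen_def <- list(n_compounds = 25L, n_reversers = 11L,
                     reverser_ids = NULL, reversal_strength = 1.5)
  cells_def <- list(n_cells = 40L, infected_fraction = 23 / 40,
                    viral_meanlog = 2, viral_sdlog = 1,
                    coupling_beta = 0.18, cell_library_sd = 0.3,
                    n_mito = 10L, n_cell_background = 50L,
                    artifact_gene = TRUE, plant_qc_failures = TRUE)
  profiles_def <- list(n_perturbagens = 20L, n_genes = 500L,
                       frac_landmark = 0.5, n_multi_probe = 100L,
                       reverser_strength = 3)
  merge_cfg <- function(def, user, what) {
    bad <- setdiff(names(user), names(def))
    if (length(bad))
      pls_error(sprintf("unknown %s config key(s): %s", what,
                        paste(bad, collapse = ", ")), "plsassay_config_error")
    utils::modifyList(def, user)
  }
  screen <- merge_cfg(screen_def, screen, "screen")
  cells <- merge_cfg(cells_def, cells, "cells")
  profiles <- merge_cfg(profiles_def, profiles, "profiles")
  if (is.null(screen$reverser_ids))
    screen$reverser_ids <- sprintf("cmpd%02d", seq_len(screen$n_reversers))
  stopifnot(n_background > 0, n_poor > 0, n_good > 0, n_housekeeping > 0,
            sigma_noise >= 0, n_replicates >= 1,
            cells$infected_fraction > 0, cells$infected_fraction <= 1)
  structure(list(seed = as.integer(seed), n_background = n_background,
                 n_poor = n_poor, n_good = n_good,
                 n_housekeeping = n_housekeeping,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 hk_log2_mean = hk_log2_mean, hk_log2_sd = hk_log2_sd,
                 sigma_noise = sigma_noise, library_sd = library_sd,
                 delta_poor = delta_poor, delta_good = delta_good,
                 n_replicates = n_replicates, count_model = count_model,
                 nb_dispersion = nb_dispersion,
                 screen = screen, cells = cells, profiles = profiles),
            class = "sim_config")
}

#' The prognostic signature of a simulation configuration
#'
#' @param config A [sim_config].
#' @return A `prognostic_signature` over the generator's gene universe.
#' @export
sim_signature <- function(config) {
  build_signature(gene_set("poor", sprintf("PPG%03d", seq_len(config$n_poor))),
                  gene_set("good", sprintf("GPG%03d", seq_len(config$n_good))),
                  gene_set("housekeeping",
                           sprintf("HK%d", seq_len(config$n_housekeeping))))
}

# draw a count matrix from a log2 mean matrix under the configured model
emit_counts <- function(log2_mu, config) {
  mu <- 2^log2_mu
  counts <- if (config$count_model == "lognormal_rounded") round(mu)
  else matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
              nrow = nrow(mu), dimnames = dimnames(mu))
  dimnames(counts) <- dimnames(log2_mu)
  counts
}

# baseline log2 expression for the bulk gene universe; hk genes stable
bulk_baselines <- function(config) {
  sig <- sim_signature(config)
  genes <- c(sig$poor$genes, sig$good$genes, sig$housekeeping$genes,
             sprintf("BG%04d", seq_len(config$n_background)))
  base <- stats::rnorm(length(genes), config$baseline_log2_mean,
                       config$baseline_log2_sd)
  names(base) <- genes
  base[sig$housekeeping$genes] <- stats::rnorm(config$n_housekeeping,
                                               config$hk_log2_mean,
                                               config$hk_log2_sd)
  list(signature = sig, baselines = base)
}

# one arm: baseline + per-gene effect + sample library offsets + noise
draw_arm <- function(baselines, effect, sample_ids, config) {
  n <- length(sample_ids)
  lib <- stats::rnorm(n, 0, config$library_sd)
  log2_mu <- outer(baselines + effect, lib, `+`) +
    matrix(stats::rnorm(length(baselines) * n, 0, config$sigma_noise),
           nrow = length(baselines))
  dimnames(log2_mu) <- list(names(baselines), sample_ids)
  emit_counts(log2_mu, config)
}

#' Simulate a bulk injury experiment (mock and injured arms)
#'
#' Gene baselines are drawn once; the injured arm shifts poor-prognosis
#' genes up by `delta_poor` and good-prognosis genes down by `delta_good`
#' on the log2 scale. Housekeeping genes receive no condition effect, only
#' per-sample library offsets (which joint housekeeping normalization
#' removes). Replicate noise is `sigma_noise`; counts follow the configured
#' count model.
#'
#' @param config A [sim_config].
#' @return A list with `matrix` (merged [expr_matrix] with `condition`
#'   metadata `mock` / `injured`), `mock`, `injured` (the individual arms),
#'   `signature`, and a `truth` record (affected genes and effect sizes).
#' @export
simulate_bulk <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    bl <- bulk_baselines(config)
    sig <- bl$signature
    effect <- stats::setNames(numeric(length(bl$baselines)), names(bl$baselines))
    effect[sig$poor$genes] <- config$delta_poor
    effect[sig$good$genes] <- -config$delta_good
    mock_ids <- sprintf("mock_%d", seq_len(config$n_replicates))
    inj_ids <- sprintf("injured_%d", seq_len(config$n_replicates))
    mock <- draw_arm(bl$baselines, 0 * effect, mock_ids, config)
    injured <- draw_arm(bl$baselines, effect, inj_ids, config)
    meta <- data.frame(sample_id = c(mock_ids, inj_ids),
                       condition = rep(c("mock", "injured"),
                                       each = config$n_replicates))
    list(matrix = expr_matrix(cbind(mock, injured), "counts", meta),
         mock = expr_matrix(mock, "counts"),
         injured = expr_matrix(injured, "counts"),
         signature = sig,
         truth = list(affected = data.frame(
                        gene = c(sig$poor$genes, sig$good$genes),
                        delta_log2 = c(rep(config$delta_poor, config$n_poor),
                                       rep(-config$delta_good, config$n_good))),
                      delta_poor = config$delta_poor,
                      delta_good = config$delta_good,
                      seed = config$seed))
  })
}

#' Simulate a signature-reversal compound screen
#'
#' Builds an injured control arm and one treated arm per compound over a
#' shared baseline. Planted reverser arms shift poor genes down and good
#' genes up by `reversal_strength` relative to the control; the other arms
#' redraw control noise and are distributionally identical to it.
#'
#' @param config A [sim_config]; `config$screen` sets the design.
#' @return A list with `control` ([expr_matrix]), `arms` (named list of
#'   `expr_matrix`), `signature`, and `truth` (reverser ids and strength).
#' @export
simulate_screen <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sc <- config$screen
  ids <- sprintf("cmpd%02d", seq_len(sc$n_compounds))
  if (!all(sc$reverser_ids %in% ids))
    pls_error("reverser_ids must be a subset of the compound ids",
              "plsassay_config_error")
  with_seed(config$seed, {
    bl <- bulk_baselines(config)
    sig <- bl$signature
    injured_effect <- stats::setNames(numeric(length(bl$baselines)),
                                      names(bl$baselines))
    injured_effect[sig$poor$genes] <- config$delta_poor
    injured_effect[sig$good$genes] <- -config$delta_good
    reversal <- stats::setNames(numeric(length(bl$baselines)),
                                names(bl$baselines))
    reversal[sig$poor$genes] <- -sc$reversal_strength
    reversal[sig$good$genes] <- sc$reversal_strength
    control <- draw_arm(bl$baselines, injured_effect,
                        sprintf("ctrl_%d", seq_len(config$n_replicates)), config)
    arms <- lapply(ids, function(id) {
      eff <- injured_effect + if (id %in% sc$reverser_ids) reversal else 0
      expr_matrix(draw_arm(bl$baselines, eff,
                           sprintf("%s_%d", id, seq_len(config$n_replicates)),
                           config), "counts")
    })
    names(arms) <- ids
    list(control = expr_matrix(control, "counts"),
         arms = arms, signature = sig,
         truth = list(reversers = sc$reverser_ids,
                      non_reversers = setdiff(ids, sc$reverser_ids),
                      reversal_strength = sc$reversal_strength,
                      seed = config$seed))
  })
}

#' Simulate a single-cell infection experiment
#'
#' Generates a cells-by-genes count matrix over the signature genes plus
#' housekeeping, mitochondrial, background, and (optionally) artifact and
#' rare genes. A configured fraction of cells is infected and receives a
#' log-normal viral load (uninfected cells have exactly 0); poor-prognosis
#' gene expression is coupled to the standardized viral load with
#' coefficient `coupling_beta` and good-prognosis genes with
#' `-coupling_beta`. When `plant_qc_failures` is set, the output contains
#' one low-total cell, one high-mitochondrial cell, one low-alignment cell,
#' two artifact-correlated genes, and two rare genes, all flagged in the
#' truth record.
#'
#' @param config A [sim_config]; `config$cells` sets the design.
#' @return A list with `counts` ([expr_matrix] genes x cells), `stats`
#'   (per-cell data.frame: `cell`, `total_transcripts`, `mito_fraction`,
#'   `align_rate`, `aligned_pairs`, `viral_load`), `viral_load` (named
#'   vector), `signature`, and `truth` (infected ids, design correlation
#'   target, planted QC failures).
#' @export
simulate_cells <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cc <- config$cells
  with_seed(config$seed + 101L, {
    sig <- sim_signature(config)
    genes <- c(sig$poor$genes, sig$good$genes, sig$housekeeping$genes,
               sprintf("MT-G%02d", seq_len(cc$n_mito)),
               sprintf("CBG%03d", seq_len(cc$n_cell_background)))
    base <- stats::rnorm(length(genes), config$baseline_log2_mean,
                         config$baseline_log2_sd)
    names(base) <- genes
    base[sig$housekeeping$genes] <- stats::rnorm(config$n_housekeeping,
                                                 config$hk_log2_mean,
                                                 config$hk_log2_sd)
    cell_ids <- sprintf("cell%02d", seq_len(cc$n_cells))
    n_inf <- max(1L, round(cc$infected_fraction * cc$n_cells))
    infected <- sort(sample(cell_ids, n_inf))
    viral <- stats::setNames(numeric(cc$n_cells), cell_ids)
    viral[infected] <- stats::rlnorm(n_inf, cc$viral_meanlog, cc$viral_sdlog)
    zv <- as.numeric(scale(viral))
    coupling <- outer(stats::setNames(numeric(length(genes)), genes), zv, `*`)
    coupling[sig$poor$genes, ] <- cc$coupling_beta *
      matrix(zv, config$n_poor, cc$n_cells, byrow = TRUE)
    coupling[sig$good$genes, ] <- -cc$coupling_beta *
      matrix(zv, config$n_good, cc$n_cells, byrow = TRUE)
    lib <- stats::rnorm(cc$n_cells, 0, cc$cell_library_sd)
    log2_mu <- base + coupling +
      matrix(lib, length(genes), cc$n_cells, byrow = TRUE) +
      matrix(stats::rnorm(length(genes) * cc$n_cells, 0, config$sigma_noise),
             length(genes))
    dimnames(log2_mu) <- list(genes, cell_ids)
    counts <- emit_counts(log2_mu, config)
    truth_genes <- list(artifact_correlated = character(0), rare = character(0))
    truth_cells <- list(low_total = character(0), high_mito = character(0),
                        low_align = character(0))
    if (cc$artifact_gene) {
      art <- 2^(5 + stats::rnorm(ncol(counts), 0, 1.5))
      art_block <- rbind(KCNQ1OT1 = round(art),
                         ARTC1 = round(art * 2^stats::rnorm(ncol(counts), 0, 0.1)),
                         ARTC2 = round(art * 2^stats::rnorm(ncol(counts), 0, 0.1)))
      counts <- rbind(counts, art_block)
      truth_genes$artifact_correlated <- c("KCNQ1OT1", "ARTC1", "ARTC2")
    }
    if (cc$plant_qc_failures) {
      rare <- matrix(0, 2, ncol(counts),
                     dimnames = list(c("RARE1", "RARE2"), colnames(counts)))
      for (g in 1:2) rare[g, sample.int(ncol(counts), 4)] <- 3
      counts <- rbind(counts, rare)
      truth_genes$rare <- c("RARE1", "RARE2")
      # planted failing cells: drawn like a normal uninfected cell, then broken
      proto <- counts[, 1]
      low_total <- round(proto * 1200 / sum(proto))
      hi_mito <- proto
      mito_rows <- startsWith(rownames(counts), "MT-")
      hi_mito[mito_rows] <- round(9 * sum(proto[!mito_rows]) / sum(mito_rows))
      low_align <- counts[, 2]
      bad <- cbind(cell_lowT = low_total, cell_hiMito = hi_mito,
                   cell_lowA = low_align)
      counts <- cbind(counts, bad)
      viral <- c(viral, cell_lowT = 0, cell_hiMito = 0, cell_lowA = 0)
      truth_cells <- list(low_total = "cell_lowT", high_mito = "cell_hiMito",
                          low_align = "cell_lowA")
    }
    totals <- colSums(counts)
    mito_rows <- startsWith(rownames(counts), "MT-")
    mito_frac <- colSums(counts[mito_rows, , drop = FALSE]) / pmax(totals, 1)
    n_all <- ncol(counts)
    stats_df <- data.frame(
      cell = colnames(counts),
      total_transcripts = as.numeric(totals),
      mito_fraction = as.numeric(mito_frac),
      align_rate = stats::runif(n_all, 0.60, 0.95),
      aligned_pairs = round(stats::runif(n_all, 2e5, 1e6)),
      viral_load = as.numeric(viral[colnames(counts)]),
      stringsAsFactors = FALSE)
    if (cc$plant_qc_failures) {
      stats_df$align_rate[stats_df$cell == "cell_lowA"] <- 0.30
      stats_df$aligned_pairs[stats_df$cell == "cell_lowA"] <- 5e4
    }
    meta <- data.frame(sample_id = colnames(counts),
                       condition = ifelse(colnames(counts) %in% infected,
                                          "infected", "uninfected"))
    list(counts = expr_matrix(counts, "counts", meta),
         stats = stats_df,
         viral_load = stats::setNames(stats_df$viral_load, stats_df$cell),
         signature = sig,
         truth = list(infected = infected,
                      n_infected = length(infected),
                      design_r = 0.5,
                      coupling_beta = cc$coupling_beta,
                      qc_fail_cells = truth_cells,
                      qc_fail_genes = truth_genes,
                      seed = config$seed))
  })
}

#' Simulate a perturbation reference collection
#'
#' Generates per-compound differential z-score profiles over the signature
#' genes plus background. One planted reverser carries a z-profile
#' anti-correlated with the injury signature (poor genes strongly negative,
#' good genes strongly positive); all other profiles are standard-normal
#' noise. Probes carry landmark/inferred classes and a subset of genes gets
#' a decoy second probe, exercising the landmark-priority collapse rule.
#'
#' @param config A [sim_config]; `config$profiles` sets the design.
#' @return A list with `profiles` (named list of [perturbation_profile]s),
#'   `signature`, and `truth` (the reverser id).
#' @export
simulate_perturbation_reference <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  pc <- config$profiles
  if (pc$n_perturbagens < 2L) pls_error("need >= 2 perturbagens")
  with_seed(config$seed + 202L, {
    sig <- sim_signature(config)
    sig_genes <- c(sig$poor$genes, sig$good$genes)
    n_bg <- max(0L, pc$n_genes - length(sig_genes))
    genes <- c(sig_genes, sprintf("PBG%03d", seq_len(n_bg)))
    ids <- sprintf("pert%02d", seq_len(pc$n_perturbagens))
    reverser <- ids[1]
    classes <- ifelse(stats::runif(length(genes)) < pc$frac_landmark,
                      "landmark", "inferred")
    profiles <- lapply(ids, function(id) {
      z <- stats::rnorm(length(genes))
      if (id == reverser) {
        z[genes %in% sig$poor$genes] <- -pc$reverser_strength +
          stats::rnorm(sum(genes %in% sig$poor$genes), 0, 0.5)
        z[genes %in% sig$good$genes] <- pc$reverser_strength +
          stats::rnorm(sum(genes %in% sig$good$genes), 0, 0.5)
      }
      probes <- data.frame(probe = paste0(id, "_p", seq_along(genes)),
                           gene = genes, z = z, probe_class = classes,
                           stringsAsFactors = FALSE)
      if (pc$n_multi_probe > 0) {
        extra <- sample(seq_along(genes), min(pc$n_multi_probe, length(genes)))
        probes <- rbind(probes, data.frame(
          probe = paste0(id, "_q", extra),
          gene = genes[extra],
          z = stats::rnorm(length(extra)),
          probe_class = "inferred", stringsAsFactors = FALSE))
      }
      perturbation_profile(id, probes)
    })
    names(profiles) <- ids
    list(profiles = profiles, signature = sig,
         truth = list(reverser = reverser,
                      reverser_strength = pc$reverser_strength,
                      seed = config$seed))
  })
}
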