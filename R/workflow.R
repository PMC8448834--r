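#' Run configuration for the end-to-end workflows
#'
#' Validates a (possibly YAML-sourced) configuration list against a strict
#' schema: unknown keys are rejected so threshold typos cannot silently
#' revert to defaults. Defaults equal the assay's published conventions
#' (FDR significance 0.25, cmap p < 0.05, tau < -90, top-100 target
#' signatures).
#'
#' @param config A named list or a path to a YAML file.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      pls_error(sprintf("config file not found: %s", config), "plsassay_input_error")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    case = NULL, reference = NULL, control = NULL, arms = NULL,
    counts = NULL, cell_stats = NULL, signature = NULL, profiles_file = NULL,
    alpha = 0.25, weight_p = 1, n_perm = 1000,
    perm_mode = "gene_set", metric = "log2fc",
    coverage_min = 0.5, pseudocount = 0.5,
    connectivity_p = 0.05, connectivity_tau = -90, target_k = 100,
    qc = list(), simulate = list(), seed = 1, verbose = FALSE)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    pls_error(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
              "plsassay_config_error")
  cfg <- utils::modifyList(defaults, config)
  qc_known <- names(formals(cell_qc_params))
  bad_qc <- setdiff(names(cfg$qc), qc_known)
  if (length(bad_qc))
    pls_error(sprintf("unknown qc config key(s): %s", paste(bad_qc, collapse = ", ")),
              "plsassay_config_error")
  structure(cfg, class = "run_config")
}

# load a prognostic signature from a GMT/TSV with poor/good/housekeeping sets
load_signature <- function(path) {
  sets <- load_gene_sets(path)
  nm <- tolower(names(sets))
  pick <- function(key) {
    i <- grep(key, nm)
    if (!length(i)) pls_error(sprintf("signature file lacks a '%s' set", key),
                              "plsassay_input_error")
    sets[[i[1]]]
  }
  build_signature(pick("poor"), pick("good"), pick("house|hk"))
}

workflow_params <- function(cfg) {
  enrichment_params(weight_p = cfg$weight_p, n_perm = cfg$n_perm,
                    perm_mode = cfg$perm_mode, seed = cfg$seed,
                    metric = cfg$metric)
}

#' Run an end-to-end workflow
#'
#' Executes one of the named stages against file inputs and writes its
#' result tables, a JSON summary (thresholds, seed, input checksums,
#' package version), and returns the artifact paths. Outputs are a pure
#' function of (inputs, config, seed).
#'
#' Workflows: `"status"` (case vs reference signature status), `"screen"`
#' (reversal screen over arm files), `"sc"` (single-cell QC +
#' normalization + viral-load enrichment), `"connectivity"` (profile
#' collection vs signature query), `"simulate"` (write synthetic inputs
#' and truth).
#'
#' @param name Workflow name.
#' @param config A [run_config], list, or YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `status` (0 on success), `files`, and
#'   the workflow's main result object.
#' @export
run_workflow <- function(name = c("status", "screen", "sc", "connectivity",
                                  "simulate"),
                         config = list(), out_dir = tempfile("plsrun")) {
  name <- match.arg(name)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- workflow_params(cfg)
  files <- character(0)
  inputs <- character(0)
  result <- switch(name,
    status = {
      for (k in c("case", "reference", "signature"))
        if (is.null(cfg[[k]]))
          pls_error(sprintf("status workflow needs config key '%s'", k),
                    "plsassay_input_error")
      inputs <- c(cfg$case, cfg$reference, cfg$signature)
      sig <- load_signature(cfg$signature)
      st <- assess_pls(read_expression(cfg$case), read_expression(cfg$reference),
                       sig, params = params, alpha = cfg$alpha,
                       coverage_min = cfg$coverage_min,
                       pseudocount = cfg$pseudocount)
      f1 <- file.path(out_dir, "status_results.tsv")
      write_gsea_tsv(st$results, f1)
      f2 <- file.path(out_dir, "status.json")
      jsonlite::write_json(list(global_label = st$global_label,
                                delta = st$delta,
                                poor = list(NES = st$poor$NES, fdr_q = st$poor$fdr_q),
                                good = list(NES = st$good$NES, fdr_q = st$good$fdr_q),
                                heatmap = as.list(st$heatmap)),
                           f2, auto_unbox = TRUE, digits = NA)
      files <- c(f1, f2)
      st
    },
    screen = {
      for (k in c("arms", "control", "signature"))
        if (is.null(cfg[[k]]))
          pls_error(sprintf("screen workflow needs config key '%s'", k),
                    "plsassay_input_error")
      arm_files <- if (dir.exists(cfg$arms))
        list.files(cfg$arms, pattern = "\\.(tsv|txt|csv)$", full.names = TRUE)
      else cfg$arms
      if (!length(arm_files))
        pls_error("no arm files found", "plsassay_input_error")
      inputs <- c(arm_files, cfg$control, cfg$signature)
      arms <- lapply(arm_files, read_expression)
      names(arms) <- sub("\\.[^.]+$", "", basename(arm_files))
      scr <- run_screen(arms, read_expression(cfg$control),
                        load_signature(cfg$signature), params = params,
                        alpha = cfg$alpha, coverage_min = cfg$coverage_min,
                        pseudocount = cfg$pseudocount)
      f1 <- file.path(out_dir, "screen_ranked.tsv")
      write_screen_tsv(scr, f1)
      f2 <- file.path(out_dir, "screen_summary.json")
      jsonlite::write_json(scr$summary, f2, auto_unbox = TRUE, digits = NA)
      files <- c(f1, f2)
      scr
    },
    sc = {
      for (k in c("counts", "cell_stats", "signature"))
        if (is.null(cfg[[k]]))
          pls_error(sprintf("sc workflow needs config key '%s'", k),
                    "plsassay_input_error")
      inputs <- c(cfg$counts, cfg$cell_stats, cfg$signature)
      qc <- do.call(cell_qc_params, cfg$qc)
      counts <- read_expression(cfg$counts)
      stats_df <- utils::read.delim(cfg$cell_stats, stringsAsFactors = FALSE)
      kept <- filter_cells_alignment(stats_df, qc)
      counts <- counts[, intersect(sample_ids(counts), kept)]
      counts <- filter_cells_counts(counts, qc)
      counts <- filter_artifact_and_rare_genes(counts, qc)
      norm <- sc_normalize(counts)
      vl <- stats::setNames(stats_df$viral_load, stats_df$cell)[sample_ids(norm)]
      vle <- viral_load_enrichment(norm, vl, load_signature(cfg$signature),
                                   params = params, alpha = cfg$alpha)
      f1 <- file.path(out_dir, "sc_enrichment.tsv")
      write_gsea_tsv(vle$results, f1)
      f2 <- file.path(out_dir, "sc_summary.json")
      jsonlite::write_json(list(n_cells = ncol(norm$values),
                                n_genes = nrow(norm$values),
                                label = vle$label,
                                cor_poor = vle$cor_poor, cor_good = vle$cor_good),
                           f2, auto_unbox = TRUE, digits = NA)
      files <- c(f1, f2)
      vle
    },
    connectivity = {
      for (k in c("profiles_file", "signature"))
        if (is.null(cfg[[k]]))
          pls_error(sprintf("connectivity workflow needs config key '%s'", k),
                    "plsassay_input_error")
      inputs <- c(cfg$profiles_file, cfg$signature)
      sig <- load_signature(cfg$signature)
      res <- connectivity_score(read_profiles(cfg$profiles_file),
                                query_signature(sig$poor, sig$good),
                                n_perm = cfg$n_perm, seed = cfg$seed)
      res$selected_cmap <- res$perturbagen %in%
        select_candidates(res, "cmap", p_max = cfg$connectivity_p)
      res$selected_lincs <- res$perturbagen %in%
        select_candidates(res, "lincs", tau_max = cfg$connectivity_tau)
      f1 <- file.path(out_dir, "connectivity.tsv")
      utils::write.table(as.data.frame(res), f1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- f1
      res
    },
    simulate = {
      sim_cfg <- do.call(sim_config,
                         c(list(seed = cfg$seed), cfg$simulate))
      bulk <- simulate_bulk(sim_cfg)
      scr <- simulate_screen(sim_cfg)
      f <- character(0)
      f[1] <- file.path(out_dir, "bulk_counts.tsv")
      write_expression(bulk$matrix, f[1])
      f[2] <- file.path(out_dir, "signature.gmt")
      write_gmt(list(bulk$signature$poor, bulk$signature$good,
                     bulk$signature$housekeeping), f[2])
      f[3] <- file.path(out_dir, "control_counts.tsv")
      write_expression(scr$control, f[3])
      arm_dir <- file.path(out_dir, "arms")
      dir.create(arm_dir, showWarnings = FALSE)
      for (id in names(scr$arms))
        write_expression(scr$arms[[id]], file.path(arm_dir, paste0(id, ".tsv")))
      f[4] <- file.path(out_dir, "truth.json")
      jsonlite::write_json(list(bulk = bulk$truth, screen = scr$truth),
                           f[4], auto_unbox = TRUE, digits = NA)
      files <- c(f, file.path(arm_dir, paste0(names(scr$arms), ".tsv")))
      list(bulk = bulk, screen = scr)
    })
  summary_file <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(list(
    workflow = name, seed = cfg$seed, alpha = cfg$alpha,
    n_perm = cfg$n_perm, weight_p = cfg$weight_p, perm_mode = cfg$perm_mode,
    connectivity_p = cfg$connectivity_p, connectivity_tau = cfg$connectivity_tau,
    target_k = cfg$target_k,
    package_version = as.character(utils::packageVersion("plsassay")),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)]))),
    summary_file, auto_unbox = TRUE, digits = NA)
  invisible(list(status = 0L, files = c(files, summary_file), result = result))
}
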