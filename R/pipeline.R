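## Workflow orchestration: simulate -> scan -> annotate -> panel ->
## hwe-test driven by a single config (a nested list, or a YAML/JSON file
## with per-stage sections mirroring the CLI flags). Every output TSV
## carries a commented header with the package version, seed and stage
## parameters; logging goes to stderr.

log_msg <- function(...) message(sprintf(...))

#' Read a pipeline configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file with optional
#'   sections `simulate`, `scan`, `annotate`, `panel`, `hwe_test` plus
#'   top-level `seed` and `out_dir`.
#' @return nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: %s", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      config_error("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

#' Default pipeline configuration
#'
#' Per-stage parameter defaults for [run_pipeline()]; a user config is
#' merged over this structure, so any subset of fields may be supplied.
#'
#' @return nested list with sections `simulate`, `scan`, `annotate`,
#'   `panel`, `hwe_test` plus `seed` and `out_dir`.
#' @export
default_run_config <- function() {
  list(seed = 1L, out_dir = ".",
       simulate = list(),
       scan = list(pools = c(3, 4), depth_min = 40, depth_max = 200,
                   maf_min = 0.2, error_floor = 0.01,
                   window = 40000, step = 20000, min_snps = 6,
                   top = 10, span = 180000, cluster_gap = 20000),
       annotate = list(gff = NULL, keywords = DEFAULT_KEYWORDS),
       panel = list(mode = "fixed", pools = c(1, 2), reduced_pool = 2,
                    depth_min = 40, depth_max = 130),
       hwe_test = list(counts = NULL, freq = 0.583, iters = 9999))
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

scan_stage <- function(sites, sc, prefix, meta) {
  scan <- run_scan(sites, pools = sc$pools, depth_min = sc$depth_min,
                   depth_max = sc$depth_max, maf_min = sc$maf_min,
                   error_floor = sc$error_floor)
  log_msg("scan: %d SNPs retained; genome-wide median AFD = %s",
          scan$n_snps,
          if (is.na(scan$median_afd)) "NA" else format(scan$median_afd))
  win <- smooth_windows(scan, width = sc$window, step = sc$step,
                        min_snps = sc$min_snps)
  files <- paste0(prefix, c(".snps.tsv", ".windows.tsv", ".top.tsv",
                            ".regions.tsv"))
  write_result_tsv(scan$snps, files[1],
                   c(meta, scan$params,
                     list(median_afd = scan$median_afd)))
  write_result_tsv(win, files[2], c(meta, sc[c("window", "step",
                                               "min_snps")]))
  top <- NULL; regions <- NULL
  if (scan$n_snps > 0) {
    top <- top_snps(scan, k = min(sc$top, scan$n_snps))
    regions <- candidate_regions(top, span = sc$span,
                                 cluster_gap = sc$cluster_gap)
    write_result_tsv(top, files[3], meta)
    write_result_tsv(regions, files[4], meta)
  } else {
    write_result_tsv(as_snp_table(scan), files[3], meta)
    write_result_tsv(candidate_regions(as_snp_table(scan)), files[4], meta)
  }
  list(scan = scan, windows = win, top = top, regions = regions,
       files = files)
}

#' Run the full synthetic-data workflow
#'
#' Executes, in dependency order: dataset simulation, the
#' `Complete_CL`-vs-`Partial_CL` differentiation scan (windows, top SNPs,
#' candidate regions), optional gene annotation of the regions, the fixed
#' SNP allele panel from a `Complete_CC`-vs-`Low_LL` scan, and an optional
#' Monte-Carlo HWE deviance test. All outputs land under `out_dir` with a
#' provenance header; nothing is written if configuration validation fails.
#'
#' @param config nested configuration list (see [default_run_config()]
#'   sections), or a path to a YAML/JSON file.
#' @return list of stage results, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(default_run_config(), config)
  ## validate before any output is produced
  sc <- cfg$scan
  if (sc$depth_min > sc$depth_max)
    config_error("scan: depth_min (%s) > depth_max (%s)",
                 sc$depth_min, sc$depth_max)
  pn <- cfg$panel
  if (pn$depth_min > pn$depth_max)
    config_error("panel: depth_min (%s) > depth_max (%s)",
                 pn$depth_min, pn$depth_max)
  sim_cfg <- do.call(sim_config, cfg$simulate)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(package = sprintf("poolscan %s",
                                 as.character(utils::packageVersion("poolscan"))),
               seed = cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  log_msg("simulate: %d individuals, %d neutral SNPs, seed %s",
          sim_cfg$n_individuals, sim_cfg$n_neutral_snps, cfg$seed)
  sim <- simulate_dataset(sim_cfg, seed = cfg$seed,
                          out_prefix = file.path(cfg$out_dir, "sim"))
  log_msg("simulate: done in %.1fs", proc.time()[["elapsed"]] - t0)

  res <- list(sim = sim)
  res$scan <- scan_stage(sim$sites, sc, file.path(cfg$out_dir, "scan"), meta)

  if (!is.null(cfg$annotate$gff)) {
    genes <- read_gff_genes(cfg$annotate$gff)
    ann <- annotate_regions(res$scan$regions, genes, cfg$annotate$keywords)
    write_result_tsv(ann, file.path(cfg$out_dir, "annotate.tsv"), meta)
    res$annotate <- ann
  }

  major_scan <- run_scan(sim$sites, pools = pn$pools,
                         depth_min = pn$depth_min, depth_max = pn$depth_max)
  panel <- fixed_snp_panel(major_scan, reduced_pool = pn$reduced_pool)
  log_msg("panel: %d fixed SNPs between pools %s", nrow(panel),
          paste(pn$pools, collapse = ","))
  write_result_tsv(panel, file.path(cfg$out_dir, "panel.tsv"), meta)
  res$panel <- panel

  if (!is.null(cfg$hwe_test$counts)) {
    mc <- mc_deviance_test(cfg$hwe_test$counts, p = cfg$hwe_test$freq,
                           n_iter = cfg$hwe_test$iters, seed = cfg$seed)
    log_msg("hwe-test: deviance %.5g, percentile %.1f, p = %.4g",
            mc$observed_deviance, mc$percentile, mc$p_value)
    write_result_tsv(
      data.table(observed_deviance = mc$observed_deviance,
                 percentile = mc$percentile, p_value = mc$p_value,
                 n_iter = mc$n_iter, tail = mc$tail),
      file.path(cfg$out_dir, "hwe_test.tsv"), meta)
    res$hwe_test <- mc
  }
  log_msg("pipeline: done in %.1fs", proc.time()[["elapsed"]] - t0)
  invisible(res)
}
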