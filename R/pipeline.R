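# ---- full-analysis orchestration ----

#' Read a run configuration
#'
#' Configurations are YAML or JSON with fields `manifest`, `models`,
#' `n_trials`, `seed`, `alpha`, `frames`, `out_dir` and optional flags
#' `keep_terminal_stop`, `one_per_genus`, `min_codons`. A seed is required:
#' there are no unseeded runs.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  validate_run_config(cfg, dir = dirname(path))
}

validate_run_config <- function(cfg, dir = ".") {
  defaults <- list(models = c("periodic2", "codon_usage"), n_trials = 200L,
                   alpha = 0.05, frames = "both", out_dir = "oscan-results",
                   keep_terminal_stop = FALSE, one_per_genus = FALSE,
                   min_codons = 100L)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  if (is.null(cfg$seed)) abort("config requires a seed", class = "oscan_config_error")
  if (is.null(cfg$manifest)) abort("config requires a manifest path",
                                   class = "oscan_config_error")
  if (!grepl("^/", cfg$manifest)) cfg$manifest <- file.path(dir, cfg$manifest)
  if (cfg$n_trials < 2L) abort("n_trials must be >= 2", class = "oscan_config_error")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must be in (0, 1)",
                                              class = "oscan_config_error")
  cfg$models <- unname(vapply(unlist(cfg$models), normalize_model_spec, character(1)))
  cfg
}

#' Run the full analysis
#'
#' Orchestrates the stages end to end: load and filter each manifest genome
#' (unreadable entries are logged and skipped), optionally trim to one
#' genome per genus, compute per-genome metrics, run the Monte Carlo
#' expectation analysis for every configured model with BH correction
#' across genomes, and, when at least three genomes are available, the
#' usage-bias PCA and density-vs-G+C regression. All tables are written as
#' TSV, the batch summary as JSON, and a log records seeds, versions and
#' per-genome exclusions.
#'
#' @param config a config list (see [read_run_config()]) or a path to one.
#' @return Invisibly, a list with `metrics`, `results`, `summary`,
#'   `pca`, `regression` and `paths` of the written files.
#' @export
run_full_analysis <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("oscan %s | R %s | seed %d", as.character(utils::packageVersion("oscan")),
       paste(R.version$major, R.version$minor, sep = "."), cfg$seed)

  manifest <- read_genome_manifest(cfg$manifest)
  if (cfg$one_per_genus) {
    n0 <- nrow(manifest)
    manifest <- select_one_per_genus(manifest, cfg$seed)
    logf("one-per-genus trim: %d -> %d genomes", n0, nrow(manifest))
  }
  genomes <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    g <- tryCatch({
      raw <- load_cds(row$path, format = row$format, table_id = row$table_id,
                      organism = row$organism, genus = row$genus,
                      division = row$division)
      filt <- filter_cds(raw, min_codons = cfg$min_codons,
                         keep_terminal_stop = cfg$keep_terminal_stop)
      rep <- attr(filt, "exclusion_report")
      logf("%s: loaded %d CDS, kept %d (%s)", row$organism, nrow(raw), nrow(filt),
           if (nrow(rep)) paste(rep$reason, rep$n, sep = "=", collapse = ", ")
           else "no exclusions")
      if (!nrow(filt)) stop("no CDS passed filters")
      filt
    }, error = function(e) {
      logf("%s: SKIPPED (%s)", row$organism, conditionMessage(e))
      NULL
    })
    if (!is.null(g)) genomes[[length(genomes) + 1L]] <- g
  }
  if (!length(genomes)) abort("zero usable genomes", class = "oscan_input_error")
  all_cds <- as_cds_tbl(bind_rows(genomes))

  metrics <- genome_metrics(all_cds)
  readr::write_tsv(metrics, file.path(cfg$out_dir, "metrics.tsv"))

  batch <- batch_analysis(all_cds, model_specs = cfg$models,
                          n_trials = cfg$n_trials, seed = cfg$seed,
                          alpha = cfg$alpha, frames = cfg$frames)
  readr::write_tsv(tidy(batch), file.path(cfg$out_dir, "expectation_results.tsv"))
  summary_tbl <- batch_summary(batch)
  jsonlite::write_json(summary_tbl, file.path(cfg$out_dir, "summary.json"),
                       digits = NA)
  fails <- attr(batch, "failures")
  if (!is.null(fails) && nrow(fails)) {
    for (i in seq_len(nrow(fails))) {
      logf("analysis failure: %s / %s: %s", fails$organism[i], fails$model[i],
           fails$error[i])
    }
  }

  pca <- NULL; reg <- NULL
  usage_cols <- grep("_f[23]$", names(metrics), value = TRUE)
  if (nrow(metrics) >= 3L) {
    pca <- tryCatch(pca_usage(metrics[, usage_cols]), error = function(e) NULL)
    if (!is.null(pca)) {
      readr::write_tsv(tidy(pca), file.path(cfg$out_dir, "pca_loadings.tsv"))
    }
    reg <- tryCatch(fit_regression(metrics, density_total ~ gc),
                    error = function(e) NULL)
    if (!is.null(reg)) {
      readr::write_tsv(tidy(reg), file.path(cfg$out_dir, "density_gc_regression.tsv"))
    }
  }
  logf("completed: %d genomes, %d models", length(genomes), length(cfg$models))
  invisible(list(
    metrics = metrics, results = batch, summary = summary_tbl,
    pca = pca, regression = reg,
    paths = file.path(cfg$out_dir,
                      c("metrics.tsv", "expectation_results.tsv", "summary.json",
                        "run.log"))
  ))
}

#' @export
tidy.osc_batch <- function(x, ...) {
  as_tibble(x) |> select(-"sim_densities")
}

#' @export
glance.osc_batch <- function(x, ...) batch_summary(x)
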