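#' Validate a pipeline run configuration
#'
#' Checks every parameter against the constraints of the consuming modules
#' before any work starts: theta a simplex, rates positive, thresholds in
#' range. A config is a plain named list (or a YAML file read with
#' [read_config()]).
#'
#' @param config named list; recognized fields: `groups`, `theta`, `G`,
#'   `lambda_sim` (default 1e-8), `lambda_hmm` (1e-15), `eps_csv` (1e-5),
#'   `eps_s` (0.01), `tau` (0.6), `buffer` (10), `n_iter` (4), `n_genotypes`,
#'   `coverage` (optional), `seed`, `preset` (`"AA"`/`"MEX"`/`"PUR"`,
#'   overrides theta/G), and either `panel` fields (`panel_path`,
#'   `labels_path`) or `synthetic` (a list of [synthetic_panel_spec()]
#'   arguments).
#' @return the validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  defaults <- list(lambda_sim = 1e-8, lambda_hmm = 1e-15, eps_csv = 1e-5,
                   eps_s = 0.01, tau = 0.6, buffer = 10L, n_iter = 4L,
                   n_genotypes = 20L, coverage = NA, seed = 1L)
  config <- utils::modifyList(defaults, config)
  if (!is.null(config$preset)) {
    m <- admix_preset(config$preset,
                      groups = if (!is.null(config$groups)) config$groups
                               else c("EUR", "NAM", "AFR"))
    config$groups <- names(m$theta)
    config$theta <- m$theta
    config$G <- m$G
  }
  if (is.null(config$groups) || is.null(config$theta) || is.null(config$G))
    stop("config must define groups, theta and G (or a preset)")
  config$theta <- stats::setNames(unlist(config$theta), config$groups)
  if (any(config$theta < 0) || abs(sum(config$theta) - 1) > 1e-8)
    stop("theta must be a simplex over the groups")
  K <- length(config$groups)
  if (config$eps_csv <= 0 || config$eps_csv >= 1 / K)
    stop("eps_csv must lie in (0, 1/K)")
  if (config$eps_s <= 0 || config$eps_s >= 0.5)
    stop("eps_s must lie in (0, 0.5)")
  if (config$tau < 0 || config$tau > 2) stop("tau must lie in [0, 2]")
  if (config$lambda_sim <= 0 || config$lambda_hmm <= 0)
    stop("recombination rates must be positive")
  if (config$G < 1) stop("G must be >= 1")
  if (config$n_iter < 0) stop("n_iter must be >= 0")
  if (is.null(config$synthetic) && is.null(config$panel_path))
    stop("config must provide either synthetic panel parameters or panel_path")
  config
}

#' @rdname validate_config
#' @param path YAML config file.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full pipeline from a config and write artifacts
#'
#' Orchestrates: build or load the reference panel, simulate an admixed
#' cohort (when a synthetic spec is given) or load genotypes, estimate
#' informative densities, run sample-aware inference, evaluate against the
#' truth where available, and write tracks, the final specific-variant
#' table, per-iteration diagnostics and a run report to `out_dir`.
#' Deterministic given the config seeds.
#'
#' @param config validated config list (see [validate_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `tracks`, `csv_table`, `diagnostics`,
#'   `report` and paths of the written files.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  if (!is.null(config$synthetic)) {
    spec_args <- utils::modifyList(list(groups = config$groups),
                                   config$synthetic)
    pspec <- do.call(synthetic_panel_spec, spec_args)
    panel <- generate_synthetic_panel(pspec, seed = seed)
  } else {
    panel <- read_panel(config$panel_path, config$labels_path)
    panel <- filter_strand_ambiguous(panel)
  }
  model <- admixture_model(config$theta, config$G, config$lambda_sim)
  truth <- NULL
  if (!is.null(config$genotypes_path)) {
    genotypes <- read_genotypes(config$genotypes_path)
    h <- harmonize_sites(panel, genotypes)
    panel <- h$panel; genotypes <- h$genotypes
    sim <- NULL
  } else {
    sim <- simulate_admixed(panel, model, config$n_genotypes,
                            seed = seed + 1L)
    genotypes <- sim$genotypes
    truth <- sim$truth_diploid
  }
  dens <- estimate_density(panel, "continental")
  N <- dens$N[config$groups]
  N[is.na(N) | N <= 0] <- 1e-3
  hspec <- hmm_spec(config$groups, config$theta, config$G,
                    lambda = config$lambda_hmm, eps_csv = config$eps_csv,
                    N = N)
  rc <- NULL
  if (!is.na(config$coverage))
    rc <- simulate_reads(genotypes, config$coverage, config$eps_s,
                         seed = seed + 2L)
  fit <- infer_ancestry(genotypes, hspec,
                        freqs = panel_frequencies(panel, "continental"),
                        n_iter = config$n_iter, buffer = config$buffer,
                        read_counts = rc, eps_s = config$eps_s,
                        tau = config$tau)
  paths <- list(tracks = file.path(out_dir, "tracks.bed"),
                csv_table = file.path(out_dir, "csv_table.tsv"),
                diagnostics = file.path(out_dir, "diagnostics.tsv"),
                report = file.path(out_dir, "report.tsv"),
                config = file.path(out_dir, "config_used.yaml"))
  write_tracks(fit$tracks, paths$tracks)
  write_csv_table(fit$csv_table, paths$csv_table)
  utils::write.table(fit$diagnostics, paths$diagnostics, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- data.frame(metric = character(), value = numeric())
  if (!is.null(truth)) {
    pos <- genotypes$sites$pos
    r2 <- r2_metric(truth, fit$tracks, pos, config$groups,
                    theta = config$theta)
    acc <- haploid_diploid_accuracy(truth, fit$tracks, pos)
    write_tracks(truth, file.path(out_dir, "truth.bed"))
    report <- data.frame(
      metric = c("mean_r2", "haploid_accuracy", "diploid_accuracy",
                 "n_csv", "n_iterations_run"),
      value = c(r2$mean_r2, acc["haploid"], acc["diploid"],
                nrow(fit$csv_table), max(fit$diagnostics$iteration)))
  } else {
    report <- data.frame(metric = c("n_csv", "n_iterations_run"),
                         value = c(nrow(fit$csv_table),
                                   max(fit$diagnostics$iteration)))
  }
  utils::write.table(report, paths$report, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg_out <- config
  cfg_out$theta <- as.list(cfg_out$theta)
  cfg_out$package_version <- as.character(utils::packageVersion("lancsv"))
  yaml::write_yaml(cfg_out, paths$config)
  invisible(list(tracks = fit$tracks, csv_table = fit$csv_table,
                 diagnostics = fit$diagnostics, report = report,
                 paths = paths))
}
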