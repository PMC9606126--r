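# End-to-end orchestration: simulate or ingest -> rarefy -> PPE-adjust ->
# beta diversity -> radius scans -> report, for the six datasets of the
# region/habitat partition, under one master seed.

#' Assemble a pipeline run configuration
#'
#' @param preset synthetic preset name passed to [synthetic_config()], or
#'   `NULL` when `pollen`/`survey`/`ppe` paths are given.
#' @param pollen,survey,ppe optional input file paths (read through the
#'   package's I/O contracts) used instead of simulation.
#' @param depth rarefaction depth for raw counts (default 943 grains).
#' @param adjusted_depth resampling depth after PPE adjustment (default 520).
#' @param n_reps repeated subsamples per site (default 100).
#' @param sqrt_d square-root transform dissimilarities before Gower centering
#'   (default TRUE).
#' @param grid radius grid for the plant-side scans.
#' @param n_perm permutations for the LCBD significance test (default 199).
#' @param seed integer master seed.
#' @param outdir optional directory for CSV/JSON outputs.
#' @return a list of class `run_config`.
#' @export
run_config <- function(preset = "field_study", pollen = NULL, survey = NULL,
                       ppe = NULL, depth = 943, adjusted_depth = 520,
                       n_reps = 100, sqrt_d = TRUE,
                       grid = default_radius_grid(), n_perm = 199, seed = 1,
                       outdir = NULL) {
  stopifnot(depth >= 1, adjusted_depth >= 1, n_reps >= 1, n_perm >= 1)
  check_radius_grid(grid)
  structure(list(preset = preset, pollen = pollen, survey = survey, ppe = ppe,
                 depth = depth, adjusted_depth = adjusted_depth,
                 n_reps = n_reps, sqrt_d = sqrt_d, grid = grid,
                 n_perm = n_perm, seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Per-dataset mean of a per-site statistic
#'
#' @param values named numeric vector (names = site ids).
#' @param partition a [partition_datasets()] result.
#' @return named numeric vector of dataset means (`NA` for empty datasets).
#' @export
report_mean_richness <- function(values, partition) {
  vapply(partition, function(ids) {
    ids <- intersect(ids, names(values))
    if (length(ids) == 0L) NA_real_ else mean(values[ids])
  }, numeric(1))
}

#' Run the full calibration pipeline
#'
#' Executes, for the six datasets of the partition: rarefaction of pollen
#' counts, PPE adjustment and resampling, pollen BD_Total and LCBD with
#' permutation significance, plant BD_Total along the radius grid, and the
#' three radius scans (richness per dataset, BD_Total across datasets, LCBD
#' per dataset), each reporting its source area. Warnings raised by the
#' stages (shallow samples, unmatched PPE taxa, zero-variance radii) are
#' collected into the report.
#'
#' @param config a [run_config()].
#' @return a list of class `run_report`: `datasets` (summary data.frame),
#'   `richness` (per-site), `lcbd` (per-site, with p-values),
#'   `scans` (named list of `scaling_result`s), `source_areas` (data.frame),
#'   `warnings`, `provenance`, and `truth` when simulated.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warn <- character()
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
  })

  truth <- NULL
  if (!is.null(config$pollen)) {
    pollen <- read_pollen_counts(config$pollen)
    survey <- read_plant_survey(config$survey)
    ppe <- read_ppe_table(config$ppe)
  } else {
    sim <- simulate_dataset(synthetic_config(config$preset, seed = config$seed))
    pollen <- sim$pollen; survey <- sim$survey; ppe <- sim$ppe
    truth <- sim$truth
  }
  partition <- collect(partition_datasets(pollen))
  partition <- partition[vapply(partition, length, 1L) >= 4L]

  rar <- collect(rarefy_dataset(pollen, depth = config$depth,
                                n_reps = config$n_reps, rng_seed = config$seed))
  rich <- stats::setNames(rar$summary$richness_median, rar$summary$site_id)

  adj <- collect(adjust_counts(pollen, ppe))
  adj_rar <- collect(resample_adjusted(adj, depth = config$adjusted_depth,
                                       n_reps = config$n_reps,
                                       rng_seed = config$seed))
  adj_rich <- stats::setNames(adj_rar$summary$richness_median,
                              adj_rar$summary$site_id)

  mean_rich <- report_mean_richness(rich, partition)
  mean_adj <- report_mean_richness(adj_rich, partition)

  pollen_bd <- vapply(partition, function(ids) {
    suppressMessages(beta_div_presence(rar$presence[ids, , drop = FALSE],
                                       sqrt_transform = config$sqrt_d)$bd_total)
  }, numeric(1))

  lcbd_tabs <- lapply(names(partition), function(d) {
    ids <- partition[[d]]
    tab <- suppressMessages(
      lcbd_permutation_test(rar$presence[ids, , drop = FALSE],
                            n_perm = config$n_perm,
                            rng_seed = child_seed(config$seed, paste0("perm:", d)),
                            sqrt_transform = config$sqrt_d))
    tab$dataset <- d
    tab
  })
  lcbd_tab <- do.call(rbind, lcbd_tabs)

  scans <- list()
  for (d in names(partition)) {
    scans[[paste0("richness:", d)]] <- collect(
      fit_scaling_regressions(rich, survey, config$grid, partition[[d]]))
    scans[[paste0("adjusted_richness:", d)]] <- collect(
      fit_scaling_regressions(adj_rich, survey, config$grid, partition[[d]]))
    lc <- lcbd_tab[lcbd_tab$dataset == d, ]
    scans[[paste0("lcbd:", d)]] <- collect(
      lcbd_scan(stats::setNames(lc$lcbd, lc$site_id), survey, config$grid,
                partition[[d]], sqrt_transform = config$sqrt_d))
  }
  scans[["bd_total"]] <- collect(
    bd_total_scan(pollen_bd, survey, partition, config$grid,
                  sqrt_transform = config$sqrt_d))

  source_areas <- do.call(rbind, lapply(names(scans), function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    data.frame(dataset = if (length(parts) == 2) parts[2] else "all",
               kind = parts[1], source_area_m = scans[[nm]]$source_area_m,
               stringsAsFactors = FALSE)
  }))

  datasets <- data.frame(dataset = names(partition),
                         n_sites = vapply(partition, length, 1L),
                         mean_richness = mean_rich,
                         mean_adjusted_richness = mean_adj,
                         bd_total = pollen_bd,
                         row.names = NULL, stringsAsFactors = FALSE)

  report <- structure(list(
    datasets = datasets,
    richness = rar$summary,
    adjusted_richness = adj_rar$summary,
    lcbd = lcbd_tab,
    scans = scans,
    source_areas = source_areas,
    warnings = unique(warn),
    truth = truth,
    provenance = list(seed = config$seed, config_hash = config_hash(config),
                      version = as.character(utils::packageVersion("pollendiv")))),
    class = "run_report")
  if (!is.null(config$outdir)) write_run_report(report, config$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$provenance$seed, ", config",
      x$provenance$config_hash, ")\n")
  print(x$datasets, digits = 4)
  cat("\nsource areas (m):\n")
  print(x$source_areas)
  if (length(x$warnings)) cat("\n", length(x$warnings), "warning(s) collected\n")
  invisible(x)
}

#' Write a run report to CSV files plus a JSON provenance block
#'
#' @param report a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header("run report")
  write_delim_file(report$datasets, file.path(outdir, "datasets.csv"), hdr)
  write_delim_file(report$richness, file.path(outdir, "richness.csv"), hdr)
  write_delim_file(report$adjusted_richness,
                   file.path(outdir, "adjusted_richness.csv"), hdr)
  write_delim_file(report$lcbd, file.path(outdir, "lcbd.csv"), hdr)
  scans <- do.call(rbind, lapply(names(report$scans), function(nm) {
    df <- report$scans[[nm]]$summary
    df$scan <- nm
    df
  }))
  write_delim_file(scans, file.path(outdir, "scaling.csv"), hdr)
  write_delim_file(report$source_areas, file.path(outdir, "source_areas.csv"), hdr)
  jsonlite::write_json(c(report$provenance, list(warnings = report$warnings)),
                       file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
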