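# Spatial scaling of the pollen-plant diversity relationship: cumulative
# plant richness as a function of radius, OLS of a pollen-derived diversity
# value on its plant-derived counterpart at every radius of a grid, and the
# source area of pollen diversity = the radius with the highest adjusted R^2.

#' Default radius grid (metres)
#'
#' Strictly increasing radii from 0.5 to 1000 m covering the survey zones
#' (complete lists to 10 m, polygon mapping to 100 m, transects to 1000 m);
#' fully overridable wherever a grid is accepted.
#'
#' @return numeric vector of 25 radii.
#' @export
default_radius_grid <- function() {
  c(0.5, 1.5, 3, 6, 10, 20, 30, 40, 50, 70, 100, 150, 200, 250, 300,
    350, 400, 450, 500, 550, 600, 700, 800, 900, 1000)
}

check_radius_grid <- function(grid) {
  if (any(!is.finite(grid)) || any(diff(grid) <= 0) ||
      grid[1] < 0.5 || grid[length(grid)] > 1000)
    stop("radius grid must be strictly increasing within [0.5, 1000] m", call. = FALSE)
  invisible(grid)
}

#' Cumulative plant richness per site along a radius grid
#'
#' Number of species whose first-appearance distance is `<= r`, per site and
#' grid radius; non-decreasing in the radius by construction. Sites listed in
#' `site_ids` but absent from the survey get a zero row.
#'
#' @param survey a [plant_survey()].
#' @param grid radius grid (metres), see [default_radius_grid()].
#' @param site_ids sites to tabulate (default: all sites in the survey).
#' @return integer matrix, sites x radii (colnames = radii).
#' @export
cumulative_richness <- function(survey, grid = default_radius_grid(),
                                site_ids = NULL) {
  check_radius_grid(grid)
  if (nrow(survey) == 0L) stop("empty survey", call. = FALSE)
  site_ids <- site_ids %||% sort(unique(survey$site_id))
  out <- matrix(0L, length(site_ids), length(grid),
                dimnames = list(site_ids, as.character(grid)))
  rec <- survey[survey$site_id %in% site_ids, ]
  for (k in seq_along(grid)) {
    within <- rec$first_distance_m <= grid[k]
    tab <- table(factor(rec$site_id[within], levels = site_ids))
    out[, k] <- as.integer(tab)
  }
  out
}

#' New species per radius band and habitat of record
#'
#' Bins first appearances into the bands `(r_{k-1}, r_k]` of the grid (the
#' innermost band includes distance 0) and tallies them by the habitat in
#' which the species was recorded, across all sites of the survey subset.
#' Band totals conserve the grand total of first appearances.
#'
#' @inheritParams cumulative_richness
#' @return data.frame `band_lo`, `band_hi`, `habitat`, `n_species`.
#' @export
new_species_by_band <- function(survey, grid = default_radius_grid()) {
  check_radius_grid(grid)
  if (!all(nzchar(survey$habitat)))
    stop("habitat of record required for every survey row", call. = FALSE)
  breaks <- c(0, grid)
  band <- cut(survey$first_distance_m, breaks = breaks, include.lowest = TRUE,
              right = TRUE, labels = FALSE)
  tab <- as.data.frame(table(band = factor(band, levels = seq_along(grid)),
                             habitat = survey$habitat),
                       stringsAsFactors = FALSE)
  data.frame(band_lo = breaks[as.integer(tab$band)],
             band_hi = grid[as.integer(tab$band)],
             habitat = tab$habitat, n_species = tab$Freq,
             stringsAsFactors = FALSE)
}

# OLS of y on x with closed-form adjusted R^2 for one predictor and the
# two-sided slope p-value; returns NA sentinels for degenerate inputs
ols_summary <- function(x, y) {
  n <- length(x)
  if (n < 3 || stats::var(x) < 1e-12)
    return(list(n = n, slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                adj_r2 = NA_real_, p_value = NA_real_))
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # perfect fits warn; p handled below
  r2 <- s$r.squared
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  p <- if (stats::var(y) < 1e-12) NA_real_ else s$coefficients["x", "Pr(>|t|)"]
  list(n = n, slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), r2 = r2, adj_r2 = adj,
       p_value = p)
}

scaling_result <- function(rows, grid, kind) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$significant <- !is.na(df$p_value) & df$p_value < 0.05
  ok <- !is.na(df$adj_r2)
  source_area <- if (any(ok)) df$radius[ok][which.max(df$adj_r2[ok])] else NA_real_
  structure(list(summary = df, source_area_m = source_area,
                 diversity_kind = kind),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat("scaling_result (", x$diversity_kind, "): ", nrow(x$summary),
      " radii, source area = ", x$source_area_m, " m\n", sep = "")
  best <- x$summary[which.max(ifelse(is.na(x$summary$adj_r2), -Inf, x$summary$adj_r2)), ]
  cat("  best fit: adj R^2 =", signif(best$adj_r2, 3), " p =",
      signif(best$p_value, 3), " n =", best$n, "\n")
  invisible(x)
}

#' Radius-scanning regression of pollen diversity on plant diversity
#'
#' At every radius of the grid, ordinary least squares of the per-site pollen
#' value (e.g. rarefied pollen richness) on the per-site plant value at that
#' radius (cumulative plant richness). The source area of pollen diversity is
#' the radius with the highest adjusted R^2 (ties broken towards the smallest
#' radius; radii with zero predictor variance carry NA sentinels and are
#' excluded from the argmax). Sites lacking any plant record within a radius
#' contribute plant richness 0 rather than being dropped.
#'
#' @param pollen_values named numeric vector, one value per site.
#' @param survey a [plant_survey()].
#' @param grid radius grid (metres).
#' @param site_ids sites forming the dataset (default: names of
#'   `pollen_values`); at least 4 required.
#' @return an object of class `scaling_result`: `summary` (one row per
#'   radius: `radius`, `n`, `slope`, `intercept`, `r2`, `adj_r2`, `p_value`,
#'   `significant`), `source_area_m`, `diversity_kind`.
#' @export
fit_scaling_regressions <- function(pollen_values, survey,
                                    grid = default_radius_grid(),
                                    site_ids = NULL) {
  check_radius_grid(grid)
  site_ids <- site_ids %||% names(pollen_values)
  site_ids <- intersect(site_ids, names(pollen_values))
  if (length(site_ids) < 4L)
    stop("need >= 4 sites with pollen values (got ", length(site_ids), ")",
         call. = FALSE)
  plant <- cumulative_richness(survey, grid, site_ids)
  y <- pollen_values[site_ids]
  rows <- lapply(seq_along(grid), function(k)
    c(list(radius = grid[k]), ols_summary(plant[, k], y)))
  scaling_result(rows, grid, "richness")
}

#' Radius scan of pollen BD_Total against plant BD_Total across datasets
#'
#' One pollen BD_Total per dataset is regressed, at each radius, on the plant
#' BD_Total of the same datasets computed from species present within that
#' radius. Radii where the plant BD_Total is constant across datasets are
#' reported with NA sentinels.
#'
#' @param pollen_bd named numeric vector of pollen BD_Total values, one per
#'   dataset (at least 3).
#' @param survey a [plant_survey()].
#' @param partition a [partition_datasets()] result (or any named list of
#'   site-id vectors) whose names cover `names(pollen_bd)`.
#' @param grid radius grid (metres).
#' @param sqrt_transform passed to [beta_div()] for the plant side.
#' @return a `scaling_result` with `diversity_kind = "bd_total"`; its
#'   `summary` carries the per-dataset plant BD_Total in attribute
#'   `plant_bd`.
#' @export
bd_total_scan <- function(pollen_bd, survey, partition,
                          grid = default_radius_grid(), sqrt_transform = TRUE) {
  check_radius_grid(grid)
  ds <- names(pollen_bd)
  if (length(ds) < 3L) stop("need >= 3 datasets (got ", length(ds), ")", call. = FALSE)
  if (!all(ds %in% names(partition)))
    stop("partition lacks datasets: ",
         paste(setdiff(ds, names(partition)), collapse = ", "), call. = FALSE)
  plant_bd <- matrix(NA_real_, length(ds), length(grid),
                     dimnames = list(ds, as.character(grid)))
  for (d in ds) for (k in seq_along(grid)) {
    bd <- tryCatch(suppressMessages(
      bd_total_at_radius(survey, partition[[d]], grid[k], sqrt_transform)),
      error = function(e) NULL)
    if (!is.null(bd)) plant_bd[d, k] <- bd$bd_total
  }
  rows <- lapply(seq_along(grid), function(k) {
    x <- plant_bd[, k]
    ok <- is.finite(x)
    c(list(radius = grid[k]), ols_summary(x[ok], pollen_bd[ok]))
  })
  res <- scaling_result(rows, grid, "bd_total")
  attr(res$summary, "plant_bd") <- plant_bd
  res
}

#' Radius scan of pollen LCBD against plant LCBD within a dataset
#'
#' Per-site local contributions to pollen beta diversity are regressed, at
#' each radius, on the local contributions to plant beta diversity computed
#' at that radius.
#'
#' @param pollen_lcbd named numeric vector of pollen LCBD values per site.
#' @inheritParams fit_scaling_regressions
#' @param sqrt_transform passed to [beta_div()] for the plant side.
#' @return a `scaling_result` with `diversity_kind = "lcbd"`.
#' @export
lcbd_scan <- function(pollen_lcbd, survey, grid = default_radius_grid(),
                      site_ids = NULL, sqrt_transform = TRUE) {
  check_radius_grid(grid)
  site_ids <- site_ids %||% names(pollen_lcbd)
  site_ids <- intersect(site_ids, names(pollen_lcbd))
  if (length(site_ids) < 4L)
    stop("need >= 4 sites with LCBD values", call. = FALSE)
  rows <- lapply(seq_along(grid), function(k) {
    plant <- tryCatch(suppressMessages(
      bd_total_at_radius(survey, site_ids, grid[k], sqrt_transform)$lcbd),
      error = function(e) rep(NA_real_, length(site_ids)))
    ok <- is.finite(plant)
    c(list(radius = grid[k]),
      ols_summary(plant[ok], pollen_lcbd[site_ids][ok]))
  })
  scaling_result(rows, grid, "lcbd")
}

#' Survey completeness relative to a reference species pool
#'
#' Percentage of a reference regional species pool captured by the survey,
#' reported to one decimal place.
#'
#' @param recorded_species number of species recorded by the survey.
#' @param reference_species number of species in the reference pool (> 0).
#' @return percentage (numeric scalar, one decimal).
#' @export
completeness_ratio <- function(recorded_species, reference_species) {
  if (!is.finite(reference_species) || reference_species <= 0)
    stop("reference_species must be > 0", call. = FALSE)
  round(100 * recorded_species / reference_species, 1)
}
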