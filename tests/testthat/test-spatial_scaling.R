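test_that("cumulative richness counts species within the closed radius", {
  sv <- survey_from_distances(list(sX = c(0.5, 40, 900)))
  cr <- cumulative_richness(sv, grid = c(10, 100, 1000))
  expect_equal(unname(cr["sX", ]), c(1L, 2L, 3L))

  cr2 <- cumulative_richness(survey_from_distances(list(sY = c(50, 60))),
                             grid = c(10, 100))
  expect_equal(unname(cr2["sY", ]), c(0L, 2L))

  # brute-force oracle on a randomized survey
  set.seed(12)
  d <- list(a = runif(40, 0, 1000), b = runif(25, 0, 1000))
  sv3 <- survey_from_distances(d)
  grid <- default_radius_grid()
  cr3 <- cumulative_richness(sv3, grid)
  for (r in c(10, 150, 700)) {
    k <- which(grid == r)
    expect_equal(cr3["a", k], sum(d$a <= r))
    expect_equal(cr3["b", k], sum(d$b <= r))
  }
  expect_true(all(t(apply(cr3, 1, diff)) >= 0))
  expect_equal(unname(cr3[, ncol(cr3)]), c(40L, 25L))
})

test_that("new-species bands partition first appearances and conserve totals", {
  sv <- plant_survey(data.frame(site_id = "s1", species = "only",
                                first_distance_m = 70, habitat = "open"))
  tab <- new_species_by_band(sv, grid = c(10, 100))
  expect_equal(tab$n_species[tab$band_lo == 10 & tab$habitat == "open"], 1)
  expect_equal(sum(tab$n_species), 1)

  sim <- sim_field_study(seed = 2)
  grid <- default_radius_grid()
  tab2 <- new_species_by_band(sim$survey, grid)
  cr <- cumulative_richness(sim$survey, grid)
  expect_equal(sum(tab2$n_species), sum(cr[, ncol(cr)]))
})

test_that("the per-radius regression reproduces hand-computed least squares", {
  # x = plant = {1,2,3,4}, y = pollen = {2,3,5,6}:
  # slope = 7/5, intercept = 1/2, r2 = 49/50, adj = 1 - (1/50)*3/2 = 0.97,
  # p = 2 * P(t_2 > sqrt(98))
  sv <- survey_from_distances(list(s1 = 5, s2 = c(5, 6), s3 = c(5, 6, 7),
                                   s4 = c(5, 6, 7, 8)))
  pollen_vals <- c(s1 = 2, s2 = 3, s3 = 5, s4 = 6)
  res <- fit_scaling_regressions(pollen_vals, sv, grid = c(10, 1000))
  row <- res$summary[res$summary$radius == 10, ]
  expect_equal(row$slope, 1.4)
  expect_equal(row$intercept, 0.5)
  expect_equal(row$r2, 0.98)
  expect_equal(row$adj_r2, 0.97)
  expect_equal(row$p_value, 2 * pt(-sqrt(98), df = 2), tolerance = 1e-10)
  expect_true(row$significant)
  expect_equal(row$n, 4)
})

test_that("adjusted R^2 follows the one-predictor closed form and is affine-invariant", {
  set.seed(30)
  sv <- survey_from_distances(lapply(setNames(1:8, sprintf("s%d", 1:8)),
                                     function(i) runif(5 + 3 * i, 0, 1000)))
  y <- rnorm(8, 20, 4); names(y) <- sprintf("s%d", 1:8)
  res <- fit_scaling_regressions(y, sv)
  s <- res$summary
  ok <- !is.na(s$adj_r2)
  expect_equal(s$adj_r2[ok], 1 - (1 - s$r2[ok]) * (s$n[ok] - 1) / (s$n[ok] - 2))
  expect_true(all(s$adj_r2[ok] <= s$r2[ok] + 1e-12))

  res2 <- fit_scaling_regressions(3 * y + 10, sv)
  expect_equal(res2$summary$adj_r2, res$summary$adj_r2, tolerance = 1e-9)
  expect_equal(res2$summary$r2, res$summary$r2, tolerance = 1e-9)
})

test_that("the source area is the argmax radius, with ties broken inward and sentinels excluded", {
  # plant richness varies across sites only at radius 100 (and beyond,
  # identically); pollen is exactly linear in that profile
  sv <- survey_from_distances(list(s1 = c(50), s2 = c(50, 60), s3 = c(50, 60, 70),
                                   s4 = c(50, 60, 70, 80), s5 = c(50, 55, 65, 75, 85)))
  cr <- cumulative_richness(sv, grid = c(10, 100, 1000))
  pollen_vals <- setNames(2 * cr[, "100"] + 1, rownames(cr))
  res <- fit_scaling_regressions(pollen_vals, sv, grid = c(10, 100, 1000))
  # radius 10: all plant values 0 -> zero-variance sentinel
  expect_true(is.na(res$summary$adj_r2[res$summary$radius == 10]))
  # radii 100 and 1000 give identical perfect fits; the tie goes inward
  expect_equal(res$summary$adj_r2[res$summary$radius == 100], 1)
  expect_equal(res$source_area_m, 100)

  expect_error(fit_scaling_regressions(pollen_vals[1:3], sv), ">= 4 sites")
})

test_that("BD_Total and LCBD scans regress across datasets and sites", {
  sim <- sim_field_study(seed = 6)
  part <- partition_datasets(sim$pollen)
  rar <- rarefy_dataset(sim$pollen, depth = 943, n_reps = 30, rng_seed = 6)
  pollen_bd <- vapply(part, function(ids)
    suppressMessages(beta_div_presence(rar$presence[ids, , drop = FALSE]))$bd_total,
    numeric(1))
  grid <- c(10, 50, 150, 500, 1000)
  scan <- bd_total_scan(pollen_bd, sim$survey, part, grid)
  expect_equal(scan$diversity_kind, "bd_total")
  expect_true(all(scan$summary$n[!is.na(scan$summary$slope)] == 6))
  expect_true(scan$source_area_m %in% grid)
  expect_error(bd_total_scan(pollen_bd[1:2], sim$survey, part, grid), ">= 3 datasets")

  # identical pollen and plant LCBD vectors give a perfect fit everywhere
  ids <- part$region_rich_open
  plant_lcbd <- suppressMessages(
    bd_total_at_radius(sim$survey, ids, 150)$lcbd)
  res <- lcbd_scan(plant_lcbd, sim$survey, grid = c(150), site_ids = ids)
  expect_equal(res$summary$adj_r2, 1, tolerance = 1e-9)

  # permuted plant values destroy the relationship
  set.seed(4)
  res2 <- lcbd_scan(setNames(sample(plant_lcbd), names(plant_lcbd)),
                    sim$survey, grid = c(150), site_ids = ids)
  expect_lt(res2$summary$adj_r2, 0.5)
})

test_that("survey completeness reproduces the regional species-pool percentages", {
  expect_equal(completeness_ratio(799, 1477), 54.1)
  expect_equal(completeness_ratio(1098, 2045), 53.7)
  expect_equal(completeness_ratio(500, 500), 100.0)
  expect_error(completeness_ratio(10, 0), "> 0")
})
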