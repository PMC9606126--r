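test_that("closed-form source radius inverts the kernel scale and is monotone in it", {
  lam <- lambda_for_source_radius(150)
  expect_equal(effective_source_radius(lam), 150, tolerance = 1e-6)
  lam_g <- lambda_for_source_radius(150, kernel = "gaussian")
  expect_equal(effective_source_radius(lam_g, kernel = "gaussian"), 150,
               tolerance = 1e-6)
  # Gaussian closed form: R_eff = lambda * sqrt(log(1/0.15)) on an
  # effectively unbounded landscape
  expect_equal(lam_g, 150 / sqrt(log(1 / 0.15)), tolerance = 1e-6)

  # decreasing lambda strictly decreases R_eff
  r <- vapply(c(20, 40, 80, 160), effective_source_radius, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("generated fixtures satisfy the I/O contracts and are byte-stable per seed", {
  cfg <- synthetic_config("field_study", seed = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(make_fixture_suite(cfg, seed = 4, outdir = d1))
  suppressMessages(make_fixture_suite(cfg, seed = 4, outdir = d2))
  for (f in c("pollen.csv", "plants.csv", "ppe.csv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  pd <- suppressMessages(read_pollen_counts(file.path(d1, "pollen.csv")))
  sv <- read_plant_survey(file.path(d1, "plants.csv"))
  pt <- read_ppe_table(file.path(d1, "ppe.csv"))
  expect_s3_class(pd, "pollen_dataset")
  expect_equal(nrow(pd$counts), 60)
  expect_true(all(pd$totals == 2000))
  expect_equal(nrow(pt), 25)
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$preset, "field_study")
})

test_that("a degenerate mosaic keeps every band in the central habitat", {
  cfg <- synthetic_config("field_study", seed = 1,
                          mosaic_grain = c(region_poor = 0, region_rich = 0))
  L <- generate_landscape(cfg)
  for (i in seq_len(nrow(L$sites))) {
    own <- L$sites$habitat[i]
    expect_true(all(L$weights[i, , own] == 1))
  }
  # and the rich region's default mosaic is finer (higher mean band diversity)
  L2 <- generate_landscape(synthetic_config("field_study", seed = 1))
  shannon <- function(w) { w <- w[w > 0]; -sum(w * log(w)) }
  mean_div <- function(region) {
    idx <- which(L2$sites$region == region)
    mean(vapply(idx, function(i)
      mean(apply(L2$weights[i, , ], 1, shannon)), numeric(1)))
  }
  expect_gt(mean_div("region_rich"), mean_div("region_poor"))
})

test_that("survey structure matches the landscape: conservation and fine-scale contrast", {
  sim <- sim_field_study(seed = 8)
  part <- partition_datasets(sim$pollen)
  cr <- cumulative_richness(sim$survey, default_radius_grid())
  per_site_total <- table(sim$survey$site_id)
  expect_equal(unname(cr[names(per_site_total), ncol(cr)]),
               as.integer(per_site_total))

  # open sites in the rich region have most species near the central point
  frac100 <- function(ids) {
    s <- sim$survey[sim$survey$site_id %in% ids, ]
    mean(s$first_distance_m <= 100)
  }
  expect_gt(frac100(part$region_rich_open), 0.5)
  expect_gt(frac100(part$region_rich_open), frac100(part$region_rich_forest))
})

test_that("canopy interception raises the forest-site share of open-habitat pollen", {
  shares <- vapply(c(0.02, 0.5), function(ci) {
    mean(vapply(1:3, function(sd) {
      sim <- simulate_dataset(synthetic_config("field_study", seed = sd,
                                               canopy_interception = ci))
      L <- sim$landscape
      open_aff <- tapply(!L$pools$forest_affiliated[names(L$type_map)],
                         L$type_map, mean) > 0.5
      forest_sites <- L$sites$site_id[L$sites$habitat == "forest"]
      cs <- sim$pollen$counts[forest_sites, , drop = FALSE]
      mean(rowSums(cs[, open_aff[colnames(cs)], drop = FALSE]) / rowSums(cs))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(shares[2], shares[1])
})

test_that("subset richness ranks follow the planted pool ordering", {
  ok <- 0; n <- 5
  for (sd in 41:(40 + n)) {
    sim <- simulate_dataset(synthetic_config("field_study", seed = sd))
    part <- partition_datasets(sim$pollen)
    rar <- rarefy_dataset(sim$pollen, depth = 943, n_reps = 50, rng_seed = sd)
    rich <- setNames(rar$summary$richness_median, rar$summary$site_id)
    mr <- report_mean_richness(rich, part)
    ok <- ok + (mr["region_poor_forest"] < mr["region_poor_open"] &&
                mr["region_poor_open"] < mr["region_rich_forest"] &&
                mr["region_rich_forest"] < mr["region_rich_open"])
  }
  expect_gte(ok, n - 1)
})

test_that("unknown config fields are rejected and invariants enforced", {
  expect_error(synthetic_config("field_study", nonsense = 1), "unknown config field")
  expect_error(synthetic_config("field_study", epsilon = 1.2), "epsilon")
  expect_error(synthetic_config("field_study", pollen_sum = 100), "pollen_sum")
})
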