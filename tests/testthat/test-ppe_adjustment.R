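test_that("counts are divided by PPE where available and passed through otherwise", {
  pd <- toy_pollen()  # taxa Pinus, Picea, Poaceae; s1 = (5, 0, 2)
  pt <- ppe_table(c("Pinus", "Poaceae"), c(2, 0.5))
  adj <- suppressMessages(adjust_counts(pd, pt))
  expect_equal(unname(adj$values["s1", ]), c(2.5, 0, 4))
  expect_equal(unname(adj$adjusted), c(TRUE, FALSE, TRUE))

  # PPE = 1 everywhere is the identity
  pt1 <- ppe_table(colnames(pd$counts), c(1, 1, 1))
  adj1 <- adjust_counts(pd, pt1)
  expect_equal(adj1$values, pd$counts, ignore_attr = TRUE)

  expect_error(ppe_table("Pinus", -2), "ppe must be > 0")
})

test_that("adjustment shifts relative proportions against high producers", {
  sim <- sim_field_study(seed = 5)
  adj <- suppressMessages(adjust_counts(sim$pollen, sim$ppe))
  prop_raw <- prop.table(sim$pollen$counts, 1)
  prop_adj <- prop.table(adj$values, 1)
  expect_equal(unname(rowSums(prop_adj)), rep(1, nrow(prop_adj)))
  # taxa with ppe > 1 lose relative share on average, ppe < 1 gain
  hi <- sim$ppe$taxon[sim$ppe$ppe > 1.2]
  lo <- sim$ppe$taxon[sim$ppe$ppe < 0.8]
  if (length(hi) && length(lo)) {
    d_hi <- mean(colMeans(prop_adj[, hi, drop = FALSE]) -
                 colMeans(prop_raw[, hi, drop = FALSE]))
    d_lo <- mean(colMeans(prop_adj[, lo, drop = FALSE]) -
                 colMeans(prop_raw[, lo, drop = FALSE]))
    expect_lt(d_hi, 0)
    expect_gt(d_lo, 0)
  }
})

test_that("multinomial resampling detects a rare type with the closed-form probability", {
  # adjusted values {1, 99}, depth 20: P(detect rare) = 1 - 0.99^20 < 0.5,
  # so the median per-draw richness is 1
  counts <- rbind(s1 = c(99L, 1L))
  colnames(counts) <- c("common", "rare")
  pd <- pollen_dataset(counts, data.frame(site_id = "s1",
                                          region = "region_poor",
                                          habitat = "open"))
  adj <- adjust_counts(pd, ppe_table(c("common", "rare"), c(1, 1)))
  r <- resample_adjusted(adj, depth = 20, n_reps = 4e4, rng_seed = 9)
  expect_equal(r$summary$richness_median, 1)

  # single nonzero taxon: richness 1 at any depth
  counts1 <- rbind(s1 = c(50L, 0L)); colnames(counts1) <- c("a", "b")
  pd1 <- suppressMessages(pollen_dataset(counts1, data.frame(
    site_id = "s1", region = "region_poor", habitat = "open")))
  adj1 <- suppressMessages(adjust_counts(pd1, ppe_table("a", 2)))
  expect_equal(resample_adjusted(adj1, depth = 30, n_reps = 50,
                                 rng_seed = 1)$summary$richness_median, 1)
})

test_that("resampling probabilities are invariant to rescaling all PPEs", {
  pd <- sim_field_study(seed = 13)$pollen
  ppe1 <- ppe_table(colnames(pd$counts), rep(c(0.5, 2), length.out = ncol(pd$counts)))
  ppe2 <- ppe_table(ppe1$taxon, ppe1$ppe * 7.3)
  r1 <- resample_adjusted(adjust_counts(pd, ppe1), depth = 520, n_reps = 40,
                          rng_seed = 31)
  r2 <- resample_adjusted(adjust_counts(pd, ppe2), depth = 520, n_reps = 40,
                          rng_seed = 31)
  # the resampling law is identical; tiny floating-point differences in the
  # normalized probabilities can flip individual draws, so compare at the
  # summary level
  expect_lte(max(abs(r1$summary$richness_median - r2$summary$richness_median)), 1)
  expect_equal(mean(r1$summary$richness_median), mean(r2$summary$richness_median),
               tolerance = 0.01)
})

test_that("with unit PPEs, multinomial resampling tracks hypergeometric rarefaction", {
  pd <- sim_field_study(seed = 17)$pollen
  ppe1 <- ppe_table(colnames(pd$counts), rep(1, ncol(pd$counts)))
  adj <- adjust_counts(pd, ppe1)
  rm_ <- resample_adjusted(adj, depth = 520, n_reps = 100, rng_seed = 2)
  rh <- rarefy_dataset(pd, depth = 520, n_reps = 100, rng_seed = 2)
  m <- match(rm_$summary$site_id, rh$summary$site_id)
  # multinomial (with replacement) misses slightly more rare taxa, so its
  # richness is a little lower but within a few taxa of the hypergeometric
  diffs <- rh$summary$richness_median[m] - rm_$summary$richness_median
  expect_lt(mean(abs(diffs)), 3)
})

test_that("all-zero adjusted samples and the rounding mode are handled explicitly", {
  counts <- rbind(s1 = c(0L, 0L), s2 = c(700L, 100L))
  colnames(counts) <- c("a", "b")
  pd <- suppressMessages(pollen_dataset(counts, data.frame(
    site_id = c("s1", "s2"), region = "region_poor", habitat = "open")))
  adj <- suppressMessages(adjust_counts(pd, ppe_table("a", 2)))
  expect_error(resample_adjusted(adj, depth = 20), "all-zero.*s1")

  pd2 <- suppressMessages(pollen_dataset(counts[2, , drop = FALSE],
                                         data.frame(site_id = "s2",
                                                    region = "region_poor",
                                                    habitat = "open")))
  adj2 <- suppressMessages(adjust_counts(pd2, ppe_table("a", 2)))
  r <- resample_adjusted(adj2, depth = 100, n_reps = 30, rng_seed = 1,
                         method = "round-hypergeometric")
  expect_equal(nrow(r$summary), 1)
  expect_lte(r$summary$richness_median, 2)
})
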