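# direct a/(a+b+c) oracle, independent of vegan
jaccard_oracle <- function(Y) {
  n <- nrow(Y)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- sum(Y[i, ] == 1 & Y[j, ] == 1)
    bc <- sum(Y[i, ] != Y[j, ])
    D[i, j] <- if (a + bc == 0) 0 else 1 - a / (a + bc)
  }
  D
}

test_that("Jaccard dissimilarity matches the shared/unique presence oracle", {
  Y <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 0, 1, 0))
  D <- jaccard_dissimilarity(Y)
  expect_equal(D["s1", "s2"], 2 / 3)

  expect_equal(max(abs(jaccard_dissimilarity(rbind(a = c(1, 1), b = c(1, 1))))), 0)
  expect_equal(jaccard_dissimilarity(rbind(a = c(1, 0), b = c(0, 1)))[1, 2], 1)

  set.seed(8)
  for (k in 1:5) {
    Y <- random_presence(8, 15)
    expect_equal(unname(jaccard_dissimilarity(Y)), jaccard_oracle(Y),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  Yempty <- rbind(a = c(1, 1, 0), b = c(0, 0, 0), c = c(0, 0, 0))
  expect_message(D <- jaccard_dissimilarity(Yempty), "all-empty")
  expect_equal(D["a", "b"], 1)
  expect_equal(D["b", "c"], 0)

  expect_error(jaccard_dissimilarity(Y[1, , drop = FALSE]), "2 sites")
  expect_error(jaccard_dissimilarity(matrix(0, 3, 2)), "no taxon")
})

test_that("BD_Total of the symmetric three-site table matches the pairwise formula", {
  Y <- rbind(s1 = c(1, 1, 0), s2 = c(1, 0, 1), s3 = c(0, 1, 1))
  # pairwise Jaccard D = 2/3 for each pair
  # with sqrt transform: SS_total = (1/3) * 3 * (2/3) = 2/3, BD = 1/3
  bd <- beta_div_presence(Y, sqrt_transform = TRUE)
  expect_equal(bd$ss_total, 2 / 3)
  expect_equal(bd$bd_total, 1 / 3)
  expect_equal(unname(bd$lcbd), rep(1 / 3, 3))

  # without transform: SS_total = (1/3) * 3 * (4/9) = 4/9, BD = 2/9
  bd2 <- beta_div_presence(Y, sqrt_transform = FALSE)
  expect_equal(bd2$ss_total, 4 / 9)
  expect_equal(bd2$bd_total, 2 / 9)
})

test_that("Gower-diagonal SS_total equals the brute-force pairwise identity", {
  set.seed(42)
  for (k in 1:20) {
    n <- sample(3:30, 1); m <- sample(5:60, 1)
    Y <- random_presence(n, m)
    D <- sqrt(jaccard_dissimilarity(Y))
    bd <- beta_div(D, sqrt_transform = FALSE)  # D already transformed
    expect_lt(abs(bd$ss_total - ss_total_pairwise(D)), 1e-10)
    expect_equal(sum(bd$lcbd), 1, tolerance = 1e-12)
    expect_gte(bd$bd_total, 0)
    expect_lte(bd$bd_total, 1)
  }
})

test_that("degenerate tables yield BD 0 with undefined local contributions", {
  Y <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(1, 1, 0))
  bd <- suppressMessages(beta_div_presence(Y))
  expect_equal(bd$bd_total, 0)
  expect_true(all(is.na(bd$lcbd)))
  expect_error(beta_div(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("permutation p-values are bounded, near-uniform under the null, and minimal for a planted outlier", {
  set.seed(1)
  Y <- random_presence(30, 25, p = 0.5)
  tab <- lcbd_permutation_test(Y, n_perm = 199, rng_seed = 10)
  expect_true(all(tab$p_value >= 1 / 200 & tab$p_value <= 1))
  ks <- suppressWarnings(ks.test(tab$p_value, "punif"))
  expect_gt(ks$p.value, 0.001)

  # homogeneous matrix + one site with a unique species set
  Yh <- matrix(rep(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), each = 12), 12, 8)
  Yh[12, ] <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L)
  rownames(Yh) <- sprintf("s%02d", 1:12)
  tab2 <- lcbd_permutation_test(Yh, n_perm = 199, rng_seed = 3)
  expect_equal(which.min(tab2$p_value), 12L)
  expect_equal(which.max(tab2$lcbd), 12L)

  Yc <- matrix(1L, 5, 4, dimnames = list(sprintf("s%d", 1:5), NULL))
  tab3 <- suppressMessages(lcbd_permutation_test(Yc, n_perm = 49, rng_seed = 1))
  expect_true(all(tab3$p_value == 1))
})

test_that("plant BD at a radius uses the closed first-appearance interval and grows monotonically", {
  sv <- toy_survey()
  Y1000 <- presence_at_radius(sv, c("s1", "s2"), 1000)
  expect_equal(sum(Y1000), 4)  # every record used at the full radius

  Y40 <- presence_at_radius(sv, c("s1", "s2"), 40)
  expect_equal(unname(rowSums(Y40)), c(2, 1))

  # monotone structure: growing radius never removes a presence
  sim <- sim_field_study(seed = 9)
  ids <- sim$pollen$sites$site_id[1:8]
  radii <- c(20, 100, 400, 1000)
  Ys <- lapply(radii, function(r) presence_at_radius(sim$survey, ids, r))
  for (k in 2:length(Ys)) {
    shared <- intersect(colnames(Ys[[k - 1]]), colnames(Ys[[k]]))
    expect_true(all(Ys[[k]][, shared] >= Ys[[k - 1]][, shared]))
  }

  bd <- bd_total_at_radius(sim$survey, ids, 100)
  expect_s3_class(bd, "beta_div_result")
  expect_error(bd_total_at_radius(sv, c("s1", "s2"), 0.1), "no species within")
})
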