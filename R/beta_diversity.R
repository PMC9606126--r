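# Total-variance beta diversity of a presence-absence community table.
#
# The total sum of squares of the site-by-species table can be obtained from
# any pairwise dissimilarity matrix D via Gower centering of A = -D^2/2:
# the diagonal of the centred matrix holds each site's squared distance to
# the multivariate centroid (SS_i), their sum is SS_total, and the identity
# SS_total = (1/n) sum_{i<j} D_ij^2 holds exactly. BD_Total = SS_total/(n-1)
# is bounded in [0, 1] for indices bounded by 1 (after square-root
# transformation, which makes Jaccard Euclidean-embeddable so every SS_i is
# non-negative). LCBD_i = SS_i / SS_total is site i's share of the variance.

#' Jaccard dissimilarity between sites of a presence-absence table
#'
#' `D_ij = 1 - a / (a + b + c)` with `a` shared presences and `b`, `c`
#' presences unique to each site; joint absences are ignored. Pairs of
#' all-empty rows get `D = 0`, an empty vs a non-empty row gets `D = 1`
#' (both situations are reported via a message).
#'
#' @param Y binary sites-by-taxa matrix (rownames = site ids).
#' @return a symmetric dissimilarity matrix with zero diagonal and attribute
#'   `sqrt_transformed = FALSE`.
#' @export
jaccard_dissimilarity <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 sites", call. = FALSE)
  if (!all(Y %in% c(0, 1))) stop("Y must be binary (0/1)", call. = FALSE)
  if (sum(Y) == 0) stop("no taxon present at any site", call. = FALSE)
  empty <- rowSums(Y) == 0
  D <- matrix(0, nrow(Y), nrow(Y), dimnames = list(rownames(Y), rownames(Y)))
  if (any(!empty)) {
    Dsub <- as.matrix(vegan::vegdist(Y[!empty, , drop = FALSE],
                                     method = "jaccard", binary = TRUE))
    D[!empty, !empty] <- Dsub
  }
  if (any(empty)) {
    message(sum(empty), " all-empty site row(s); dissimilarity set to 1 ",
            "against non-empty sites and 0 among empty sites")
    D[empty, !empty] <- 1
    D[!empty, empty] <- 1
  }
  diag(D) <- 0
  attr(D, "sqrt_transformed") <- FALSE
  D
}

#' Total-variance beta diversity (BD_Total) and local contributions (LCBD)
#'
#' Computes `SS_total`, `BD_Total = SS_total / (n - 1)` and per-site `LCBD`
#' from a dissimilarity matrix via Gower centering. By default the
#' dissimilarities are square-root transformed first (recommended for
#' Jaccard, which is then Euclidean-embeddable so all per-site sums of
#' squares are non-negative and BD_Total is bounded by 1).
#'
#' @param D symmetric dissimilarity matrix (zero diagonal), e.g. from
#'   [jaccard_dissimilarity()]; a `dist` object is also accepted.
#' @param sqrt_transform square-root transform `D` before centering (default
#'   `TRUE`; ignored if `D` carries attribute `sqrt_transformed = TRUE`).
#' @return an object of class `beta_div_result`: `ss_total`, `bd_total`,
#'   `lcbd` (named vector summing to 1, or all `NA` when `ss_total` is 0),
#'   `n_sites`, `sqrt_transformed`.
#' @export
beta_div <- function(D, sqrt_transform = TRUE) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-10))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  if (any(D < -1e-12) || any(diag(D) != 0))
    stop("dissimilarities must be >= 0 with a zero diagonal", call. = FALSE)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 sites", call. = FALSE)
  already <- isTRUE(attr(D, "sqrt_transformed"))
  if (sqrt_transform && !already) D <- sqrt(D)
  A <- -0.5 * D^2
  rm_ <- rowMeans(A); cm_ <- colMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), cm_) + gm
  ss_i <- diag(G)
  ss_total <- sum(ss_i)
  if (ss_total > 1e-12) {
    lcbd <- ss_i / ss_total
  } else {
    ss_total <- max(ss_total, 0)
    lcbd <- rep(NA_real_, n)
    message("SS_total is zero (all sites identical); LCBD undefined")
  }
  names(lcbd) <- rownames(D)
  structure(list(ss_total = ss_total, bd_total = ss_total / (n - 1),
                 lcbd = lcbd, n_sites = n,
                 sqrt_transformed = sqrt_transform || already),
            class = "beta_div_result")
}

#' @export
print.beta_div_result <- function(x, ...) {
  cat("beta_div_result: n =", x$n_sites,
      " SS_total =", signif(x$ss_total, 4),
      " BD_Total =", signif(x$bd_total, 4),
      if (x$sqrt_transformed) " (sqrt-transformed D)" else "", "\n")
  invisible(x)
}

#' BD_Total and LCBD straight from a presence-absence table
#'
#' Convenience wrapper: [jaccard_dissimilarity()] then [beta_div()].
#'
#' @inheritParams jaccard_dissimilarity
#' @inheritParams beta_div
#' @return a [beta_div()] result.
#' @export
beta_div_presence <- function(Y, sqrt_transform = TRUE) {
  beta_div(jaccard_dissimilarity(Y), sqrt_transform = sqrt_transform)
}

#' Brute-force SS_total from pairwise dissimilarities
#'
#' Independent identity `SS_total = (1/n) sum_{i<j} D_ij^2`, useful as an
#' oracle for the Gower-centred computation.
#'
#' @param D symmetric dissimilarity matrix (already transformed as desired).
#' @return `SS_total` (numeric scalar).
#' @export
ss_total_pairwise <- function(D) {
  D <- as.matrix(D)
  sum(D[upper.tri(D)]^2) / nrow(D)
}

#' Permutation test for local contributions to beta diversity
#'
#' Null hypothesis: species are distributed independently of sites. Each
#' permutation shuffles the values within each taxon column independently;
#' `p_i = (#{perm: LCBD_perm_i >= LCBD_obs_i} + 1) / (n_perm + 1)`. A
#' Holm-adjusted column is returned alongside the raw p-values (no correction
#' is applied to the raw values themselves).
#'
#' @param Y binary sites-by-taxa matrix.
#' @param n_perm number of permutations (default 999).
#' @param rng_seed integer seed.
#' @param sqrt_transform as in [beta_div()].
#' @return data.frame with `site_id`, `lcbd`, `p_value`, `p_holm`.
#' @export
lcbd_permutation_test <- function(Y, n_perm = 999, rng_seed = 1,
                                  sqrt_transform = TRUE) {
  stopifnot(n_perm >= 1)
  Y <- as.matrix(Y)
  obs <- beta_div_presence(Y, sqrt_transform = sqrt_transform)
  n <- nrow(Y)
  if (all(is.na(obs$lcbd))) {
    message("degenerate (constant) matrix: all permutation p-values are 1")
    return(data.frame(site_id = rownames(Y), lcbd = NA_real_,
                      p_value = 1, p_holm = 1, stringsAsFactors = FALSE))
  }
  ge <- rep(0L, n)
  with_seed_(rng_seed, {
    for (b in seq_len(n_perm)) {
      Yp <- apply(Y, 2L, sample)
      lp <- suppressMessages(beta_div_presence(Yp, sqrt_transform = sqrt_transform)$lcbd)
      if (all(is.na(lp))) lp <- rep(1 / n, n)   # flat table: every site equal
      ge <- ge + (lp >= obs$lcbd - 1e-12)
    }
  })
  p <- (ge + 1) / (n_perm + 1)
  data.frame(site_id = rownames(Y), lcbd = obs$lcbd, p_value = p,
             p_holm = stats::p.adjust(p, "holm"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Plant presence-absence table at a given radius
#'
#' Species is present at a site iff its first-appearance distance is
#' `<= radius` (closed interval, matching cumulative richness curves).
#'
#' @param survey a [plant_survey()].
#' @param site_ids sites (rows) to include; sites without any record within
#'   the radius get an all-zero row.
#' @param radius metres, > 0.
#' @return binary sites-by-species matrix.
#' @export
presence_at_radius <- function(survey, site_ids, radius) {
  stopifnot(radius > 0)
  rec <- survey[survey$site_id %in% site_ids & survey$first_distance_m <= radius, ]
  species <- sort(unique(rec$species))
  if (length(species) == 0L)
    stop("no species within radius ", radius, " m at any of the sites", call. = FALSE)
  Y <- matrix(0L, length(site_ids), length(species),
              dimnames = list(site_ids, species))
  Y[cbind(match(rec$site_id, site_ids), match(rec$species, species))] <- 1L
  Y
}

#' Plant BD_Total at a given radius
#'
#' Builds the presence-absence table for the sites at the radius (species
#' present iff first appearance `<= radius`) and computes [beta_div()].
#'
#' @inheritParams presence_at_radius
#' @inheritParams beta_div
#' @return a [beta_div()] result.
#' @export
bd_total_at_radius <- function(survey, site_ids, radius, sqrt_transform = TRUE) {
  beta_div_presence(presence_at_radius(survey, site_ids, radius),
                    sqrt_transform = sqrt_transform)
}
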