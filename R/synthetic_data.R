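# Synthetic landscape, vegetation-survey, and pollen-rain generator with
# known ground truth, so every pipeline stage can be exercised and validated
# without field data.
#
# Geometry: concentric bands around each sampling point, delimited by the
# radius grid. Each band carries habitat mixing weights (forest/open); the
# central zone (<= 10 m) is pure site habitat and outer bands mix in the
# other habitat according to a region-specific mosaic grain. Species live in
# per-(region, habitat) pools with configurable overlap; per band, a species
# occupies it with probability 1 - exp(-commonness * habitat weight * band
# intensity), where the band intensity is annulus-area weighted and a
# fine-scale parameter boosts the central zone. The first occupied band
# defines the species' first-appearance distance (the survey); occupied
# bands also emit pollen, attenuated by an exponential dispersal kernel
# exp(-d / lambda) and weighted by annulus area, aggregated many-to-one from
# species to pollen types, multiplied by per-type pollen productivity, mixed
# with a long-distance regional background (boosted at forest sites by
# canopy interception), and finally drawn as a multinomial grain count.

band_geometry <- function(grid) {
  lo <- c(0, grid[-length(grid)])
  hi <- grid
  data.frame(lo = lo, hi = hi, mid = (lo + hi) / 2,
             area = pi * (hi^2 - lo^2), inner = hi <= 10)
}

#' Radius containing a given fraction of kernel-weighted pollen mass
#'
#' With annulus-area weighting in a uniform landscape, the pollen mass
#' originating within radius `R` of a point has a closed-form CDF for both
#' kernel families: `F(R) = 1 - (1 + R/lambda) exp(-R/lambda)` for the
#' exponential kernel `exp(-d/lambda)`, and `F(R) = 1 - exp(-(R/lambda)^2)`
#' for the Gaussian kernel `exp(-(d/lambda)^2)`. The effective source radius
#' `R_eff` is the radius where `F(R)/F(total_radius)` reaches `mass`
#' (default 85%); the CDF is inverted numerically.
#'
#' @param lambda kernel scale (metres), > 0.
#' @param total_radius outer limit of the landscape (default 1000 m).
#' @param mass mass fraction defining the source radius (default 0.85).
#' @param kernel `"exponential"` (default) or `"gaussian"`.
#' @return `R_eff` in metres.
#' @export
effective_source_radius <- function(lambda, total_radius = 1000, mass = 0.85,
                                    kernel = c("exponential", "gaussian")) {
  kernel <- match.arg(kernel)
  stopifnot(lambda > 0, mass > 0, mass < 1)
  Fm <- if (kernel == "exponential")
    function(R) 1 - (1 + R / lambda) * exp(-R / lambda)
  else
    function(R) 1 - exp(-(R / lambda)^2)
  f <- function(R) Fm(R) / Fm(total_radius) - mass
  stats::uniroot(f, c(1e-9, total_radius), tol = 1e-10)$root
}

#' Kernel scale whose effective source radius equals a target
#'
#' Inverse of [effective_source_radius()] in `lambda`.
#'
#' @param r_eff target source radius (metres).
#' @inheritParams effective_source_radius
#' @return `lambda` in metres.
#' @export
lambda_for_source_radius <- function(r_eff, total_radius = 1000, mass = 0.85,
                                     kernel = c("exponential", "gaussian")) {
  kernel <- match.arg(kernel)
  stopifnot(r_eff > 0, r_eff < total_radius)
  f <- function(l) effective_source_radius(l, total_radius, mass, kernel) - r_eff
  stats::uniroot(f, c(0.05, 5000), tol = 1e-8)$root
}

kernel_weights <- function(d, lambda, kernel) {
  if (kernel == "exponential") exp(-d / lambda) else exp(-(d / lambda)^2)
}

#' Configuration for the synthetic landscape generator
#'
#' Two presets bundle the study conditions:
#' \describe{
#'   \item{`field_study`}{two regions with contrasting richness (21 sites in
#'     the poor region: 10 forest + 11 open; 39 in the rich region: 19 forest
#'     + 20 open), habitat pools sized so open > forest and rich > poor,
#'     mosaic mixing finer in the rich region, many-to-one species-to-pollen
#'     aggregation, lognormal PPEs, long-distance background with canopy
#'     interception at forest sites, 2000 grains per sample.}
#'   \item{`strong_signal`}{40 open sites of one region, a single large
#'     species pool, 1:1 species-to-type map, PPE = 1, minimal background,
#'     and a kernel scale solved so the 85% source radius is 150 m - a
#'     configuration whose source area the radius scan should recover.}
#' }
#' Any field can be overridden through `...`.
#'
#' @param preset `"field_study"` or `"strong_signal"`.
#' @param seed integer master seed stored in the config.
#' @param ... named overrides of individual fields.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(preset = c("field_study", "strong_signal"),
                             seed = 1, ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "field_study") list(
    preset = "field_study",
    n_sites = c(region_poor.forest = 10, region_poor.open = 11,
                region_rich.forest = 19, region_rich.open = 20),
    pool_size = c(region_poor.forest = 42, region_poor.open = 100,
                  region_rich.forest = 115, region_rich.open = 155),
    habitat_overlap = 0.08,
    region_overlap = 0.30,
    commonness_sdlog = 0.6,
    fine_intensity = c(region_poor.forest = 1.0, region_poor.open = 1.4,
                       region_rich.forest = 1.1, region_rich.open = 2.6),
    outer_intensity = 3.0,
    outer_area_exponent = 1,
    band_quality_cv = 0.4,
    band_quality_scale = Inf,
    mosaic_grain = c(region_poor = 0.15, region_rich = 0.25),
    mosaic_asym = c(forest = 1, open = 0.35),
    band_concentration = 12,
    kernel = "exponential",
    lambda = c(forest = 45, open = 35),
    aggregation = 1.4,
    ppe_forest_mean = 2.2,
    ppe_open_mean = 0.8,
    ppe_sdlog = 0.35,
    dominance_sdlog_forest = 0.6,
    dominance_sdlog_open = 0.3,
    n_dominants = 3,
    dominant_boost = 18,
    dominant_commonness = NA,
    ppe_table_size = 25,
    epsilon = 0.015,
    canopy_interception = 0.05,
    pollen_sum = 2000,
    mass_quantile = 0.85,
    grid = default_radius_grid()
  ) else list(
    preset = "strong_signal",
    n_sites = c(region_poor.forest = 0, region_poor.open = 0,
                region_rich.forest = 0, region_rich.open = 40),
    pool_size = c(region_poor.forest = 0, region_poor.open = 0,
                  region_rich.forest = 0, region_rich.open = 600),
    habitat_overlap = 0,
    region_overlap = 0,
    commonness_sdlog = 0.4,
    fine_intensity = c(region_poor.forest = 0, region_poor.open = 0,
                       region_rich.forest = 0, region_rich.open = 0.05),
    outer_intensity = 3,
    outer_area_exponent = 0.5,
    band_quality_cv = 1.0,
    band_quality_scale = Inf,
    mosaic_grain = c(region_poor = 0, region_rich = 0),
    mosaic_asym = c(forest = 1, open = 1),
    band_concentration = 12,
    kernel = "gaussian",
    lambda = c(forest = lambda_for_source_radius(150, kernel = "gaussian"),
               open = lambda_for_source_radius(150, kernel = "gaussian")),
    aggregation = 1,
    ppe_forest_mean = 1,
    ppe_open_mean = 1,
    ppe_sdlog = 0,
    dominance_sdlog_forest = 0,
    dominance_sdlog_open = 0,
    n_dominants = 2,
    dominant_boost = 1,
    dominant_commonness = 60,
    ppe_table_size = 25,
    epsilon = 0.02,
    canopy_interception = 0,
    pollen_sum = 2000,
    mass_quantile = 0.85,
    grid = default_radius_grid()
  )
  cfg$seed <- as.integer(seed)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm, call. = FALSE)
    if (length(dots[[nm]]) == length(cfg[[nm]]) || nm == "grid")
      cfg[[nm]] <- dots[[nm]]
    else cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
  }
  stopifnot(cfg$lambda > 0, cfg$epsilon >= 0, cfg$epsilon < 1,
            cfg$canopy_interception >= 0, cfg$canopy_interception <= 1,
            cfg$pollen_sum >= 943, all(cfg$mosaic_grain >= 0),
            all(cfg$mosaic_grain <= 1), cfg$aggregation >= 1)
  check_radius_grid(cfg$grid)
  class(cfg) <- "synthetic_config"
  cfg
}

pool_key <- function(region, habitat) paste(region, habitat, sep = ".")

# species pools with within-region habitat overlap and cross-region overlap
build_species_pools <- function(config) {
  usize <- function(r) {
    pf <- config$pool_size[[pool_key(r, "forest")]]
    po <- config$pool_size[[pool_key(r, "open")]]
    s <- round(config$habitat_overlap * min(pf, po))
    c(total = pf + po - s, forest = pf, open = po, shared = s)
  }
  up <- usize("region_poor"); ur <- usize("region_rich")
  shared_regions <- round(config$region_overlap * min(up["total"], ur["total"]))
  n_species <- up["total"] + ur["total"] - shared_regions
  species <- sprintf("sp%04d", seq_len(n_species))
  poor_universe <- seq_len(up["total"])
  rich_universe <- c(seq_len(shared_regions),
                     seq.int(up[["total"]] + 1, length.out = ur["total"] - shared_regions))
  member <- matrix(FALSE, n_species, 4,
                   dimnames = list(species, c(pool_key("region_poor", "forest"),
                                              pool_key("region_poor", "open"),
                                              pool_key("region_rich", "forest"),
                                              pool_key("region_rich", "open"))))
  assign_habitats <- function(universe, sizes, region) {
    if (sizes["total"] == 0) return()
    ord <- sample(universe)
    if (sizes["forest"] > 0)
      member[ord[seq_len(sizes["forest"])], pool_key(region, "forest")] <<- TRUE
    if (sizes["open"] > 0)
      member[ord[seq.int(sizes["total"] - sizes["open"] + 1, sizes["total"])],
             pool_key(region, "open")] <<- TRUE
  }
  assign_habitats(poor_universe, up, "region_poor")
  assign_habitats(rich_universe, ur, "region_rich")
  q <- stats::rlnorm(n_species, meanlog = -config$commonness_sdlog^2 / 2,
                     sdlog = config$commonness_sdlog)
  # pollen-production skew: canopy trees dominate biomass, so
  # forest-affiliated species get a heavier-tailed abundance multiplier
  # (applies to pollen emission only, not to survey occupancy)
  in_forest <- rowSums(member[, grep("forest", colnames(member)), drop = FALSE]) > 0
  sk <- ifelse(in_forest, config$dominance_sdlog_forest, config$dominance_sdlog_open)
  skew <- stats::rlnorm(n_species, meanlog = -sk^2 / 2, sdlog = sk)
  # a few canopy dominants per region carry most of the pollen mass; they
  # are also ubiquitous (high commonness), so the matrix rain they produce
  # is nearly constant from site to site
  if (config$n_dominants > 0) {
    for (r in REGIONS) {
      fp <- which(member[, pool_key(r, "forest")])
      if (length(fp) == 0) fp <- which(member[, pool_key(r, "open")])
      if (length(fp) > 0) {
        dom <- sample(fp, min(config$n_dominants, length(fp)))
        skew[dom] <- config$dominant_boost
        if (is.finite(config$dominant_commonness))
          q[dom] <- config$dominant_commonness
      }
    }
  }
  list(species = species, q = stats::setNames(q, species),
       skew = stats::setNames(skew, species),
       forest_affiliated = stats::setNames(in_forest, species), member = member)
}

# consecutive genus-like blocking of species into pollen types
build_type_map <- function(species, aggregation) {
  n <- length(species)
  if (aggregation <= 1) {
    sizes <- rep(1L, n)
  } else {
    sizes <- integer(0)
    while (sum(sizes) < n) sizes <- c(sizes, 1L + stats::rpois(n, aggregation - 1))
    cum <- cumsum(sizes)
    sizes <- sizes[seq_len(which(cum >= n)[1])]
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  }
  type <- rep(sprintf("pt%04d", seq_along(sizes)), sizes)
  stats::setNames(type, species)
}

#' Generate a synthetic landscape
#'
#' Draws the species pools, commonness values, species-to-pollen-type map,
#' PPEs, and per-site band-wise habitat mixing weights; also computes the
#' ground-truth effective source radius from the kernel scale.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (default: the config's seed).
#' @return a list of class `synthetic_landscape` with elements `sites`,
#'   `bands`, `weights` (sites x bands x habitat array), `pools`,
#'   `type_map`, `ppe_full`, `truth` and `config`.
#' @export
generate_landscape <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed_(child_seed(seed, "landscape"), {
    bands <- band_geometry(config$grid)
    nb <- nrow(bands)
    keys <- names(config$n_sites)[config$n_sites > 0]
    sites <- do.call(rbind, lapply(keys, function(k) {
      rh <- strsplit(k, ".", fixed = TRUE)[[1]]
      data.frame(region = rh[1], habitat = rh[2],
                 stringsAsFactors = FALSE)[rep(1, config$n_sites[[k]]), ]
    }))
    sites$site_id <- sprintf("site%02d", seq_len(nrow(sites)))
    sites <- sites[, c("site_id", "region", "habitat")]
    rownames(sites) <- NULL

    pools <- build_species_pools(config)
    type_map <- build_type_map(pools$species, config$aggregation)
    types <- unique(type_map)
    # tree (forest-affiliated) pollen types over-produce: PPE mean by the
    # habitat affinity of the type's member species
    forest_member <- rowSums(pools$member[, grep("forest", colnames(pools$member)),
                                          drop = FALSE]) > 0
    any_member <- rowSums(pools$member) > 0
    affinity <- tapply(forest_member & any_member, type_map, sum) /
                pmax(1, tapply(any_member, type_map, sum))
    ppe_mean <- ifelse(affinity[types] > 0.5,
                       config$ppe_forest_mean, config$ppe_open_mean)
    ppe_full <- stats::setNames(
      stats::rlnorm(length(types), log(ppe_mean), config$ppe_sdlog), types)

    W <- array(0, dim = c(nrow(sites), nb, 2),
               dimnames = list(sites$site_id, NULL, HABITATS))
    conc <- config$band_concentration
    for (i in seq_len(nrow(sites))) {
      own <- sites$habitat[i]
      other <- setdiff(HABITATS, own)
      grain <- config$mosaic_grain[[sites$region[i]]] *
               config$mosaic_asym[[own]]
      m <- ifelse(bands$inner, 0, grain * (1 - exp(-bands$mid / 200)))
      w_other <- ifelse(m <= 0, 0, ifelse(m >= 1, 1,
                        stats::rbeta(nb, conc * m, conc * (1 - m))))
      W[i, , own] <- 1 - w_other
      W[i, , other] <- w_other
    }
    r_eff <- vapply(config$lambda, effective_source_radius, numeric(1),
                    total_radius = max(config$grid), mass = config$mass_quantile,
                    kernel = config$kernel)
    truth <- list(lambda = as.list(config$lambda),
                  kernel = config$kernel,
                  r_eff = if (length(unique(r_eff)) == 1) unname(r_eff[1])
                          else as.list(r_eff),
                  mass_quantile = config$mass_quantile,
                  pool_size = as.list(config$pool_size),
                  n_species = length(pools$species),
                  n_types = length(types),
                  preset = config$preset, seed = as.integer(seed))
    structure(list(sites = sites, bands = bands, weights = W, pools = pools,
                   type_map = type_map, ppe_full = ppe_full, truth = truth,
                   config = config),
              class = "synthetic_landscape")
  })
}

# per-band occupancy intensity profile for one site
band_intensity <- function(config, bands, region, site_habitat) {
  fine <- config$fine_intensity[[pool_key(region, site_habitat)]]
  outer <- if (length(config$outer_intensity) == 1) config$outer_intensity
           else config$outer_intensity[[pool_key(region, site_habitat)]]
  shape <- numeric(nrow(bands))
  shape[bands$inner] <- fine * bands$area[bands$inner] / sum(bands$area[bands$inner])
  # outer accumulation of new species saturates with radius when the
  # exponent is < 1 (area^exponent weighting)
  ae <- bands$area[!bands$inner]^config$outer_area_exponent
  shape[!bands$inner] <- outer * ae / sum(ae)
  shape
}

#' Simulate the vegetation survey over a synthetic landscape
#'
#' For every site and species of the site's regional pools, per-band
#' occupancy is drawn independently; the innermost occupied band gives the
#' species' first-appearance distance (recorded as the band's outer radius)
#' and the habitat component that triggered it gives the habitat of record.
#' Per-band occupied masses (commonness x habitat weight x relative band
#' area) are attached for the pollen simulation.
#'
#' @param landscape a [generate_landscape()] result.
#' @param seed integer seed (default: derived from the config seed).
#' @return a [plant_survey()] with attribute `occupancy_mass` (per-site list
#'   of species-by-band mass matrices).
#' @export
simulate_plant_survey <- function(landscape, seed = landscape$config$seed) {
  config <- landscape$config
  bands <- landscape$bands
  pools <- landscape$pools
  nb <- nrow(bands)
  area_rel <- bands$area / sum(bands$area)
  rows <- vector("list", nrow(landscape$sites))
  mass_list <- vector("list", nrow(landscape$sites))
  names(mass_list) <- landscape$sites$site_id
  for (i in seq_len(nrow(landscape$sites))) {
    sid <- landscape$sites$site_id[i]
    region <- landscape$sites$region[i]
    shape <- band_intensity(config, bands, region, landscape$sites$habitat[i])
    member_keys <- paste(region, HABITATS, sep = ".")
    in_region <- rowSums(pools$member[, member_keys, drop = FALSE]) > 0
    sp <- pools$species[in_region]
    q <- pools$q[sp]
    occ <- array(FALSE, dim = c(length(sp), nb, 2),
                 dimnames = list(sp, NULL, HABITATS))
    with_seed_(child_seed(seed, paste0("survey:", sid)), {
      # per-band habitat-quality patchiness (gamma, mean 1): the same local
      # richness anomaly is seen by the survey and emitted as pollen; the
      # patchiness can fade with distance (landscapes homogenize at broad
      # scales) on the band_quality_scale
      cvb <- config$band_quality_cv * exp(-bands$mid / config$band_quality_scale)
      g <- ifelse(cvb > 1e-8,
                  stats::rgamma(nb, shape = 1 / cvb^2, rate = 1 / cvb^2), 1)
      for (h in HABITATS) {
        mem <- pools$member[sp, pool_key(region, h)]
        if (!any(mem)) next
        w <- landscape$weights[i, , h]
        p <- 1 - exp(-outer(q[mem], shape * g * w))
        occ[mem, , h] <- matrix(stats::runif(length(p)) < p, nrow = sum(mem))
      }
      occ_any <- occ[, , 1] | occ[, , 2]
      first <- apply(occ_any, 1L, function(z) if (any(z)) which(z)[1] else NA_integer_)
      found <- which(!is.na(first))
      hab_rec <- character(length(found))
      for (j in seq_along(found)) {
        s <- found[j]; b <- first[s]
        cand <- HABITATS[occ[s, b, ]]
        hab_rec[j] <- if (length(cand) == 1) cand
                      else cand[which.max(landscape$weights[i, b, cand])]
      }
      rows[[i]] <- data.frame(site_id = sid, species = sp[found],
                              first_distance_m = bands$hi[first[found]],
                              habitat = hab_rec, stringsAsFactors = FALSE)
      w_comb <- landscape$weights[i, , "forest"] * occ[, , "forest"] +
                landscape$weights[i, , "open"] * occ[, , "open"]
      mass_list[[sid]] <- q * w_comb * rep(area_rel, each = length(sp))
    })
  }
  survey <- plant_survey(do.call(rbind, rows))
  attr(survey, "occupancy_mass") <- mass_list
  survey
}

#' Simulate pollen counts over a synthetic landscape and survey
#'
#' Expected pollen-type proportions at a site combine the kernel- and
#' area-weighted masses of the occupied bands (from the survey), the
#' species-to-type aggregation, per-type PPE, and a long-distance regional
#' background; forest sites receive extra background in proportion to the
#' canopy interception factor. Counts are one multinomial draw of
#' `pollen_sum` grains per site.
#'
#' @param landscape a [generate_landscape()] result.
#' @param survey the matching [simulate_plant_survey()] result.
#' @param seed integer seed.
#' @return a [pollen_dataset()].
#' @export
simulate_pollen <- function(landscape, survey, seed = landscape$config$seed) {
  config <- landscape$config
  mass_list <- attr(survey, "occupancy_mass")
  if (is.null(mass_list)) stop("survey lacks occupancy masses; use simulate_plant_survey()",
                               call. = FALSE)
  # dispersal kernel per taxon class: trees (forest-affiliated) travel
  # farther than herbs
  lam <- config$lambda
  if (length(lam) == 1) lam <- c(forest = unname(lam), open = unname(lam))
  kernel_forest <- kernel_weights(landscape$bands$mid, lam[["forest"]], config$kernel)
  kernel_open <- kernel_weights(landscape$bands$mid, lam[["open"]], config$kernel)
  type_of <- landscape$type_map
  types <- sort(unique(type_of))
  ppe <- landscape$ppe_full[types]

  regional <- sapply(REGIONS, function(r) {
    keys <- paste(r, HABITATS, sep = ".")
    in_r <- rowSums(landscape$pools$member[, keys, drop = FALSE]) > 0
    m <- tapply(landscape$pools$q * landscape$pools$skew * in_r,
                type_of, sum)[types]
    m[is.na(m)] <- 0
    m <- m * ppe
    if (sum(m) > 0) m / sum(m) else m
  })

  counts <- matrix(0L, nrow(landscape$sites), length(types),
                   dimnames = list(landscape$sites$site_id, types))
  for (i in seq_len(nrow(landscape$sites))) {
    sid <- landscape$sites$site_id[i]
    region <- landscape$sites$region[i]
    mass <- mass_list[[sid]]
    fa <- landscape$pools$forest_affiliated[rownames(mass)]
    m_s <- ifelse(fa, as.vector(mass %*% kernel_forest),
                      as.vector(mass %*% kernel_open)) *
           landscape$pools$skew[rownames(mass)]
    M_t <- tapply(m_s, type_of[rownames(mass)], sum)[types]
    M_t[is.na(M_t)] <- 0
    M_t <- M_t * ppe
    eps <- config$epsilon
    if (landscape$sites$habitat[i] == "forest")
      eps <- eps + (1 - eps) * config$canopy_interception
    local <- if (sum(M_t) > 0) M_t / sum(M_t) else M_t
    p <- (1 - eps) * local + eps * regional[, region]
    if (sum(p) <= 0) stop("degenerate all-zero pollen proportions at ", sid,
                          call. = FALSE)
    counts[i, ] <- with_seed_(child_seed(seed, paste0("pollen:", sid)),
                              as.integer(stats::rmultinom(1, config$pollen_sum,
                                                          p / sum(p))))
  }
  suppressMessages(pollen_dataset(counts, landscape$sites))
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates [generate_landscape()], [simulate_plant_survey()] and
#' [simulate_pollen()] under child seeds of one master seed, and extracts the
#' emitted PPE table (the `ppe_table_size` regionally most abundant types,
#' mirroring a partial-coverage PPE set).
#'
#' @param config a [synthetic_config()].
#' @param seed integer master seed (default: the config's).
#' @return a list of class `synthetic_dataset`: `pollen` (a
#'   [pollen_dataset()]), `survey` (a [plant_survey()]), `ppe` (a
#'   [ppe_table()]), `truth` (ground-truth list incl. `r_eff`), `landscape`.
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  landscape <- generate_landscape(config, seed)
  survey <- simulate_plant_survey(landscape, seed)
  pollen <- simulate_pollen(landscape, survey, seed)
  abundance <- colSums(pollen$counts)
  top <- names(sort(abundance, decreasing = TRUE))
  top <- utils::head(top, min(config$ppe_table_size, length(top)))
  ppe <- ppe_table(top, unname(landscape$ppe_full[top]))
  truth <- landscape$truth
  truth$seed <- as.integer(seed)
  structure(list(pollen = pollen, survey = survey, ppe = ppe,
                 truth = truth, landscape = landscape),
            class = "synthetic_dataset")
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits `pollen.csv`, `plants.csv`, `ppe.csv` (matching the package's I/O
#' contracts) and `truth.json` with the generator's ground truth. Output is
#' byte-identical for identical config and seed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer master seed.
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of file paths.
#' @export
make_fixture_suite <- function(config, seed = config$seed, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config, seed)
  paths <- list(pollen = file.path(outdir, "pollen.csv"),
                plants = file.path(outdir, "plants.csv"),
                ppe = file.path(outdir, "ppe.csv"),
                truth = file.path(outdir, "truth.json"))
  write_pollen_counts(sim$pollen, paths$pollen, seed = seed)
  write_plant_survey(sim$survey, paths$plants, seed = seed)
  write_ppe_table(sim$ppe, paths$ppe, seed = seed)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
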