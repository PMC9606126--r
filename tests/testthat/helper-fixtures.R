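# small in-code fixtures shared across test files

toy_pollen <- function() {
  counts <- rbind(s1 = c(5L, 0L, 2L), s2 = c(1L, 1L, 1L))
  colnames(counts) <- c("Pinus", "Picea", "Poaceae")
  suppressMessages(pollen_dataset(
    counts,
    data.frame(site_id = c("s1", "s2"),
               region = c("region_poor", "region_poor"),
               habitat = c("forest", "open"))))
}

toy_survey <- function() {
  plant_survey(data.frame(
    site_id = c("s1", "s1", "s1", "s2"),
    species = c("Quercus robur", "Festuca ovina", "Thymus", "Quercus robur"),
    first_distance_m = c(0.5, 40, 900, 10),
    habitat = c("forest", "open", "open", "forest")))
}

# survey in which site "sX" has a known cumulative richness profile: one
# record per species at the given distances
survey_from_distances <- function(dist_by_site, habitat = "open") {
  rows <- do.call(rbind, lapply(names(dist_by_site), function(sid) {
    d <- dist_by_site[[sid]]
    data.frame(site_id = sid,
               species = sprintf("%s_sp%03d", sid, seq_along(d)),
               first_distance_m = d, habitat = habitat,
               stringsAsFactors = FALSE)
  }))
  plant_survey(rows)
}

random_presence <- function(n, m, p = 0.4) {
  Y <- matrix(rbinom(n * m, 1, p), n, m,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("t%02d", seq_len(m))))
  # ensure no empty rows/columns for clean oracle comparisons
  for (i in which(rowSums(Y) == 0)) Y[i, sample(m, 1)] <- 1L
  Y
}

sim_field_study <- function(seed = 1, ...) {
  simulate_dataset(synthetic_config("field_study", seed = seed, ...))
}
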