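#!/usr/bin/env Rscript
# Stage 5 - the source area of pollen diversity.
#
# At every radius of the default grid (0.5-1000 m), pollen diversity is
# regressed on the matching plant diversity: rarefied richness per site
# within each dataset, BD_Total across the six datasets, and LCBD per site.
# The source area is the radius with the highest adjusted R^2. Survey
# completeness against the regional reference pools closes the report.

library(pollendiv)

seed <- 1
pollen <- read_pollen_counts("results/fixtures/pollen.csv")
survey <- read_plant_survey("results/fixtures/plants.csv")
part <- partition_datasets(pollen)
grid <- default_radius_grid()

rar <- rarefy_dataset(pollen, depth = 943, n_reps = 100, rng_seed = seed)
rich <- setNames(rar$summary$richness_median, rar$summary$site_id)

all_rows <- list(); sa_rows <- list()
for (d in names(part)) {
  scan <- fit_scaling_regressions(rich, survey, grid, part[[d]])
  df <- scan$summary; df$scan <- paste0("richness:", d)
  all_rows[[length(all_rows) + 1]] <- df
  sa_rows[[length(sa_rows) + 1]] <- data.frame(
    dataset = d, kind = "richness", source_area_m = scan$source_area_m)
}

pollen_bd <- vapply(part, function(ids)
  beta_div_presence(rar$presence[ids, , drop = FALSE])$bd_total, numeric(1))
bd_scan <- bd_total_scan(pollen_bd, survey, part, grid)
df <- bd_scan$summary; df$scan <- "bd_total:all"
all_rows[[length(all_rows) + 1]] <- df
sa_rows[[length(sa_rows) + 1]] <- data.frame(
  dataset = "all", kind = "bd_total", source_area_m = bd_scan$source_area_m)

scaling <- do.call(rbind, all_rows)
source_areas <- do.call(rbind, sa_rows)
write.csv(scaling, "results/scaling.csv", row.names = FALSE)
write.csv(source_areas, "results/source_areas.csv", row.names = FALSE)

cat("Source areas (radius of maximal adjusted R^2):\n")
print(source_areas, row.names = FALSE)

best <- scaling[scaling$scan == "bd_total:all", ]
best <- best[which.max(ifelse(is.na(best$adj_r2), -Inf, best$adj_r2)), ]
cat("\nBD_Total scan peak: adj R^2 =", round(best$adj_r2, 2),
    "at", best$radius, "m (p =", signif(best$p_value, 2), ")\n")

cat("\nSurvey completeness against the regional reference pools:\n")
cat("  species-poor region:", completeness_ratio(799, 1477), "%\n")
cat("  species-rich region:", completeness_ratio(1098, 2045), "%\n")
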