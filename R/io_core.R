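# Domain containers and delimited-file I/O shared by every analysis stage.
#
# Three tabular contracts:
#   * pollen counts: wide table (site_id, region, habitat, <taxon columns>)
#   * plant survey : long table (site_id, species, first_distance_m, habitat)
#   * PPE table    : two columns (taxon, ppe)
# Files are comma- or tab-delimited by extension (.csv/.tsv), UTF-8, decimal
# point; lines starting with '#' are run-metadata comments and are skipped.

REGIONS  <- c("region_poor", "region_rich")
HABITATS <- c("forest", "open")

#' Construct a validated pollen dataset
#'
#' A pollen dataset is a sites-by-pollen-type matrix of non-negative integer
#' grain counts plus per-site metadata: a region label (`region_poor` /
#' `region_rich`, the low/high-diversity study-region analogue) and a habitat
#' class (`forest` / `open`).
#'
#' @param counts integer matrix, rows = sites (rownames = site ids),
#'   columns = pollen types.
#' @param sites data.frame with columns `site_id`, `region`, `habitat`,
#'   one row per row of `counts`, in the same order.
#' @return an object of class `pollen_dataset` with elements `counts`,
#'   `sites`, `taxa` and per-site `totals` (row sums).
#' @export
pollen_dataset <- function(counts, sites) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) rownames(counts) <- sites$site_id
  validate_pollen_inputs(counts, sites)
  storage.mode(counts) <- "integer"
  sites <- data.frame(site_id = as.character(sites$site_id),
                      region = as.character(sites$region),
                      habitat = as.character(sites$habitat),
                      stringsAsFactors = FALSE)
  structure(list(counts = counts, sites = sites,
                 taxa = colnames(counts), totals = rowSums(counts)),
            class = "pollen_dataset")
}

validate_pollen_inputs <- function(counts, sites) {
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("pollen dataset is empty", call. = FALSE)
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon names: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  if (any(is.na(sites$region)) || !all(sites$region %in% REGIONS))
    stop("region must be one of: ", paste(REGIONS, collapse = ", "), call. = FALSE)
  if (any(is.na(sites$habitat)) || !all(sites$habitat %in% HABITATS))
    stop("habitat must be one of: ", paste(HABITATS, collapse = ", "), call. = FALSE)
  bad <- which(!is_wholenumber(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("counts must be non-negative integers; first offender at site '",
         rownames(counts)[bad[1, 1]], "', taxon '", colnames(counts)[bad[1, 2]],
         "' (value ", counts[bad[1, 1], bad[1, 2]], ")", call. = FALSE)
  zero_taxa <- colnames(counts)[colSums(counts) == 0]
  if (length(zero_taxa) > 0L)
    message("retaining ", length(zero_taxa), " all-zero taxon column(s): ",
            paste(utils::head(zero_taxa, 5L), collapse = ", "),
            if (length(zero_taxa) > 5L) ", ..." else "")
  invisible(TRUE)
}

#' @export
print.pollen_dataset <- function(x, ...) {
  cat("pollen_dataset:", nrow(x$counts), "sites x", ncol(x$counts), "pollen types\n")
  cat("  grain sums:", min(x$totals), "-", max(x$totals), "\n")
  tab <- table(x$sites$region, x$sites$habitat)
  print(tab)
  invisible(x)
}

#' Read a wide site-by-pollen-type count table
#'
#' Expects columns `site_id`, `region`, `habitat` followed by one integer
#' column per pollen type. All-zero taxon columns are retained (and noted).
#'
#' @param path path to a `.csv` or `.tsv` file.
#' @return a [pollen_dataset()].
#' @export
read_pollen_counts <- function(path) {
  df <- read_delim_file(path)
  need <- c("site_id", "region", "habitat")
  if (!all(need %in% names(df)))
    stop("pollen table must start with columns: ", paste(need, collapse = ", "), call. = FALSE)
  taxa <- setdiff(names(df), need)
  if (length(taxa) == 0L) stop("no taxon columns found in ", path, call. = FALSE)
  counts <- as.matrix(df[, taxa, drop = FALSE])
  rownames(counts) <- df$site_id
  pollen_dataset(counts, df[, need])
}

#' Write a pollen dataset to a delimited file
#'
#' @param x a [pollen_dataset()].
#' @param path output path (`.csv` or `.tsv`).
#' @param seed optional integer recorded in the metadata comment header.
#' @return `path`, invisibly.
#' @export
write_pollen_counts <- function(x, path, seed = NULL) {
  df <- data.frame(x$sites, x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  write_delim_file(df, path, provenance_header("pollen counts", seed))
}

provenance_header <- function(what, seed = NULL) {
  c(paste0("pollendiv ", as.character(utils::packageVersion("pollendiv")), ": ", what),
    if (!is.null(seed)) paste0("seed: ", seed))
}

#' Construct a validated plant survey
#'
#' Long-format vegetation records: per site and species, the radius (m) at
#' which the species first appeared when surveying outward from the pollen
#' sampling point, and the habitat in which that first record was made.
#' Distances are metres in \[0, 1000\]; radius semantics downstream are
#' "first appearance at distance <= r" (closed interval).
#'
#' @param records data.frame with columns `site_id`, `species`,
#'   `first_distance_m`, `habitat`.
#' @return an object of class `plant_survey` (a validated data.frame).
#' @export
plant_survey <- function(records) {
  need <- c("site_id", "species", "first_distance_m", "habitat")
  if (!all(need %in% names(records)))
    stop("plant survey needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  records <- records[, need]
  records$site_id <- as.character(records$site_id)
  records$species <- as.character(records$species)
  records$habitat <- as.character(records$habitat)
  d <- records$first_distance_m
  if (any(!is.finite(d) | d < 0 | d > 1000)) {
    bad <- which(!is.finite(d) | d < 0 | d > 1000)
    stop("first_distance_m must lie in [0, 1000] m; offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(records$site_id, records$species, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (site, species) records: ",
         paste(gsub("\r", " / ", utils::head(dup, 5L)), collapse = "; "),
         call. = FALSE)
  }
  class(records) <- c("plant_survey", "data.frame")
  records
}

#' Read a long-format plant survey table
#'
#' @param path path to a `.csv` or `.tsv` file with columns `site_id`,
#'   `species`, `first_distance_m`, `habitat`.
#' @return a [plant_survey()].
#' @export
read_plant_survey <- function(path) plant_survey(read_delim_file(path))

#' Write a plant survey to a delimited file
#' @param x a [plant_survey()].
#' @param path output path.
#' @param seed optional integer recorded in the header comment.
#' @export
write_plant_survey <- function(x, path, seed = NULL) {
  write_delim_file(as.data.frame(x), path, provenance_header("plant survey", seed))
}

#' Construct a pollen productivity estimate (PPE) table
#'
#' Relative pollen productivity per pollen type; dividing counts by PPE
#' balances over-producing taxa (e.g. wind-pollinated trees).
#'
#' @param taxon character vector of pollen-type names.
#' @param ppe positive numeric vector of the same length.
#' @param reference optional name of the reference taxon (PPE = 1 by
#'   convention).
#' @return an object of class `ppe_table` (a data.frame `taxon`, `ppe`).
#' @export
ppe_table <- function(taxon, ppe, reference = NULL) {
  stopifnot(length(taxon) == length(ppe))
  if (any(!is.finite(ppe) | ppe <= 0))
    stop("ppe must be > 0 for all taxa; offenders: ",
         paste(taxon[!is.finite(ppe) | ppe <= 0], collapse = ", "), call. = FALSE)
  if (anyDuplicated(taxon))
    stop("duplicate taxon in PPE table: ",
         paste(unique(taxon[duplicated(taxon)]), collapse = ", "), call. = FALSE)
  structure(data.frame(taxon = as.character(taxon), ppe = as.numeric(ppe),
                       stringsAsFactors = FALSE),
            reference = reference, class = c("ppe_table", "data.frame"))
}

#' Read a two-column PPE table (taxon, ppe)
#' @param path path to a `.csv` or `.tsv` file.
#' @return a [ppe_table()].
#' @export
read_ppe_table <- function(path) {
  df <- read_delim_file(path)
  if (!all(c("taxon", "ppe") %in% names(df)))
    stop("PPE table needs columns taxon, ppe", call. = FALSE)
  ppe_table(df$taxon, df$ppe)
}

#' Write a PPE table
#' @param x a [ppe_table()].
#' @param path output path.
#' @param seed optional integer recorded in the header comment.
#' @export
write_ppe_table <- function(x, path, seed = NULL) {
  write_delim_file(as.data.frame(x), path, provenance_header("PPE table", seed))
}

#' Partition sites into the six analysis datasets
#'
#' The study design compares, for each region, the complete dataset (all
#' sites) with its forest-only and open-only subsets: six datasets in total.
#' The partition is a pure function of the site metadata and is invariant to
#' site ordering.
#'
#' @param pollen a [pollen_dataset()].
#' @return a named list of sorted site-id vectors with class
#'   `dataset_partition`; names are `region_poor_complete`,
#'   `region_poor_forest`, `region_poor_open`, `region_rich_complete`,
#'   `region_rich_forest`, `region_rich_open`.
#' @export
partition_datasets <- function(pollen) {
  s <- pollen$sites
  out <- list()
  for (r in REGIONS) {
    in_r <- s$region == r
    out[[paste0(r, "_complete")]] <- sort(s$site_id[in_r])
    for (h in HABITATS)
      out[[paste0(r, "_", h)]] <- sort(s$site_id[in_r & s$habitat == h])
    if (!any(in_r))
      warning("no sites in ", r, "; its datasets are empty", call. = FALSE)
  }
  structure(out, class = "dataset_partition")
}
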