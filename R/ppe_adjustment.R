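# Pollen-productivity correction: dividing counts by relative PPEs balances
# the over-representation of high producers before richness is recomputed at
# a common (smaller) depth.

#' Divide pollen counts by pollen productivity estimates
#'
#' Taxa present in the PPE table are divided element-wise by their PPE; taxa
#' without a PPE keep their raw counts and are flagged `unadjusted` (dropping
#' them would delete most of the richness signal, since PPE sets typically
#' cover only a few dozen taxa).
#'
#' @param pollen a [pollen_dataset()].
#' @param ppe a [ppe_table()].
#' @return an object of class `adjusted_counts`: `values` (sites-by-taxa
#'   non-negative real matrix), `adjusted` (logical per taxon), `sites`
#'   (metadata carried through), `unmatched_ppe` (PPE taxa absent from the
#'   dataset).
#' @export
adjust_counts <- function(pollen, ppe) {
  stopifnot(inherits(pollen, "pollen_dataset"), inherits(ppe, "ppe_table"))
  taxa <- trimws(colnames(pollen$counts))
  ppe_taxa <- trimws(ppe$taxon)
  idx <- match(taxa, ppe_taxa)
  adjusted <- !is.na(idx)
  div <- rep(1, length(taxa))
  div[adjusted] <- ppe$ppe[idx[adjusted]]
  values <- sweep(pollen$counts, 2L, div, "/")
  storage.mode(values) <- "double"
  unmatched <- setdiff(ppe_taxa, taxa)
  if (any(!adjusted))
    message(sum(!adjusted), " taxa without a PPE kept unadjusted (of ",
            length(taxa), ")")
  if (length(unmatched) > 0L)
    message("PPE taxa absent from the dataset: ", paste(unmatched, collapse = ", "))
  structure(list(values = values, adjusted = stats::setNames(adjusted, taxa),
                 sites = pollen$sites, unmatched_ppe = unmatched),
            class = "adjusted_counts")
}

#' Resample PPE-adjusted counts to a fixed depth
#'
#' Adjusted counts are non-integer, so a without-replacement draw is
#' ill-defined; the default resamples `depth` grains multinomially with
#' probabilities proportional to the adjusted values (scale-invariant in the
#' PPEs). An alternative `"round-hypergeometric"` mode rounds the adjusted
#' values to integers and subsamples without replacement, for sensitivity
#' checks.
#'
#' @param adjusted an [adjust_counts()] result.
#' @param depth grains per resample (default 520).
#' @param n_reps repeated draws per site (default 100).
#' @param rng_seed integer master seed; per-site streams derived via
#'   [child_seed()].
#' @param method `"multinomial"` (default) or `"round-hypergeometric"`.
#' @return a `rarefaction_result` (see [rarefy_dataset()]); its `presence`
#'   matrix uses adjusted value > 0.
#' @export
resample_adjusted <- function(adjusted, depth = 520, n_reps = 100, rng_seed = 1,
                              method = c("multinomial", "round-hypergeometric")) {
  method <- match.arg(method)
  stopifnot(inherits(adjusted, "adjusted_counts"), depth >= 1, n_reps >= 1)
  values <- adjusted$values
  site_ids <- rownames(values)
  tot <- rowSums(values)
  if (any(tot <= 0))
    stop("all-zero adjusted sample(s): ",
         paste(site_ids[tot <= 0], collapse = ", "), call. = FALSE)
  n <- length(site_ids)
  med <- numeric(n)
  detection <- matrix(0, n, ncol(values), dimnames = dimnames(values))
  excluded <- character()
  for (i in seq_len(n)) {
    sid <- site_ids[i]
    seed_i <- child_seed(rng_seed, paste0("adj:", sid))
    if (method == "multinomial") {
      p <- values[i, ] / tot[i]
      draws <- with_seed_(seed_i, t(stats::rmultinom(n_reps, depth, p)))
    } else {
      cnt <- round(values[i, ])
      if (sum(cnt) < depth) {
        excluded <- c(excluded, sid); med[i] <- NA_real_; next
      }
      draws <- with_seed_(seed_i, draw_hypergeometric(cnt, depth, n_reps))
    }
    rich <- rowSums(draws > 0L)
    med[i] <- stats::median(rich)
    detection[i, ] <- colMeans(draws > 0L)
  }
  if (length(excluded) > 0L)
    warning("excluding ", length(excluded),
            " site(s) whose rounded adjusted total is below depth ", depth, ": ",
            paste(excluded, collapse = ", "), call. = FALSE)
  keep <- is.finite(med)
  structure(list(
    summary = data.frame(site_id = site_ids[keep], total = tot[keep],
                         depth = depth, n_reps = n_reps,
                         richness_raw = rowSums(values[keep, , drop = FALSE] > 0),
                         richness_median = med[keep],
                         row.names = NULL, stringsAsFactors = FALSE),
    presence = (values[keep, , drop = FALSE] > 0) + 0L,
    detection = detection[keep, , drop = FALSE], reps = NULL,
    presence_rule = "raw", excluded = excluded),
    class = "rarefaction_result")
}
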