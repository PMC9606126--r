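# Rarefaction of pollen counts: subsampling without replacement to a common
# grain sum so richness is comparable across samples with different totals.
# A draw at depth d from a count vector is a multivariate hypergeometric
# sample (equivalent to shuffling the pooled grains and keeping the first d),
# realised as sequential conditional univariate hypergeometric draws, which
# vectorises cleanly over repeats.

# matrix of n_reps hypergeometric subsamples (rows = reps, cols = taxa)
draw_hypergeometric <- function(counts, depth, n_reps) {
  k <- length(counts)
  out <- matrix(0L, nrow = n_reps, ncol = k)
  rem_total <- sum(counts)
  rem_depth <- rep.int(as.integer(depth), n_reps)
  for (j in seq_len(k)) {
    m <- counts[j]
    if (m <= 0) { rem_total <- rem_total - m; next }
    if (rem_total == m) { out[, j] <- rem_depth; rem_depth[] <- 0L; break }
    x <- stats::rhyper(n_reps, m, rem_total - m, rem_depth)
    out[, j] <- x
    rem_depth <- rem_depth - x
    rem_total <- rem_total - m
    if (all(rem_depth == 0L)) break
  }
  out
}

#' Subsample a pollen count vector without replacement
#'
#' Draws `depth` grains from the pooled sample, i.e. one multivariate
#' hypergeometric realisation. Every element of the result is bounded by the
#' original count and the result sums exactly to `depth`.
#'
#' @param counts non-negative integer vector of grain counts per taxon.
#' @param depth integer number of grains to retain; must not exceed
#'   `sum(counts)`.
#' @param rng_seed optional integer seed (the draw is made in a local RNG
#'   scope when given).
#' @return an integer vector of the same length (and names) as `counts`.
#' @export
rarefy_sample <- function(counts, depth, rng_seed = NULL) {
  check_rarefaction_pre(counts, depth)
  draw <- with_seed_(rng_seed, draw_hypergeometric(counts, depth, 1L))[1L, ]
  names(draw) <- names(counts)
  draw
}

check_rarefaction_pre <- function(counts, depth, site_id = NULL) {
  if (!all(is_wholenumber(counts)) || any(counts < 0))
    stop("counts must be non-negative integers", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (sum(counts) < depth)
    stop("sample", if (!is.null(site_id)) paste0(" '", site_id, "'"),
         " too shallow: total ", sum(counts), " < depth ", depth, call. = FALSE)
  invisible(TRUE)
}

#' Rarefied richness of one sample
#'
#' Repeats the without-replacement subsample `n_reps` times and returns the
#' median number of taxa detected per draw. The median of an even number of
#' integer richnesses can be half-integer; it is kept as a real, never
#' rounded.
#'
#' @inheritParams rarefy_sample
#' @param n_reps number of repeated subsamples (default 100).
#' @return median richness (numeric scalar), with attribute `reps` holding
#'   the per-draw richness vector.
#' @export
rarefied_richness <- function(counts, depth = 943, n_reps = 100, rng_seed = NULL) {
  check_rarefaction_pre(counts, depth)
  stopifnot(n_reps >= 1)
  draws <- with_seed_(rng_seed, draw_hypergeometric(counts, depth, n_reps))
  rich <- rowSums(draws > 0L)
  structure(stats::median(rich), reps = as.integer(rich))
}

#' Rarefy every sample of a pollen dataset
#'
#' Applies [rarefied_richness()] site by site. Per-site RNG streams are
#' derived from the master seed and the site id (see [child_seed()]), so the
#' result is independent of site ordering. Sites whose grain sum is below
#' `depth` are listed in a warning and excluded.
#'
#' @param pollen a [pollen_dataset()].
#' @param depth grains per sample after reduction (default 943).
#' @param n_reps repeated subsamples per site (default 100).
#' @param rng_seed integer master seed.
#' @param presence how to build the consensus presence-absence matrix
#'   returned for beta-diversity use: `"raw"` (default; taxon present iff its
#'   full count is > 0) or `"rarefied-majority"` (present iff detected in more
#'   than half of the repeats).
#' @param keep_reps keep the per-site vector of per-draw richnesses.
#' @return a list of class `rarefaction_result`: `summary` (data.frame with
#'   `site_id`, `total`, `depth`, `n_reps`, `richness_raw`,
#'   `richness_median`), `presence` (binary sites-by-taxa matrix),
#'   `detection` (per-site fraction of repeats detecting each taxon), and
#'   optionally `reps`.
#' @export
rarefy_dataset <- function(pollen, depth = 943, n_reps = 100, rng_seed = 1,
                           presence = c("raw", "rarefied-majority"),
                           keep_reps = FALSE) {
  presence <- match.arg(presence)
  stopifnot(inherits(pollen, "pollen_dataset"))
  counts <- pollen$counts
  if (nrow(counts) == 0L) stop("empty pollen dataset", call. = FALSE)
  shallow <- rownames(counts)[rowSums(counts) < depth]
  if (length(shallow) == nrow(counts))
    stop("every sample is shallower than depth ", depth, call. = FALSE)
  if (length(shallow) > 0L)
    warning("excluding ", length(shallow), " sample(s) shallower than depth ",
            depth, ": ", paste(shallow, collapse = ", "), call. = FALSE)
  keep <- setdiff(rownames(counts), shallow)
  counts <- counts[keep, , drop = FALSE]

  n <- length(keep)
  med <- numeric(n)
  detection <- matrix(0, n, ncol(counts), dimnames = list(keep, colnames(counts)))
  reps <- if (keep_reps) matrix(NA_integer_, n, n_reps, dimnames = list(keep, NULL))
  for (i in seq_len(n)) {
    sid <- keep[i]
    draws <- with_seed_(child_seed(rng_seed, sid),
                        draw_hypergeometric(counts[i, ], depth, n_reps))
    rich <- rowSums(draws > 0L)
    med[i] <- stats::median(rich)
    detection[i, ] <- colMeans(draws > 0L)
    if (keep_reps) reps[i, ] <- as.integer(rich)
  }
  pres <- if (presence == "raw") (counts > 0) + 0L else (detection > 0.5) + 0L
  structure(list(
    summary = data.frame(site_id = keep, total = rowSums(counts),
                         depth = depth, n_reps = n_reps,
                         richness_raw = rowSums(counts > 0),
                         richness_median = med,
                         row.names = NULL, stringsAsFactors = FALSE),
    presence = pres, detection = detection, reps = reps,
    presence_rule = presence, excluded = shallow),
    class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat("rarefaction_result:", nrow(x$summary), "sites, depth", x$summary$depth[1],
      "x", x$summary$n_reps[1], "reps\n")
  cat("  median richness:", round(min(x$summary$richness_median), 1), "-",
      round(max(x$summary$richness_median), 1), "\n")
  invisible(x)
}

#' Exact expected rarefied richness
#'
#' Closed-form expectation of the number of taxa detected in a
#' without-replacement subsample of size `depth`:
#' `sum_t (1 - choose(total - c_t, depth) / choose(total, depth))`.
#' Used as an independent oracle for the Monte-Carlo rarefaction.
#'
#' @inheritParams rarefy_sample
#' @return expected richness (numeric scalar).
#' @export
expected_rarefied_richness <- function(counts, depth) {
  check_rarefaction_pre(counts, depth)
  total <- sum(counts)
  cc <- counts[counts > 0]
  miss <- exp(lchoose(total - cc, depth) - lchoose(total, depth))
  miss[total - cc < depth] <- 0
  sum(1 - miss)
}
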