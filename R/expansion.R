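#' Detect expanded clonotypes at a fixed frequency threshold
#'
#' A clonotype is *expanded* when its within-sample frequency strictly exceeds
#' the threshold (default 1/1000): a clone at exactly the threshold is not
#' expanded. The expanded proportion is taken over unique clonotypes
#' (richness), not reads; see [expanded_read_fraction()] for the read-weighted
#' variant.
#'
#' @param rep a non-empty [repertoire()].
#' @param threshold frequency threshold in (0, 1); default `1/1000`.
#' @return An object of class `expansion_result`: list with `threshold`,
#'   `expanded` (tibble of expanded clones with their frequencies, in
#'   descending frequency order), `n_expanded`, and `proportion_expanded`
#'   (`n_expanded / richness`).
#' @export
expanded_clones <- function(rep, threshold = 1 / 1000) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (richness(rep) == 0) stop("repertoire is empty", call. = FALSE)
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly inside (0, 1)", call. = FALSE)
  }
  freq <- clone_frequencies(rep)
  hit <- freq > threshold  # strict: "exceeding"
  expanded <- rep$clones[hit, , drop = FALSE]
  expanded$frequency <- freq[hit]
  ord <- order(-expanded$frequency, expanded$cdr3_aa)
  expanded <- expanded[ord, , drop = FALSE]
  structure(
    list(threshold = threshold,
         expanded = tibble::as_tibble(expanded),
         n_expanded = sum(hit),
         proportion_expanded = sum(hit) / richness(rep)),
    class = "expansion_result"
  )
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf("<expansion_result> %d expanded clonotypes (freq > %g), %.3f of richness\n",
              x$n_expanded, x$threshold, x$proportion_expanded))
  invisible(x)
}

#' Read-weighted expanded fraction
#'
#' Fraction of *reads* (rather than unique clonotypes) carried by clones whose
#' frequency strictly exceeds the threshold.
#'
#' @inheritParams expanded_clones
#' @return A single number in `[0, 1]`.
#' @export
expanded_read_fraction <- function(rep, threshold = 1 / 1000) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (richness(rep) == 0) stop("repertoire is empty", call. = FALSE)
  freq <- clone_frequencies(rep)
  sum(freq[freq > threshold])
}

#' Clone counts above a grid of frequency thresholds
#'
#' For each threshold, the number of clones whose frequency strictly exceeds
#' it. With a subsampling depth given, the curve is computed on each subsample
#' iterate and summarized (median/mean/min/max) across iterates, mirroring
#' rarefied threshold-count displays; otherwise it is computed once on the
#' full repertoire.
#'
#' @param rep a [repertoire()].
#' @param thresholds strictly increasing frequencies within (0, 1).
#' @param depth optional subsample depth; `NULL` (default) uses the full
#'   repertoire.
#' @param n_iterations subsample iterations when `depth` is given.
#' @param seed master seed when `depth` is given.
#' @return A tibble with column `threshold` plus either `count` (full-sample
#'   mode) or `median`, `mean`, `min`, `max` (subsampled mode). Counts are
#'   non-increasing in the threshold.
#' @export
threshold_curve <- function(rep, thresholds = c(1e-4, 2e-4, 5e-4, 1e-3,
                                                2e-3, 5e-3, 1e-2),
                            depth = NULL, n_iterations = 100L, seed = 1L) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (any(thresholds <= 0) || any(thresholds >= 1) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly increasing within (0, 1)",
         call. = FALSE)
  }
  count_above <- function(r) {
    freq <- clone_frequencies(r)
    vapply(thresholds, function(t) sum(freq > t), numeric(1))
  }
  if (is.null(depth)) {
    return(tibble::tibble(threshold = thresholds, count = count_above(rep)))
  }
  counts <- matrix(NA_real_, nrow = as.integer(n_iterations),
                   ncol = length(thresholds))
  for (i in seq_len(as.integer(n_iterations))) {
    counts[i, ] <- count_above(subsample(rep, depth,
                                         derive_seed(seed, i, rep$sample_id)))
  }
  tibble::tibble(
    threshold = thresholds,
    median = apply(counts, 2, stats::median),
    mean = colMeans(counts),
    min = apply(counts, 2, min),
    max = apply(counts, 2, max)
  )
}
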