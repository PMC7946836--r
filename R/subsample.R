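#' Derive a reproducible per-iteration seed
#'
#' Mixes a master seed, an iteration index and a sample identifier into a
#' 31-bit seed, so cohort runs are reproducible and independent of the order
#' in which samples are processed.
#'
#' @param master integer master seed.
#' @param iteration iteration index (>= 1).
#' @param sample_id character scalar mixed into the seed.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, iteration = 1L, sample_id = "") {
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  if (nzchar(sample_id)) {
    codes <- utf8ToInt(sample_id)
    for (k in seq_along(codes)) h <- (h * 131 + codes[k]) %% m
  }
  x <- (abs(as.numeric(master)) %% m) * 69069 %% m
  x <- (x + as.numeric(iteration) * 40503 + h) %% m
  as.integer(x %% (m - 1)) + 1L
}

#' Subsample a repertoire to a fixed read depth
#'
#' Draws `depth` reads without replacement from the repertoire's read multiset
#' (a multivariate hypergeometric draw over clone counts). Clones drawn zero
#' times are dropped, so subsampled richness never exceeds the original.
#' Sampling at full depth returns the repertoire unchanged.
#'
#' @param rep a [repertoire()].
#' @param depth target read count; must not exceed `total_reads(rep)` —
#'   the deeper member of a pair is subsampled, never the shallower upsampled.
#' @param seed optional integer seed; fixed seed gives a bit-identical draw.
#' @return A [repertoire()] with `total_reads == depth`.
#' @export
subsample <- function(rep, depth, seed = NULL) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  depth <- as.integer(depth)
  if (length(depth) != 1 || is.na(depth) || depth < 1) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  total <- total_reads(rep)
  if (depth > total) {
    stop("depth (", depth, ") exceeds total reads (", total,
         "); subsample the deeper member of a pair, never upsample",
         call. = FALSE)
  }
  if (depth == total) return(rep)
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- rep$clones$count
  cum <- cumsum(as.numeric(counts))
  idx <- sample.int(total, depth, replace = FALSE)
  clone_of <- findInterval(idx - 1L, cum) + 1L
  new_counts <- tabulate(clone_of, nbins = length(counts))
  keep <- new_counts > 0L
  out <- rep
  out$clones <- rep$clones[keep, , drop = FALSE]
  out$clones$count <- as.integer(new_counts[keep])
  out
}

#' Depth-match a pair of repertoires by iterative subsampling
#'
#' Whichever member of the pair has more reads is subsampled to the other
#' member's depth, independently in each iteration with a per-iteration seed
#' derived from `(seed, iteration, sample_id)`. The shallower member passes
#' through unchanged in every iterate. With equal depths both pass through.
#'
#' @param rep_a,rep_b paired repertoires of the same chain (typically baseline
#'   and post-treatment samples of one patient).
#' @param n_iterations number of independent subsampling iterations.
#' @param seed master seed.
#' @return A list of `n_iterations` elements, each `list(a = , b = )` holding
#'   the depth-matched pair for that iterate.
#' @export
match_pair <- function(rep_a, rep_b, n_iterations = 100L, seed = 1L) {
  stopifnot(inherits(rep_a, "tcr_repertoire"),
            inherits(rep_b, "tcr_repertoire"))
  if (richness(rep_a) == 0 || richness(rep_b) == 0) {
    stop("both repertoires must be non-empty", call. = FALSE)
  }
  if (!identical(rep_a$chain, rep_b$chain)) {
    stop("chain mismatch: '", rep_a$chain, "' vs '", rep_b$chain, "'",
         call. = FALSE)
  }
  n_iterations <- as.integer(n_iterations)
  stopifnot(n_iterations >= 1L)
  ta <- total_reads(rep_a); tb <- total_reads(rep_b)
  target <- min(ta, tb)
  lapply(seq_len(n_iterations), function(i) {
    a <- if (ta > target) {
      subsample(rep_a, target, derive_seed(seed, i, rep_a$sample_id))
    } else rep_a
    b <- if (tb > target) {
      subsample(rep_b, target, derive_seed(seed, i, rep_b$sample_id))
    } else rep_b
    list(a = a, b = b)
  })
}

#' Summarize a statistic across subsample iterations
#'
#' The median is the headline summary (matching the convention of showing the
#' median with min/max whiskers across iterations); mean, min and max are
#' always reported alongside.
#'
#' @param values numeric vector of per-iterate values (non-empty).
#' @return Named numeric vector with elements `mean`, `median`, `min`, `max`.
#' @export
summarize_iterates <- function(values) {
  if (length(values) == 0 || !is.numeric(values)) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  c(mean = mean(values), median = stats::median(values),
    min = min(values), max = max(values))
}
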