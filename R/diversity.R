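#' Default Rényi order grid
#'
#' The grid runs from 0 (log-richness) through 1 (Shannon) and 2
#' (log inverse Simpson) up to infinity (dominance), matching the grid
#' conventionally used for Rényi diversity profiles of ecological and
#' repertoire data.
#'
#' @return Numeric vector `c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, Inf)`.
#' @export
default_renyi_orders <- function() c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, Inf)

#' Rényi entropy of a frequency distribution
#'
#' For order \eqn{q \notin \{1, \infty\}},
#' \eqn{H_q = \frac{1}{1-q} \ln \sum_i p_i^q}; the Shannon limit
#' \eqn{H_1 = -\sum_i p_i \ln p_i} is computed by its own formula, and
#' \eqn{H_\infty = -\ln \max_i p_i}. \eqn{H_0} is the log of the number of
#' entries (log-richness). All values are in nats (natural logarithm).
#' The spectrum is non-increasing in the order.
#'
#' @param freqs vector of clone frequencies, all positive, summing to 1
#'   within `1e-9`.
#' @param orders one or more non-negative orders; `Inf` allowed.
#' @return Numeric vector of entropies, one per order.
#' @examples
#' renyi_entropy(rep(0.1, 10), c(0, 1, 2, Inf))  # all log(10)
#' renyi_entropy(c(0.5, 0.3, 0.2), 2)            # -log(0.38)
#' @export
renyi_entropy <- function(freqs, orders) {
  if (length(freqs) == 0 || any(freqs <= 0)) {
    stop("`freqs` must be a non-empty vector of positive frequencies",
         call. = FALSE)
  }
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("frequencies must sum to 1 (got ", format(sum(freqs)), ")",
         call. = FALSE)
  }
  if (any(is.na(orders)) || any(orders < 0)) {
    stop("orders must be non-negative (Inf allowed)", call. = FALSE)
  }
  vapply(orders, function(q) {
    if (is.infinite(q)) {
      -log(max(freqs))
    } else if (q == 0) {
      log(length(freqs))
    } else if (q == 1) {
      -sum(freqs * log(freqs))
    } else {
      log(sum(freqs^q)) / (1 - q)
    }
  }, numeric(1))
}

#' Rényi diversity profile under iterative subsampling
#'
#' Subsamples the repertoire to `depth` reads `n_iterations` times, computes
#' the Rényi spectrum on each iterate's frequencies, and summarizes each order
#' across iterates (median, mean, min, max). Typical depths are 3000 reads for
#' alpha-chain and 9000 for beta-chain libraries.
#'
#' @param rep a [repertoire()].
#' @param depth subsample depth; must not exceed `total_reads(rep)`.
#' @param n_iterations number of subsampling iterations (default 100).
#' @param seed master seed for the iteration sequence.
#' @param orders order grid; defaults to [default_renyi_orders()].
#' @return A tibble of class `renyi_profile` with columns `order`, `median`,
#'   `mean`, `min`, `max`, and attributes `depth`, `n_iterations`, `seed`,
#'   `sample_id`.
#' @export
renyi_profile <- function(rep, depth, n_iterations = 100L, seed = 1L,
                          orders = default_renyi_orders()) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  n_iterations <- as.integer(n_iterations)
  stopifnot(n_iterations >= 1L)
  spectra <- matrix(NA_real_, nrow = n_iterations, ncol = length(orders))
  for (i in seq_len(n_iterations)) {
    it <- subsample(rep, depth, derive_seed(seed, i, rep$sample_id))
    spectra[i, ] <- renyi_entropy(clone_frequencies(it), orders)
  }
  out <- tibble::tibble(
    order = orders,
    median = apply(spectra, 2, stats::median),
    mean = colMeans(spectra),
    min = apply(spectra, 2, min),
    max = apply(spectra, 2, max)
  )
  attr(out, "depth") <- as.integer(depth)
  attr(out, "n_iterations") <- n_iterations
  attr(out, "seed") <- seed
  attr(out, "sample_id") <- rep$sample_id
  class(out) <- c("renyi_profile", class(out))
  out
}
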