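#' Amino-acid triplet (3-mer) counts of a CDR3 sequence
#'
#' Counts every contiguous length-3 substring, overlapping occurrences
#' included. Sequences shorter than 3 residues have no triplets and yield an
#' empty mapping.
#'
#' @param s amino-acid string over the standard 20-letter alphabet.
#' @return Named integer vector mapping each 3-mer to its occurrence count.
#' @examples
#' triplet_counts("CASS")  # CAS = 1, ASS = 1
#' triplet_counts("AAAA")  # AAA = 2
#' @export
triplet_counts <- function(s) {
  if (length(s) != 1 || is.na(s)) {
    stop("`s` must be a single string", call. = FALSE)
  }
  chars <- strsplit(s, "")[[1]]
  if (!all(chars %in% AA_ALPHABET)) {
    bad <- setdiff(unique(chars), AA_ALPHABET)
    stop("invalid amino-acid character(s) in '", s, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nchar(s)
  if (n < 3) return(structure(integer(0), names = character(0)))
  kmers <- substring(s, 1:(n - 2), 3:n)
  tab <- table(kmers)
  structure(as.integer(tab), names = names(tab))
}

#' Cosine-normalised triplet spectrum kernel similarity
#'
#' The raw kernel is the inner product of the two sequences' 3-mer count
#' vectors, \eqn{K(s,t) = \sum_u c_s(u) c_t(u)}; similarity is the cosine
#' normalisation \eqn{K(s,t)/\sqrt{K(s,s) K(t,t)}}, which is symmetric, lies
#' in [0, 1], equals 1 for identical sequences and 0 when no triplet is
#' shared.
#'
#' @param s,t amino-acid strings, each at least 3 residues long.
#' @return Similarity in `[0, 1]`.
#' @examples
#' kernel_similarity("CASS", "CASSF")   # 2 / sqrt(6)
#' kernel_similarity("CASSL", "WGYQP")  # 0
#' @export
kernel_similarity <- function(s, t) {
  cs <- triplet_counts(s)
  ct <- triplet_counts(t)
  if (length(cs) == 0 || length(ct) == 0) {
    stop("similarity is undefined for sequences shorter than 3 residues",
         call. = FALSE)
  }
  shared <- intersect(names(cs), names(ct))
  k_st <- sum(as.numeric(cs[shared]) * as.numeric(ct[shared]))
  k_st / sqrt(sum(as.numeric(cs)^2) * sum(as.numeric(ct)^2))
}

#' Top expanded CDR3 amino-acid sequences of a repertoire
#'
#' Takes the expanded clones (frequency strictly above `threshold`),
#' aggregates them by CDR3 amino-acid sequence, drops nonproductive CDR3s
#' (containing `*`) and those shorter than 3 residues, then returns the `n`
#' most frequent CDR3s in descending aggregate frequency, ties broken
#' lexicographically. Fewer than `n` expanded CDR3s returns them all.
#'
#' @param rep a [repertoire()].
#' @param n number of CDR3s to keep (default 50).
#' @param threshold expansion frequency threshold (default 1/1000).
#' @return Character vector of up to `n` unique CDR3 sequences.
#' @export
top_expanded_cdr3s <- function(rep, n = 50L, threshold = 1 / 1000) {
  ex <- expanded_clones(rep, threshold)$expanded
  keep <- !grepl("*", ex$cdr3_aa, fixed = TRUE) & nchar(ex$cdr3_aa) >= 3
  ex <- ex[keep, , drop = FALSE]
  if (nrow(ex) == 0) return(character(0))
  agg <- tapply(ex$frequency, ex$cdr3_aa, sum)
  ord <- order(-agg, names(agg))
  utils::head(names(agg)[ord], n)
}

#' Build a CDR3 similarity network
#'
#' Computes all-pairs [kernel_similarity()] over the input CDR3s and draws an
#' edge wherever similarity is at least `threshold` (inclusive; default 0.80,
#' a level at which motif-free control sequences show minimal clustering — see
#' [calibrate_control()]). Clusters are connected components with at least two
#' nodes; singletons are not clusters.
#'
#' @param cdr3s character vector of unique CDR3 amino-acid sequences, each at
#'   least 3 residues.
#' @param threshold similarity threshold in (0, 1].
#' @return An object of class `similarity_network`: list with `nodes`, `edges`
#'   (tibble `from`, `to`, `similarity`), `threshold`, `membership` (integer
#'   component id per node, NA for singletons), `clusters` (list of node-name
#'   vectors, components of size >= 2) and `n_clusters`.
#' @export
build_network <- function(cdr3s, threshold = 0.80) {
  if (anyDuplicated(cdr3s)) {
    stop("input CDR3s must be unique (duplicates: ",
         paste(unique(cdr3s[duplicated(cdr3s)]), collapse = ", "), ")",
         call. = FALSE)
  }
  if (length(threshold) != 1 || threshold < 0 || threshold > 1) {
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  }
  n <- length(cdr3s)
  counts <- lapply(cdr3s, triplet_counts)
  if (any(lengths(counts) == 0)) {
    stop("all CDR3s must be at least 3 residues long", call. = FALSE)
  }
  norms <- vapply(counts, function(v) sqrt(sum(as.numeric(v)^2)), numeric(1))
  from <- integer(0); to <- integer(0); sim <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      ci <- counts[[i]]
      for (j in (i + 1):n) {
        cj <- counts[[j]]
        shared <- intersect(names(ci), names(cj))
        if (length(shared) == 0 && threshold > 0) next
        s <- sum(as.numeric(ci[shared]) * as.numeric(cj[shared])) /
          (norms[i] * norms[j])
        if (s >= threshold) {
          from <- c(from, i); to <- c(to, j); sim <- c(sim, s)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = cdr3s)
  if (length(from) > 0) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  comp <- igraph::components(g)
  member <- comp$membership
  big <- which(comp$csize >= 2)
  membership <- ifelse(member %in% big, member, NA_integer_)
  clusters <- lapply(big, function(k) cdr3s[member == k])
  structure(
    list(nodes = cdr3s,
         edges = tibble::tibble(from = cdr3s[from], to = cdr3s[to],
                                similarity = sim),
         threshold = threshold,
         membership = membership,
         clusters = clusters,
         n_clusters = length(clusters)),
    class = "similarity_network"
  )
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d edges (sim >= %.2f), %d clusters\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$n_clusters))
  invisible(x)
}

#' Fraction of control CDR3s that fall into clusters
#'
#' Builds the similarity network over a control set (unexpanded clones, or
#' motif-free synthetic CDR3s) and returns the fraction of nodes belonging to
#' a cluster of size >= 2. Used to verify that the default 0.80 similarity
#' threshold produces minimal clustering of unrelated sequences.
#'
#' @param control_cdr3s character vector of unique control CDR3s (may be
#'   empty).
#' @param threshold similarity threshold.
#' @return Clustered-node fraction in `[0, 1]`; 0 for an empty control list.
#' @export
calibrate_control <- function(control_cdr3s, threshold = 0.80) {
  if (length(control_cdr3s) == 0) return(0)
  net <- build_network(control_cdr3s, threshold)
  sum(!is.na(net$membership)) / length(net$nodes)
}
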