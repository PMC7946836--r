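#' Clonotype keys for a set of clones
#'
#' Two identity conventions are supported. Nucleotide mode (`"nt"`) keys a
#' clone by its V call, J call and CDR3 nucleotide sequence — the
#' clonotype-faithful convention; amino-acid mode (`"aa"`) keys by the CDR3
#' amino-acid sequence alone, a coarser key under which distinct nucleotide
#' clonotypes that converge on one peptide merge. The aa key can therefore
#' only merge clonotypes, never split them.
#'
#' @param clones data frame of clones (e.g. `rep$clones`) with columns
#'   `cdr3_aa`, `cdr3_nt`, `v_call`, `j_call`.
#' @param mode `"nt"` or `"aa"`.
#' @return Character vector of keys, one per row.
#' @export
clonotype_key <- function(clones, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  if (mode == "aa") return(as.character(clones$cdr3_aa))
  if (anyNA(clones$cdr3_nt)) {
    stop("nt-mode keys require `cdr3_nt` for every clone; ",
         sum(is.na(clones$cdr3_nt)), " clone(s) lack it", call. = FALSE)
  }
  paste(ifelse(is.na(clones$v_call), "", clones$v_call),
        ifelse(is.na(clones$j_call), "", clones$j_call),
        clones$cdr3_nt, sep = "|")
}

#' Which post-treatment expanded clonotypes pre-existed at baseline
#'
#' Applies the expansion threshold to the post-treatment repertoire and counts
#' how many of its expanded clonotype keys are present in the baseline
#' repertoire *at any frequency* (baseline membership carries no frequency
#' qualifier). The result is deterministic and independent of clone ordering.
#'
#' @param post,baseline paired repertoires of the same patient and chain.
#' @param mode clonotype key mode: `"nt"`, `"aa"`, or `"auto"` (the default),
#'   which uses nucleotide keys when both repertoires carry `cdr3_nt` for
#'   every clone and amino-acid keys otherwise (see [clonotype_key()]).
#' @param threshold expansion frequency threshold applied to `post`.
#' @return An object of class `overlap_result`: list with `patient_id`,
#'   `chain`, `mode`, `n_expanded_post`, `n_shared`, `shared_fraction`
#'   (`n_shared / n_expanded_post`; `NaN` when nothing is expanded) and
#'   `shared_keys`.
#' @export
shared_expanded_fraction <- function(post, baseline,
                                     mode = c("auto", "nt", "aa"),
                                     threshold = 1 / 1000) {
  stopifnot(inherits(post, "tcr_repertoire"),
            inherits(baseline, "tcr_repertoire"))
  mode <- match.arg(mode)
  if (mode == "auto") {
    has_nt <- !anyNA(post$clones$cdr3_nt) && !anyNA(baseline$clones$cdr3_nt)
    mode <- if (has_nt) "nt" else "aa"
  }
  if (!identical(post$patient_id, baseline$patient_id)) {
    stop("patient mismatch: '", post$patient_id, "' vs '",
         baseline$patient_id, "'", call. = FALSE)
  }
  if (!identical(post$chain, baseline$chain)) {
    stop("chain mismatch: '", post$chain, "' vs '", baseline$chain, "'",
         call. = FALSE)
  }
  ex <- expanded_clones(post, threshold)$expanded
  post_keys <- unique(clonotype_key(ex, mode))
  bl_keys <- unique(clonotype_key(baseline$clones, mode))
  shared <- intersect(post_keys, bl_keys)
  structure(
    list(patient_id = post$patient_id,
         chain = post$chain,
         mode = mode,
         n_expanded_post = length(post_keys),
         n_shared = length(shared),
         shared_fraction = length(shared) / length(post_keys),
         shared_keys = shared),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> patient %s (%s, %s keys): %d/%d post-expanded clonotypes present at baseline (%.2f)\n",
    x$patient_id, x$chain, x$mode, x$n_shared, x$n_expanded_post,
    x$shared_fraction))
  invisible(x)
}
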