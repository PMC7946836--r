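#' @keywords internal
"_PACKAGE"

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a TCR repertoire
#'
#' A repertoire is a sample's collection of clonotypes ("clones") plus identity
#' metadata. Clones carry a CDR3 amino-acid sequence, an optional CDR3
#' nucleotide sequence, optional V/J gene calls, and a read (or UMI) abundance
#' count. Rows whose full clonotype identity (`cdr3_aa`, `cdr3_nt`, `v_call`,
#' `j_call`) coincides are merged with counts summed, so clonotype keys are
#' unique within a repertoire.
#'
#' Nonproductive CDR3s (containing `*`) are retained here; stages that require
#' translatable amino-acid sequences (e.g. similarity clustering) exclude them.
#'
#' @param clones data frame with columns `cdr3_aa` and `count`; optional
#'   columns `cdr3_nt`, `v_call`, `j_call`. `count` must be positive integers
#'   and `cdr3_aa` non-empty.
#' @param sample_id,patient_id sample and patient identifiers.
#' @param chain `"alpha"` or `"beta"`.
#' @param timepoint `"BL"`, `"postASCT"` or `"other"`.
#' @return An object of class `tcr_repertoire`: a list with element `clones`
#'   (a tibble) and the metadata fields.
#' @examples
#' rep <- repertoire(data.frame(cdr3_aa = c("CASSLGETQYF", "CAWSVGQF"),
#'                              count = c(5L, 1L)),
#'                   sample_id = "s1", patient_id = "p1",
#'                   chain = "alpha", timepoint = "BL")
#' richness(rep)
#' total_reads(rep)
#' @export
repertoire <- function(clones, sample_id = "sample", patient_id = "patient",
                       chain = c("alpha", "beta"),
                       timepoint = c("BL", "postASCT", "other")) {
  chain <- match.arg(chain)
  timepoint <- match.arg(timepoint)
  clones <- as.data.frame(clones, stringsAsFactors = FALSE)
  if (!all(c("cdr3_aa", "count") %in% names(clones))) {
    stop("`clones` must have columns `cdr3_aa` and `count`", call. = FALSE)
  }
  for (col in c("cdr3_nt", "v_call", "j_call")) {
    if (!col %in% names(clones)) {
      clones[[col]] <- rep(NA_character_, nrow(clones))
    }
  }
  clones <- clones[c("cdr3_aa", "cdr3_nt", "v_call", "j_call", "count")]
  if (nrow(clones) > 0) {
    clones$cdr3_aa <- as.character(clones$cdr3_aa)
    if (anyNA(clones$cdr3_aa) || any(!nzchar(clones$cdr3_aa))) {
      stop("every clone must have a non-empty `cdr3_aa`", call. = FALSE)
    }
    count <- clones$count
    if (anyNA(count) || any(count < 1) || any(count != round(count))) {
      stop("`count` must be positive integers (>= 1)", call. = FALSE)
    }
    clones$count <- as.integer(round(count))
    # merge rows sharing the full clonotype identity; counts sum
    key <- paste(clones$cdr3_aa,
                 ifelse(is.na(clones$cdr3_nt), "", clones$cdr3_nt),
                 ifelse(is.na(clones$v_call), "", clones$v_call),
                 ifelse(is.na(clones$j_call), "", clones$j_call),
                 sep = "\r")
    if (anyDuplicated(key)) {
      first <- !duplicated(key)
      summed <- tapply(clones$count, key, sum)
      merged <- clones[first, , drop = FALSE]
      merged$count <- as.integer(summed[key[first]])
      clones <- merged
    }
    rownames(clones) <- NULL
  }
  structure(
    list(clones = tibble::as_tibble(clones),
         sample_id = as.character(sample_id),
         patient_id = as.character(patient_id),
         chain = chain, timepoint = timepoint),
    class = "tcr_repertoire"
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> %s (patient %s, %s chain, %s)\n",
              x$sample_id, x$patient_id, x$chain, x$timepoint))
  cat(sprintf("  %d clonotypes, %d total reads\n",
              richness(x), total_reads(x)))
  invisible(x)
}

#' Repertoire richness (number of unique clonotypes)
#'
#' @param rep a `tcr_repertoire`.
#' @return Integer count of unique clonotypes.
#' @export
richness <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  nrow(rep$clones)
}

#' Total read count of a repertoire
#'
#' @param rep a `tcr_repertoire`.
#' @return Integer sum of clone counts.
#' @export
total_reads <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (nrow(rep$clones) == 0) return(0L)
  sum(rep$clones$count)
}

#' Clone frequencies
#'
#' Per-clone frequencies `count / total_reads`, in clone order. They sum to 1
#' (within numerical tolerance) for any non-empty repertoire.
#'
#' @param rep a `tcr_repertoire`.
#' @return Numeric vector of frequencies.
#' @export
clone_frequencies <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (nrow(rep$clones) == 0) return(numeric(0))
  rep$clones$count / sum(rep$clones$count)
}
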