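#' Read an AIRR Rearrangement TSV into a repertoire
#'
#' Expects a tab-separated file with a header row containing at least
#' `junction_aa`; `duplicate_count`, `junction`, `v_call` and `j_call` are used
#' when present. Rows with the same clonotype identity are merged with counts
#' summed; rows with a missing or zero `duplicate_count` default to count 1.
#'
#' @param path path to the TSV file.
#' @param sample_id,patient_id,chain,timepoint repertoire metadata; never
#'   inferred from file content.
#' @return A [repertoire()].
#' @export
read_airr <- function(path, sample_id = basename(path), patient_id = "patient",
                      chain = "alpha", timepoint = "other") {
  tab <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      colClasses = "character", check.names = FALSE),
    error = function(e) stop("cannot read AIRR file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(tab) == 0) {
    if (!"junction_aa" %in% names(tab)) {
      stop("AIRR file '", path, "' is missing mandatory column 'junction_aa'",
           call. = FALSE)
    }
    stop("AIRR file '", path, "' contains no rearrangement rows",
         call. = FALSE)
  }
  if (!"junction_aa" %in% names(tab)) {
    stop("AIRR file '", path, "' is missing mandatory column 'junction_aa'",
         call. = FALSE)
  }
  count <- if ("duplicate_count" %in% names(tab)) {
    n <- suppressWarnings(as.numeric(tab$duplicate_count))
    n[is.na(n) | n <= 0] <- 1
    as.integer(n)
  } else rep(1L, nrow(tab))
  clones <- data.frame(
    cdr3_aa = tab$junction_aa,
    cdr3_nt = if ("junction" %in% names(tab)) empty_to_na(tab$junction) else NA_character_,
    v_call  = if ("v_call" %in% names(tab)) empty_to_na(tab$v_call) else NA_character_,
    j_call  = if ("j_call" %in% names(tab)) empty_to_na(tab$j_call) else NA_character_,
    count   = count,
    stringsAsFactors = FALSE
  )
  repertoire(clones, sample_id = sample_id, patient_id = patient_id,
             chain = chain, timepoint = timepoint)
}

empty_to_na <- function(x) {
  x <- as.character(x)
  x[!nzchar(x)] <- NA_character_
  x
}

#' Read a Decombinator-style frequency file into a repertoire
#'
#' Parses the comma-separated clonotype dialect written by Decombinator-style
#' pipelines: five classifier fields (V index, J index, V deletions,
#' J deletions, insert sequence), then an integer abundance, then the CDR3
#' amino-acid sequence. V/J indices are stored verbatim as `v_call`/`j_call`.
#'
#' @inheritParams read_airr
#' @param dialect only `"decombinator"` is currently understood; the argument
#'   exists so other comma-separated layouts can be added.
#' @return A [repertoire()].
#' @export
read_decombinator <- function(path, sample_id = basename(path),
                              patient_id = "patient", chain = "alpha",
                              timepoint = "other", dialect = "decombinator") {
  dialect <- match.arg(dialect, "decombinator")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("Decombinator file '", path, "' contains no clonotype lines",
         call. = FALSE)
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields < 7)
  if (length(bad) > 0) {
    stop("Decombinator file '", path, "': line ", bad[1],
         " has ", n_fields[bad[1]], " fields (expected 7)", call. = FALSE)
  }
  fields <- lapply(parts, trimws)
  abundance <- vapply(fields, `[[`, "", 6L)
  num <- suppressWarnings(as.numeric(abundance))
  bad <- which(is.na(num) | num != round(num) | num < 1)
  if (length(bad) > 0) {
    stop("Decombinator file '", path, "': non-integer abundance '",
         abundance[bad[1]], "' on line ", bad[1], call. = FALSE)
  }
  clones <- data.frame(
    cdr3_aa = vapply(fields, `[[`, "", 7L),
    cdr3_nt = NA_character_,
    v_call  = vapply(fields, `[[`, "", 1L),
    j_call  = vapply(fields, `[[`, "", 2L),
    count   = as.integer(num),
    stringsAsFactors = FALSE
  )
  repertoire(clones, sample_id = sample_id, patient_id = patient_id,
             chain = chain, timepoint = timepoint)
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' One row per clonotype with columns `junction_aa`, `junction`, `v_call`,
#' `j_call`, `duplicate_count`. `read_airr(write_airr(r))` reproduces `r`'s
#' clonotype keys and counts exactly.
#'
#' @param rep a [repertoire()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(rep, path) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  cl <- rep$clones
  out <- data.frame(
    junction_aa = cl$cdr3_aa,
    junction = ifelse(is.na(cl$cdr3_nt), "", cl$cdr3_nt),
    v_call = ifelse(is.na(cl$v_call), "", cl$v_call),
    j_call = ifelse(is.na(cl$j_call), "", cl$j_call),
    duplicate_count = cl$count,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write AIRR file '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a tab-separated table with columns `sample_id`, `patient_id`,
#' `chain`, `timepoint`, `path` and optionally `dialect` (`airr` or
#' `decombinator`, defaulting to `airr`). Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path manifest file path.
#' @return A tibble, one row per sample.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "patient_id", "chain", "timepoint", "path")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("manifest '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"dialect" %in% names(tab)) tab$dialect <- "airr"
  tab$dialect[!nzchar(tab$dialect)] <- "airr"
  rel <- !grepl("^(/|[A-Za-z]:)", tab$path)
  tab$path[rel] <- file.path(dirname(path), tab$path[rel])
  tibble::as_tibble(tab)
}
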