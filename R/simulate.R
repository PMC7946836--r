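NT_ALPHABET <- c("A", "C", "G", "T")

random_cdr3s <- function(n, length_range, existing = character(0)) {
  out <- character(0)
  seen <- existing
  len_pool <- seq(length_range[1], length_range[2])
  while (length(out) < n) {
    need <- n - length(out)
    lens <- len_pool[sample.int(length(len_pool), need, replace = TRUE)]
    new <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1))
    new <- new[!duplicated(new) & !(new %in% seen)]
    seen <- c(seen, new)
    out <- c(out, new)
  }
  out[seq_len(n)]
}

random_nt <- function(aa) {
  vapply(nchar(aa), function(L) {
    paste(sample(NT_ALPHABET, 3 * L, replace = TRUE), collapse = "")
  }, character(1))
}

# Motif families model convergent CDR3 selection: all members of a family
# share one consensus backbone (which contains the implanted core) and differ
# only in their carboxy-terminal residue, as in natural families like
# CASSLGETQYF / CASSLGETQYW. Members therefore share at least
# `core_length` contiguous residues and remain mutually similar under the
# triplet kernel, while being distinct clonotypes.
implant_motifs <- function(cdr3s, n_families, family_size, core_length,
                           length_range = c(8L, 20L),
                           existing = character(0)) {
  if (n_families == 0) {
    return(list(cdr3s = cdr3s, families = list()))
  }
  if (family_size > length(AA_ALPHABET)) {
    stop("`family_size` cannot exceed ", length(AA_ALPHABET),
         " (members vary a single terminal residue)", call. = FALSE)
  }
  n_members <- n_families * family_size
  if (n_members > length(cdr3s)) {
    stop("motif families need ", n_members, " clones but only ",
         length(cdr3s), " are available", call. = FALSE)
  }
  members <- sample(length(cdr3s), n_members)
  families <- vector("list", n_families)
  seen <- c(setdiff(cdr3s, cdr3s[members]), existing)
  min_len <- max(length_range[1], core_length + 1L)
  len_pool <- seq(min_len, max(min_len, length_range[2]))
  idx <- 1
  for (f in seq_len(n_families)) {
    fam_members <- members[idx:(idx + family_size - 1)]
    idx <- idx + family_size
    repeat {
      L <- len_pool[sample.int(length(len_pool), 1)]
      stem <- paste(sample(AA_ALPHABET, L - 1, replace = TRUE),
                    collapse = "")
      tails <- sample(AA_ALPHABET, family_size)
      fam_cdr3s <- paste0(stem, tails)
      if (!any(fam_cdr3s %in% seen)) break
    }
    cdr3s[fam_members] <- fam_cdr3s
    seen <- c(seen, fam_cdr3s)
    families[[f]] <- fam_cdr3s
  }
  list(cdr3s = cdr3s, families = families)
}

#' Simulate a single TCR repertoire with power-law clone sizes
#'
#' Clone sampling weights follow a Zipf law, weight of rank r proportional to
#' \eqn{r^{-s}} — the standard heavy-tailed model for clone-size
#' distributions. Counts are drawn multinomially over `total_reads - n_clones`
#' reads and one read is then added to every clone (a "+1 floor", recorded in
#' the repertoire's `count_model` attribute) so every clone is observed. CDR3
#' amino-acid sequences are uniform random strings over the 20-letter
#' alphabet, unique across clones, with optional motif families sharing an
#' implanted contiguous core that similarity clustering can recover.
#'
#' @param n_clones number of clonotypes (>= 1).
#' @param total_reads total read count (>= `n_clones`).
#' @param zipf_exponent power-law exponent `s > 0` (heavier tail for smaller
#'   `s`); default 1.3.
#' @param cdr3_length_range integer pair, CDR3 length bounds (default 8-20).
#' @param n_motif_families number of planted CDR3 motif families (default 0).
#' @param family_size clones per motif family (default 5).
#' @param family_core_length implanted shared core length (default 6).
#' @param chain,sample_id,patient_id,timepoint repertoire metadata.
#' @param seed integer seed; the entire repertoire is a deterministic function
#'   of the arguments and this seed.
#' @return A [repertoire()] carrying attributes `zipf_weights` (normalised
#'   sampling weights), `motif_families` (list of member CDR3 vectors) and
#'   `count_model` (`"multinomial+1"`).
#' @export
simulate_repertoire <- function(n_clones, total_reads, zipf_exponent = 1.3,
                                cdr3_length_range = c(8L, 20L),
                                n_motif_families = 0L, family_size = 5L,
                                family_core_length = 6L,
                                chain = "alpha", sample_id = "sim",
                                patient_id = "sim", timepoint = "other",
                                seed = 1L) {
  if (n_clones < 1) stop("`n_clones` must be >= 1", call. = FALSE)
  if (total_reads < n_clones) {
    stop("`total_reads` (", total_reads, ") must be >= `n_clones` (",
         n_clones, ") so every clone can receive a read", call. = FALSE)
  }
  set.seed(as.integer(seed))
  w <- (seq_len(n_clones))^(-zipf_exponent)
  w <- w / sum(w)
  counts <- draw_counts(w, total_reads)
  cdr3 <- random_cdr3s(n_clones, cdr3_length_range)
  fam <- implant_motifs(cdr3, n_motif_families, family_size,
                        family_core_length,
                        length_range = cdr3_length_range)
  cdr3 <- fam$cdr3s
  v_pool <- if (chain == "alpha") paste0("TRAV", 1:40) else paste0("TRBV", 1:30)
  j_pool <- if (chain == "alpha") paste0("TRAJ", 1:50) else paste0("TRBJ", 1:13)
  clones <- data.frame(
    cdr3_aa = cdr3,
    cdr3_nt = random_nt(cdr3),
    v_call = sample(v_pool, n_clones, replace = TRUE),
    j_call = sample(j_pool, n_clones, replace = TRUE),
    count = counts,
    stringsAsFactors = FALSE
  )
  out <- repertoire(clones, sample_id = sample_id, patient_id = patient_id,
                    chain = chain, timepoint = timepoint)
  attr(out, "zipf_weights") <- w
  attr(out, "motif_families") <- fam$families
  attr(out, "count_model") <- "multinomial+1"
  out
}

# multinomial over (total - n) reads plus a +1 floor per clone
draw_counts <- function(weights, total_reads) {
  n <- length(weights)
  extra <- total_reads - n
  counts <- rep(1L, n)
  if (extra > 0) {
    counts <- counts + as.integer(stats::rmultinom(1, extra, weights)[, 1])
  }
  counts
}

#' Configuration for a paired baseline / post-transplant simulation
#'
#' Bundles the generative parameters for one patient's paired repertoires.
#' Defaults describe a realistic transplant scenario: a baseline marrow of
#' 5000 clonotypes with a heavy-tailed (Zipf exponent 1.3) clone-size law
#' sequenced to 50,000 reads; a post-treatment bottleneck in which 40% of
#' baseline clonotypes survive but baseline-expanded clones persist with
#' probability 0.6; a five-fold sampling-weight boost for surviving clones;
#' 500 novel low-weight clonotypes absent at baseline; and 20,000
#' post-treatment reads.
#'
#' @param n_clones_bl baseline clonotype count.
#' @param zipf_exponent clone-size power-law exponent (> 0).
#' @param total_reads_bl,total_reads_post read depths of the two samples.
#' @param bottleneck fraction in (0, 1] of baseline *unexpanded* clonotypes
#'   surviving to the post sample.
#' @param persistence_rho fraction in \[0, 1\] of baseline-*expanded* clones
#'   that persist (the most abundant ones survive).
#' @param expansion_boost multiplicative factor applied to surviving clones'
#'   sampling weights post-treatment.
#' @param n_novel_post clonotypes present post-treatment but absent at
#'   baseline; they enter with tail (low) weights.
#' @param cdr3_length_range,n_motif_families,family_size,family_core_length
#'   CDR3 generation parameters, as in [simulate_repertoire()].
#' @param chain,patient_id metadata.
#' @param seed master seed; all randomness in [simulate_paired()] flows from
#'   it.
#' @return A list of class `paired_sim_config`.
#' @export
paired_sim_config <- function(n_clones_bl = 5000L, zipf_exponent = 1.3,
                              total_reads_bl = 50000L,
                              total_reads_post = 20000L,
                              bottleneck = 0.4, persistence_rho = 0.6,
                              expansion_boost = 5, n_novel_post = 500L,
                              cdr3_length_range = c(8L, 20L),
                              n_motif_families = 0L, family_size = 5L,
                              family_core_length = 6L,
                              chain = "alpha", patient_id = "simpatient",
                              seed = 1L) {
  cfg <- list(n_clones_bl = as.integer(n_clones_bl),
              zipf_exponent = zipf_exponent,
              total_reads_bl = as.integer(total_reads_bl),
              total_reads_post = as.integer(total_reads_post),
              bottleneck = bottleneck, persistence_rho = persistence_rho,
              expansion_boost = expansion_boost,
              n_novel_post = as.integer(n_novel_post),
              cdr3_length_range = as.integer(cdr3_length_range),
              n_motif_families = as.integer(n_motif_families),
              family_size = as.integer(family_size),
              family_core_length = as.integer(family_core_length),
              chain = chain, patient_id = as.character(patient_id),
              seed = as.integer(seed))
  if (cfg$bottleneck <= 0 || cfg$bottleneck > 1) {
    stop("`bottleneck` must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$persistence_rho < 0 || cfg$persistence_rho > 1) {
    stop("`persistence_rho` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$expansion_boost <= 0) {
    stop("`expansion_boost` must be positive", call. = FALSE)
  }
  if (floor(cfg$bottleneck * cfg$n_clones_bl) + cfg$n_novel_post < 1) {
    stop("configuration yields an empty post-treatment repertoire",
         call. = FALSE)
  }
  class(cfg) <- "paired_sim_config"
  cfg
}

#' Simulate a paired baseline / post-transplant repertoire pair
#'
#' The baseline repertoire is drawn as in [simulate_repertoire()]. Survivor
#' numbers are fixed at `round(p * n)`: the `round(persistence_rho * n)` most
#' abundant of the baseline-expanded clones (frequency > 1/1000) persist —
#' dominant clones are the ones that survive the transplant — while
#' `round(bottleneck * n)` unexpanded clones are sampled uniformly, so a
#' bottleneck below 1 always reduces richness deterministically. Surviving clones keep their baseline sampling
#' weights multiplied by `expansion_boost`; `n_novel_post` novel clonotypes
#' join with the continuing (low) tail of the Zipf weight sequence. Post
#' counts are then drawn with the same multinomial-plus-floor scheme.
#'
#' @param config a [paired_sim_config()].
#' @return A list with elements `baseline` and `post` (repertoires) and
#'   `truth`, a ground-truth record containing `surviving_keys`,
#'   `novel_keys`, `bl_expanded_keys`, `post_expanded_keys` (all aa keys),
#'   `persistent_expanded_fraction` (realized fraction of post-expanded
#'   clonotypes that descend from baseline) and the echoed `config`.
#' @export
simulate_paired <- function(config = paired_sim_config()) {
  stopifnot(inherits(config, "paired_sim_config"))
  cfg <- config
  baseline <- simulate_repertoire(
    n_clones = cfg$n_clones_bl, total_reads = cfg$total_reads_bl,
    zipf_exponent = cfg$zipf_exponent,
    cdr3_length_range = cfg$cdr3_length_range,
    n_motif_families = cfg$n_motif_families, family_size = cfg$family_size,
    family_core_length = cfg$family_core_length,
    chain = cfg$chain, sample_id = paste0(cfg$patient_id, "_BL"),
    patient_id = cfg$patient_id, timepoint = "BL", seed = cfg$seed
  )
  w_bl <- attr(baseline, "zipf_weights")
  freq_bl <- clone_frequencies(baseline)
  expanded_bl <- freq_bl > 1 / 1000

  set.seed(derive_seed(cfg$seed, 2L, paste0(cfg$patient_id, "_post")))
  resample <- function(x, size) x[sample.int(length(x), size)]
  idx_exp <- which(expanded_bl)
  idx_une <- which(!expanded_bl)
  # expanded clones persist in abundance order (the most expanded clones are
  # the ones that survive the transplant); unexpanded survivors are uniform
  n_surv_exp <- round(cfg$persistence_rho * length(idx_exp))
  surv_exp <- idx_exp[order(-freq_bl[idx_exp])][seq_len(n_surv_exp)]
  surv_une <- sort(resample(idx_une,
                            round(cfg$bottleneck * length(idx_une))))
  surviving <- sort(c(surv_exp, surv_une))

  w_post <- w_bl[surviving] * cfg$expansion_boost
  n_novel <- cfg$n_novel_post
  if (n_novel > 0) {
    novel_rank <- cfg$n_clones_bl + seq_len(n_novel)
    w_novel <- novel_rank^(-cfg$zipf_exponent) /
      sum(seq_len(cfg$n_clones_bl)^(-cfg$zipf_exponent))
    novel_cdr3 <- random_cdr3s(n_novel, cfg$cdr3_length_range,
                               existing = baseline$clones$cdr3_aa)
  } else {
    w_novel <- numeric(0)
    novel_cdr3 <- character(0)
  }
  w_all <- c(w_post, w_novel)
  w_all <- w_all / sum(w_all)
  n_post <- length(w_all)
  if (cfg$total_reads_post < n_post) {
    stop("`total_reads_post` (", cfg$total_reads_post,
         ") must be >= post clonotype count (", n_post, ")", call. = FALSE)
  }
  counts_post <- draw_counts(w_all, cfg$total_reads_post)

  v_pool <- if (cfg$chain == "alpha") paste0("TRAV", 1:40) else paste0("TRBV", 1:30)
  j_pool <- if (cfg$chain == "alpha") paste0("TRAJ", 1:50) else paste0("TRBJ", 1:13)
  surv_clones <- baseline$clones[surviving, , drop = FALSE]
  novel_clones <- if (n_novel > 0) {
    data.frame(cdr3_aa = novel_cdr3, cdr3_nt = random_nt(novel_cdr3),
               v_call = sample(v_pool, n_novel, replace = TRUE),
               j_call = sample(j_pool, n_novel, replace = TRUE),
               count = 1L, stringsAsFactors = FALSE)
  } else NULL
  post_clones <- rbind(as.data.frame(surv_clones)[, 1:4],
                       if (is.null(novel_clones)) NULL else novel_clones[, 1:4])
  post_clones$count <- counts_post
  post <- repertoire(post_clones,
                     sample_id = paste0(cfg$patient_id, "_post"),
                     patient_id = cfg$patient_id, chain = cfg$chain,
                     timepoint = "postASCT")

  freq_post <- clone_frequencies(post)
  post_exp <- freq_post > 1 / 1000
  origin_bl <- c(rep(TRUE, length(surviving)), rep(FALSE, n_novel))
  pef <- if (any(post_exp)) sum(post_exp & origin_bl) / sum(post_exp) else NaN

  list(
    baseline = baseline,
    post = post,
    truth = list(
      surviving_keys = baseline$clones$cdr3_aa[surviving],
      novel_keys = novel_cdr3,
      bl_expanded_keys = baseline$clones$cdr3_aa[expanded_bl],
      post_expanded_keys = post$clones$cdr3_aa[post_exp],
      persistent_expanded_fraction = pef,
      config = cfg
    )
  )
}
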