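#' Paired t-test on baseline vs post-treatment richness
#'
#' Two-sided paired Student t-test on the per-patient differences
#' `bl - post`. The raw (unadjusted) p-value is reported; an optional
#' multiplicity adjustment over a stated number of comparisons can be
#' requested and is labelled as such. All-zero differences make the t
#' statistic undefined and raise an error.
#'
#' @param bl_values,post_values equal-length paired numeric vectors, n >= 2.
#' @param adjust `"none"` (default), `"bonferroni"` or `"holm"`.
#' @param n_comparisons number of comparisons the adjustment spans (used by
#'   Bonferroni; default 1).
#' @return List with `statistic` (t), `df`, `p_value`, `p_adjusted` (equal to
#'   `p_value` when `adjust = "none"`), `adjust` and `mean_difference`.
#' @export
paired_richness_test <- function(bl_values, post_values,
                                 adjust = c("none", "bonferroni", "holm"),
                                 n_comparisons = 1L) {
  adjust <- match.arg(adjust)
  if (length(bl_values) != length(post_values)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(bl_values) < 2) {
    stop("paired test needs at least 2 pairs", call. = FALSE)
  }
  d <- bl_values - post_values
  if (stats::sd(d) == 0) {
    stop("all paired differences are identical; the t statistic is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(bl_values, post_values, paired = TRUE)
  p_adj <- switch(adjust,
    none = unname(ht$p.value),
    bonferroni = min(1, unname(ht$p.value) * n_comparisons),
    holm = unname(ht$p.value)  # single p: holm reduces to the raw value
  )
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), p_adjusted = p_adj, adjust = adjust,
       mean_difference = mean(d))
}

default_depth_for_chain <- function(chain) {
  if (identical(chain, "beta")) 9000L else 3000L
}

#' Run the full paired-repertoire analysis over a cohort
#'
#' For every (patient, chain) pair in the manifest with a baseline (`BL`) and
#' post-treatment (`postASCT`) sample, the pipeline: depth-matches the pair by
#' iterative subsampling; computes Rényi diversity profiles (at 3000 reads for
#' alpha, 9000 for beta, capped at the pair's matched depth); counts clones
#' above a frequency-threshold grid on the depth-matched iterates; detects
#' expanded clones (> `threshold`) on the full samples; clusters each sample's
#' top expanded CDR3s in a triplet-kernel similarity network; and measures
#' what fraction of post-treatment expanded clonotypes were present at
#' baseline. Tables are written as TSV files to `outdir` (plus PDF plots
#' unless `write_plots = FALSE`); re-running with the same inputs and seed
#' reproduces every file byte for byte.
#'
#' @param manifest path to a manifest file (see [read_manifest()]) or an
#'   equivalent data frame.
#' @param outdir output directory, created if needed.
#' @param n_iterations subsampling iterations (default 100).
#' @param threshold expansion frequency threshold (default 1/1000).
#' @param similarity network similarity threshold (default 0.80).
#' @param top_n expanded CDR3s per sample used for clustering (default 50).
#' @param orders Rényi order grid.
#' @param curve_thresholds frequency grid for the threshold curves.
#' @param key_mode clonotype key mode for the overlap stage (`"auto"`,
#'   `"nt"`, `"aa"`).
#' @param seed master seed.
#' @param write_plots write PDF plots of the diversity profiles and threshold
#'   curves.
#' @return Invisibly, a `cohort_report` list: `richness` (per-sample tibble),
#'   `renyi` (long tibble over orders), `curves`, `expansion`, `clusters`,
#'   `overlap` tibbles, and `metadata` (parameter echo).
#' @export
run_cohort <- function(manifest, outdir, n_iterations = 100L,
                       threshold = 1 / 1000, similarity = 0.80,
                       top_n = 50L,
                       orders = default_renyi_orders(),
                       curve_thresholds = c(1e-4, 2e-4, 5e-4, 1e-3, 2e-3,
                                            5e-3, 1e-2),
                       key_mode = c("auto", "nt", "aa"), seed = 1L,
                       write_plots = TRUE) {
  key_mode <- match.arg(key_mode)
  man <- if (is.character(manifest)) read_manifest(manifest)
         else tibble::as_tibble(manifest)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[tcrfocus] ", sprintf(...))

  reps <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    reader <- if (identical(row$dialect, "decombinator")) read_decombinator
              else read_airr
    reps[[i]] <- reader(row$path, sample_id = row$sample_id,
                        patient_id = row$patient_id, chain = row$chain,
                        timepoint = row$timepoint)
    log_msg("loaded %s: %d clonotypes, %d reads", row$sample_id,
            richness(reps[[i]]), total_reads(reps[[i]]))
  }
  names(reps) <- man$sample_id

  pair_id <- paste(man$patient_id, man$chain, sep = "/")
  pairs <- list()
  for (pid in unique(pair_id)) {
    rows <- which(pair_id == pid)
    tps <- man$timepoint[rows]
    if (!all(c("BL", "postASCT") %in% tps)) {
      stop("manifest pair '", pid, "' is unresolved: has timepoint(s) ",
           paste(tps, collapse = ", "), " but needs BL and postASCT",
           call. = FALSE)
    }
    pairs[[pid]] <- list(bl = reps[[rows[tps == "BL"][1]]],
                         post = reps[[rows[tps == "postASCT"][1]]])
  }

  richness_tab <- tibble::tibble(
    sample_id = man$sample_id, patient_id = man$patient_id,
    chain = man$chain, timepoint = man$timepoint,
    richness = vapply(reps, richness, numeric(1)),
    total_reads = vapply(reps, total_reads, numeric(1))
  )

  renyi_tab <- NULL; curve_tab <- NULL; expansion_tab <- NULL
  cluster_tab <- NULL; overlap_tab <- NULL
  for (pid in names(pairs)) {
    bl <- pairs[[pid]]$bl; post <- pairs[[pid]]$post
    matched_depth <- min(total_reads(bl), total_reads(post))
    depth <- min(default_depth_for_chain(bl$chain), matched_depth)
    log_msg("pair %s: matched depth %d, diversity depth %d", pid,
            matched_depth, depth)
    for (r in list(bl, post)) {
      prof <- renyi_profile(r, depth = depth, n_iterations = n_iterations,
                            seed = seed, orders = orders)
      renyi_tab <- rbind(renyi_tab, tibble::tibble(
        sample_id = r$sample_id, patient_id = r$patient_id,
        chain = r$chain, timepoint = r$timepoint, depth = depth,
        order = prof$order, median = prof$median, mean = prof$mean,
        min = prof$min, max = prof$max))
      crv <- threshold_curve(r, curve_thresholds, depth = matched_depth,
                             n_iterations = n_iterations, seed = seed)
      curve_tab <- rbind(curve_tab, tibble::tibble(
        sample_id = r$sample_id, timepoint = r$timepoint,
        depth = matched_depth, threshold = crv$threshold,
        median = crv$median, mean = crv$mean, min = crv$min, max = crv$max))
      ex <- expanded_clones(r, threshold)
      expansion_tab <- rbind(expansion_tab, tibble::tibble(
        sample_id = r$sample_id, timepoint = r$timepoint,
        threshold = threshold, n_expanded = ex$n_expanded,
        richness = richness(r),
        proportion_expanded = ex$proportion_expanded,
        read_fraction_expanded = expanded_read_fraction(r, threshold)))
      top <- top_expanded_cdr3s(r, n = top_n, threshold = threshold)
      net <- if (length(top) >= 2) build_network(top, similarity)
             else list(nodes = top, n_clusters = 0L, membership = NA)
      cluster_tab <- rbind(cluster_tab, tibble::tibble(
        sample_id = r$sample_id, timepoint = r$timepoint,
        n_top_cdr3s = length(top), similarity = similarity,
        n_clusters = net$n_clusters,
        clustered_fraction = if (length(top) > 0)
          sum(!is.na(net$membership)) / length(top) else 0))
    }
    ov <- shared_expanded_fraction(post, bl, mode = key_mode,
                                   threshold = threshold)
    ov_aa <- shared_expanded_fraction(post, bl, mode = "aa",
                                      threshold = threshold)
    overlap_tab <- rbind(overlap_tab, tibble::tibble(
      patient_id = ov$patient_id, chain = ov$chain, key_mode = ov$mode,
      n_expanded_post = ov$n_expanded_post, n_shared = ov$n_shared,
      shared_fraction = ov$shared_fraction,
      shared_fraction_aa = ov_aa$shared_fraction))
  }

  meta <- tibble::tibble(
    key = c("n_iterations", "expansion_threshold", "similarity_threshold",
            "top_n", "key_mode", "seed", "orders", "curve_thresholds",
            "tcrfocus_version"),
    value = c(n_iterations, threshold, similarity, top_n, key_mode, seed,
              paste(orders, collapse = ","),
              paste(curve_thresholds, collapse = ","),
              as.character(utils::packageVersion("tcrfocus")))
  )

  write_tsv <- function(tab, name) {
    utils::write.table(tab, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(richness_tab, "richness.tsv")
  write_tsv(renyi_tab, "renyi_profiles.tsv")
  write_tsv(curve_tab, "threshold_curves.tsv")
  write_tsv(expansion_tab, "expansion.tsv")
  write_tsv(cluster_tab, "clusters.tsv")
  write_tsv(overlap_tab, "overlap.tsv")
  write_tsv(meta, "run_config.tsv")

  if (isTRUE(write_plots)) {
    plot_cohort(renyi_tab, curve_tab, outdir)
  }
  report <- list(richness = richness_tab, renyi = renyi_tab,
                 curves = curve_tab, expansion = expansion_tab,
                 clusters = cluster_tab, overlap = overlap_tab,
                 metadata = meta)
  class(report) <- "cohort_report"
  invisible(report)
}

# diversity-profile and threshold-curve figures, one panel per patient
plot_cohort <- function(renyi_tab, curve_tab, outdir) {
  rt <- renyi_tab
  rt$order_label <- factor(ifelse(is.infinite(rt$order), "Inf",
                                  format(rt$order)),
                           levels = unique(ifelse(is.infinite(rt$order),
                                                  "Inf", format(rt$order))))
  p1 <- ggplot2::ggplot(rt, ggplot2::aes(x = order_label, y = median,
                                         colour = timepoint,
                                         group = sample_id)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~patient_id) +
    ggplot2::labs(x = "Rényi order", y = "Entropy (nats)",
                  title = "Rényi diversity profiles") +
    ggplot2::theme_minimal()
  grDevices::pdf(file.path(outdir, "renyi_profiles.pdf"), width = 8,
                 height = 6)
  print(p1)
  grDevices::dev.off()

  p2 <- ggplot2::ggplot(curve_tab,
                        ggplot2::aes(x = threshold, y = median,
                                     colour = timepoint,
                                     group = sample_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = min, ymax = max),
                           width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency threshold",
                  y = "Clones above threshold (median across iterates)",
                  title = "Threshold curves") +
    ggplot2::theme_minimal()
  grDevices::pdf(file.path(outdir, "threshold_curves.pdf"), width = 8,
                 height = 6)
  print(p2)
  grDevices::dev.off()
  invisible(NULL)
}
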