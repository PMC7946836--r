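# Small fixture builders and independent oracles used across the suite.

make_rep <- function(counts, cdr3 = NULL, chain = "alpha",
                     timepoint = "other", sample_id = "s",
                     patient_id = "p", with_nt = FALSE) {
  n <- length(counts)
  if (is.null(cdr3)) {
    cdr3 <- vapply(seq_len(n), function(i) {
      paste0("CASS", paste(rep(LETTERS[(i %% 20) + 1], 3), collapse = ""),
             sprintf("Q%02dF", i))
    }, character(1))
    cdr3 <- make.unique(cdr3, sep = "")
  }
  clones <- data.frame(cdr3_aa = cdr3, count = as.integer(counts),
                       stringsAsFactors = FALSE)
  if (with_nt) {
    clones$cdr3_nt <- vapply(seq_len(n), function(i) {
      paste(rep(c("A", "C", "G", "T"), length.out = 12 + i), collapse = "")
    }, character(1))
    clones$v_call <- paste0("TRAV", seq_len(n))
    clones$j_call <- "TRAJ1"
  }
  repertoire(clones, sample_id = sample_id, patient_id = patient_id,
             chain = chain, timepoint = timepoint)
}

random_peptide <- function(len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# brute-force 3-mer enumeration, independent of triplet_counts()
brute_triplets <- function(s) {
  n <- nchar(s)
  if (n < 3) return(structure(integer(0), names = character(0)))
  kmers <- character(n - 2)
  for (i in seq_len(n - 2)) kmers[i] <- substr(s, i, i + 2)
  tab <- table(kmers)
  structure(as.integer(tab), names = names(tab))
}

# brute-force cosine spectrum-kernel similarity from brute_triplets
brute_similarity <- function(s, t) {
  cs <- brute_triplets(s); ct <- brute_triplets(t)
  all_k <- union(names(cs), names(ct))
  vs <- vt <- numeric(length(all_k))
  names(vs) <- names(vt) <- all_k
  vs[names(cs)] <- cs; vt[names(ct)] <- ct
  sum(vs * vt) / sqrt(sum(vs^2) * sum(vt^2))
}

# independent connected-components search over an adjacency matrix (BFS)
brute_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

# random frequency vector for property tests
random_freqs <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# write a small synthetic paired cohort to disk and return the manifest path
make_cohort <- function(dir, n_patients = 2, seed = 100) {
  rows <- list()
  for (k in seq_len(n_patients)) {
    pid <- sprintf("P%02d", k)
    pr <- simulate_paired(paired_sim_config(
      n_clones_bl = 600, total_reads_bl = 9000, total_reads_post = 5000,
      n_novel_post = 100, patient_id = pid, seed = seed + k))
    for (tp in c("BL", "postASCT")) {
      r <- if (tp == "BL") pr$baseline else pr$post
      f <- file.path(dir, paste0(pid, "_", tp, ".tsv"))
      write_airr(r, f)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = r$sample_id, patient_id = pid, chain = "alpha",
        timepoint = tp, path = basename(f), stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  man_path
}
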