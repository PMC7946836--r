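test_that("triplet counting enumerates overlapping 3-mers", {
  expect_equal(triplet_counts("CASS"), c(ASS = 1L, CAS = 1L))
  expect_equal(triplet_counts("AAAA"), c(AAA = 2L))
  expect_length(triplet_counts("CA"), 0)
  expect_error(triplet_counts("CAXZ1"), "invalid amino-acid")

  set.seed(21)
  for (i in 1:50) {
    s <- random_peptide(15)
    expect_equal(triplet_counts(s), brute_triplets(s))
  }
})

test_that("kernel similarity matches brute force and its algebraic properties", {
  expect_equal(kernel_similarity("CASS", "CASSF"), 2 / sqrt(6),
               tolerance = 1e-12)
  expect_equal(kernel_similarity("CASSL", "WGYQP"), 0)
  expect_error(kernel_similarity("CA", "CASS"), "shorter than 3")

  set.seed(5)
  for (i in 1:100) {
    s <- random_peptide(sample(3:20, 1))
    t <- random_peptide(sample(3:20, 1))
    sim <- kernel_similarity(s, t)
    expect_equal(sim, brute_similarity(s, t), tolerance = 1e-12)
    expect_equal(sim, kernel_similarity(t, s), tolerance = 1e-12)  # symmetry
    expect_gte(sim, 0); expect_lte(sim, 1 + 1e-12)                 # range
    expect_equal(kernel_similarity(s, s), 1, tolerance = 1e-12)    # identity
  }
})

test_that("top expanded CDR3s are ranked by frequency with lexicographic ties", {
  rep <- make_rep(c(30, 30, 20, 5, 1),
                  cdr3 = c("CZZZAAA", "CAAAZZZ", "CBBBQQQ", "CDDDQQQ",
                           "CEEEQQQ"))
  # total 86; threshold 1/1000 -> all but none excluded; top 3 requested
  top <- top_expanded_cdr3s(rep, n = 3)
  expect_equal(top[1], "CAAAZZZ")  # tie at 30 broken lexicographically
  expect_equal(top[2], "CZZZAAA")
  expect_equal(top[3], "CBBBQQQ")

  # fewer expanded than n: all returned; short/nonproductive excluded
  rep2 <- repertoire(data.frame(
    cdr3_aa = c("CASSLGETQYF", "CA", "CASS*GETQYF", "CAWSVGQF"),
    count = c(50L, 40L, 30L, 20L)))
  top2 <- top_expanded_cdr3s(rep2, n = 50)
  expect_setequal(top2, c("CASSLGETQYF", "CAWSVGQF"))

  # planted ground truth: exactly the n most frequent expanded CDR3s
  sim <- simulate_repertoire(300, 30000, zipf_exponent = 1.5, seed = 13)
  ex <- expanded_clones(sim)$expanded
  top3 <- top_expanded_cdr3s(sim, n = 50)
  expect_length(top3, 50)
  expect_identical(top3, ex$cdr3_aa[1:50])
})

test_that("similarity networks match a brute-force component search", {
  set.seed(88)
  cdr3s <- replicate(40, random_peptide(sample(8:18, 1)))
  # add a couple of engineered near-duplicates so edges exist
  cdr3s <- unique(c(cdr3s, paste0(cdr3s[1], "F"), paste0("A", cdr3s[2])))
  net <- build_network(cdr3s, threshold = 0.6)
  n <- length(cdr3s)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- adj[j, i] <- brute_similarity(cdr3s[i], cdr3s[j]) >= 0.6
  }
  comp <- brute_components(adj)
  sizes <- table(comp)
  expect_equal(net$n_clusters, sum(sizes >= 2))
  # identical partition on clustered nodes
  for (cl in net$clusters) {
    ids <- match(cl, cdr3s)
    expect_length(unique(comp[ids]), 1)
    expect_equal(sum(comp == comp[ids[1]]), length(ids))
  }
  # every clustered node has an incident edge
  clustered <- unlist(net$clusters)
  expect_true(all(clustered %in% c(net$edges$from, net$edges$to)))
  expect_lte(net$n_clusters, floor(length(net$nodes) / 2))
})

test_that("network edge cases: duplicates rejected, trivial clusters found", {
  expect_error(build_network(c("CASSA", "CASSA")), "unique")
  net <- build_network(c("CASSLGETQYF", "CASSLGETQYW", "WGYQPWGYQP"),
                       threshold = 0.80)
  expect_equal(net$n_clusters, 1)
  expect_setequal(net$clusters[[1]], c("CASSLGETQYF", "CASSLGETQYW"))

  set.seed(66)
  randoms <- replicate(50, random_peptide(14))
  netr <- build_network(unique(randoms), threshold = 0.80)
  expect_equal(netr$n_clusters, 0)
})

test_that("raising the threshold never increases edges or clustering", {
  set.seed(14)
  cdr3s <- unique(c(replicate(30, random_peptide(sample(10, 1) + 7)),
                    "CASSLGETQYF", "CASSLGETQYW", "CASSLGETQAF"))
  prev_edges <- Inf; prev_frac <- Inf
  for (th in c(0.3, 0.5, 0.7, 0.8, 0.95)) {
    net <- build_network(cdr3s, th)
    frac <- sum(!is.na(net$membership)) / length(net$nodes)
    expect_lte(nrow(net$edges), prev_edges)
    expect_lte(frac, prev_frac)
    prev_edges <- nrow(net$edges); prev_frac <- frac
  }
})

test_that("control calibration: motif-free CDR3s barely cluster at 0.80", {
  expect_equal(calibrate_control(character(0)), 0)
  set.seed(19)
  fracs <- vapply(1:20, function(i) {
    ctrl <- unique(replicate(50, random_peptide(sample(10:18, 1))))
    calibrate_control(ctrl, 0.80)
  }, numeric(1))
  expect_lt(stats::median(fracs), 0.05)
  # threshold floor: everything connects at threshold 0
  expect_equal(calibrate_control(c("CASSA", "WGYQP", "LLLLL"), 0), 1)
})

test_that("planted motif families are recovered with high purity at 0.80", {
  sim <- simulate_repertoire(n_clones = 120, total_reads = 20000,
                             zipf_exponent = 0.8, n_motif_families = 4,
                             family_size = 5, family_core_length = 6,
                             seed = 23)
  fams <- attr(sim, "motif_families")
  members <- unlist(fams)
  # family members share the consensus minus one terminal residue
  for (fam in fams) {
    L <- nchar(fam[1])
    expect_true(all(nchar(fam) == L))
    expect_length(unique(substr(fam, 1, L - 1)), 1)
    expect_gte(L - 1, 6)
  }
  net <- build_network(members, threshold = 0.80)
  truth <- rep(seq_along(fams), lengths(fams))
  names(truth) <- members
  purity <- vapply(net$clusters, function(cl) {
    max(table(truth[cl])) / length(cl)
  }, numeric(1))
  expect_gte(length(net$clusters), 1)
  expect_gte(mean(purity), 0.9)
  # recovery: every family lands (entirely) inside some cluster
  for (fam in fams) {
    host <- vapply(net$clusters, function(cl) all(fam %in% cl), logical(1))
    expect_true(any(host))
  }
})
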