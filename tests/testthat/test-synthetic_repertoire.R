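test_that("single-repertoire generator is deterministic and well formed", {
  a <- simulate_repertoire(200, 5000, seed = 42)
  b <- simulate_repertoire(200, 5000, seed = 42)
  expect_identical(a$clones, b$clones)
  expect_equal(richness(a), 200)
  expect_equal(total_reads(a), 5000)
  expect_false(anyDuplicated(a$clones$cdr3_aa) > 0)
  expect_true(all(a$clones$count >= 1))
  expect_equal(attr(a, "count_model"), "multinomial+1")

  expect_error(simulate_repertoire(100, 50, seed = 1), "must be >=")
})

test_that("a steep power law makes the top clone dominate", {
  steep <- simulate_repertoire(100, 10000, zipf_exponent = 6, seed = 2)
  f <- clone_frequencies(steep)
  expect_gt(max(f), 0.9)
  expect_lt(renyi_entropy(f, Inf), 0.11)  # H_inf = -log(max f), small

  flat <- simulate_repertoire(100, 10000, zipf_exponent = 0.01, seed = 2)
  expect_gt(renyi_entropy(clone_frequencies(flat), Inf), 4)
})

test_that("realized top-clone frequency concentrates on its Zipf weight", {
  w1 <- (1:500)^(-1.5); w1 <- w1[1] / sum(w1)
  reals <- vapply(1:50, function(s) {
    r <- simulate_repertoire(500, 50000, zipf_exponent = 1.5, seed = s)
    clone_frequencies(r)[1]
  }, numeric(1))
  # +1 floor shifts weights by at most n/total = 1%
  expect_lt(abs(mean(reals) - w1), 0.02)
  expect_lt(stats::sd(reals), 0.02)
})

test_that("identity-limit paired config shares every clonotype", {
  pr <- simulate_paired(paired_sim_config(
    n_clones_bl = 300, total_reads_bl = 5000, total_reads_post = 5000,
    bottleneck = 1, persistence_rho = 1, expansion_boost = 1,
    n_novel_post = 0, seed = 7))
  expect_setequal(pr$post$clones$cdr3_aa, pr$baseline$clones$cdr3_aa)
  ov <- shared_expanded_fraction(pr$post, pr$baseline, "aa")
  expect_equal(ov$shared_fraction, 1)
  expect_equal(pr$truth$persistent_expanded_fraction, 1)
})

test_that("the bottleneck reduces post-treatment richness", {
  for (s in 1:5) {
    pr <- simulate_paired(paired_sim_config(
      n_clones_bl = 1000, total_reads_bl = 15000, total_reads_post = 6000,
      bottleneck = 0.3, n_novel_post = 100, seed = s))
    expect_lt(richness(pr$post), richness(pr$baseline))
  }
})

test_that("ground truth is consistent with the emitted repertoires", {
  pr <- simulate_paired(paired_sim_config(n_clones_bl = 600,
                                          total_reads_bl = 9000,
                                          total_reads_post = 5000,
                                          n_novel_post = 150, seed = 21))
  expect_true(all(pr$truth$surviving_keys %in% pr$post$clones$cdr3_aa))
  expect_true(all(pr$truth$surviving_keys %in% pr$baseline$clones$cdr3_aa))
  expect_true(all(pr$truth$novel_keys %in% pr$post$clones$cdr3_aa))
  expect_false(any(pr$truth$novel_keys %in% pr$baseline$clones$cdr3_aa))
  expect_setequal(c(pr$truth$surviving_keys, pr$truth$novel_keys),
                  pr$post$clones$cdr3_aa)
  # all randomness flows from the config seed
  pr2 <- simulate_paired(paired_sim_config(n_clones_bl = 600,
                                           total_reads_bl = 9000,
                                           total_reads_post = 5000,
                                           n_novel_post = 150, seed = 21))
  expect_identical(pr$baseline$clones, pr2$baseline$clones)
  expect_identical(pr$post$clones, pr2$post$clones)
})

test_that("config validation rejects impossible settings", {
  expect_error(paired_sim_config(bottleneck = 0), "bottleneck")
  expect_error(paired_sim_config(bottleneck = 1.2), "bottleneck")
  expect_error(paired_sim_config(persistence_rho = -0.1), "persistence_rho")
  expect_error(paired_sim_config(expansion_boost = 0), "expansion_boost")
  expect_error(
    paired_sim_config(n_clones_bl = 10, bottleneck = 0.01, n_novel_post = 0),
    "empty post-treatment")
})
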