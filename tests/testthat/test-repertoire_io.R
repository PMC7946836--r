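test_that("repertoire construction merges duplicate clonotypes and validates", {
  clones <- data.frame(
    cdr3_aa = c("CASSLG", "CASSLG", "CAWSV"),
    v_call = c("TRAV1", "TRAV1", "TRAV2"),
    j_call = c("TRAJ1", "TRAJ1", "TRAJ2"),
    count = c(2L, 3L, 1L)
  )
  rep <- make <- repertoire(clones, chain = "alpha", timepoint = "BL")
  expect_equal(richness(rep), 2)
  expect_equal(total_reads(rep), 6)
  expect_setequal(rep$clones$count, c(5L, 1L))
  expect_equal(sum(clone_frequencies(rep)), 1, tolerance = 1e-12)

  expect_error(repertoire(data.frame(cdr3_aa = "CASS", count = 0L)),
               "positive integers")
  expect_error(repertoire(data.frame(cdr3_aa = "", count = 1L)),
               "non-empty")
})

test_that("AIRR reading merges duplicates, defaults counts, and flags bad files", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count",
               "CASSLG\tTRAV1\tTRAJ1\t2",
               "CASSLG\tTRAV1\tTRAJ1\t3",
               "CAWSV\tTRAV2\tTRAJ2\t1"), tmp)
  rep <- read_airr(tmp, chain = "alpha", timepoint = "BL")
  expect_equal(richness(rep), 2)
  expect_equal(total_reads(rep), 6)

  # no duplicate_count column -> every clone counts 1
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa", "CASSLG", "CAWSV"), tmp2)
  rep2 <- read_airr(tmp2)
  expect_true(all(rep2$clones$count == 1L))

  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("v_call\tduplicate_count", "TRAV1\t2"), tmp3)
  expect_error(read_airr(tmp3), "junction_aa")

  tmp4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("junction_aa\tduplicate_count", tmp4)
  expect_error(read_airr(tmp4), "no rearrangement rows")
})

test_that("Decombinator dialect parses classifier fields and abundances", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("12, 4, 1, 2, ACGT, 57, CASSLGETQYF",
               "3, 7, 0, 1, TT, 1, CAWSVGQF",
               "5, 2, 2, 0, , 1, CAVRDSNYQLIW",
               "8, 9, 1, 1, GG, 2, CILRVGATNKLIF"), tmp)
  rep <- read_decombinator(tmp)
  expect_equal(richness(rep), 4)
  expect_equal(total_reads(rep), 61)
  first <- rep$clones[rep$clones$cdr3_aa == "CASSLGETQYF", ]
  expect_equal(first$count, 57L)
  expect_equal(first$v_call, "12")
  expect_equal(first$j_call, "4")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("12, 4, 1, 2, ACGT, 57x, CASSLGETQYF", bad)
  expect_error(read_decombinator(bad), "line 1")
})

test_that("AIRR round trip preserves keys, counts, richness and total reads", {
  set.seed(42)
  rep <- simulate_repertoire(n_clones = 1000, total_reads = 20000, seed = 9,
                             sample_id = "rt", patient_id = "pt",
                             timepoint = "BL")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_airr(rep, tmp)
  back <- read_airr(tmp, sample_id = "rt", patient_id = "pt",
                    chain = "alpha", timepoint = "BL")
  ord <- function(r) {
    cl <- as.data.frame(r$clones)
    cl[order(cl$cdr3_aa), c("cdr3_aa", "cdr3_nt", "v_call", "j_call", "count")]
  }
  a <- ord(rep); b <- ord(back)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  expect_equal(richness(back), richness(rep))
  expect_equal(total_reads(back), total_reads(rep))

  # reading twice yields identical repertoires (no hidden state)
  again <- read_airr(tmp, sample_id = "rt", patient_id = "pt",
                     chain = "alpha", timepoint = "BL")
  expect_identical(back, again)
})

test_that("manifest reading resolves relative paths and requires columns", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id\tpatient_id\tchain\ttimepoint\tpath",
               "s1\tp1\talpha\tBL\ts1.tsv"),
             file.path(dir, "manifest.tsv"))
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man$path, file.path(dir, "s1.tsv"))
  expect_equal(man$dialect, "airr")

  writeLines("sample_id\tpath", file.path(dir, "bad.tsv"))
  expect_error(read_manifest(file.path(dir, "bad.tsv")), "patient_id")
})
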