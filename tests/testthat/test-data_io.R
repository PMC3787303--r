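test_that("expression study round-trips through TSV unchanged", {
  g <- generate_study(50, seed = 3, absent_fraction = 0.1)
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_study(g$study, mp, dp)
  back <- read_expression_study(mp, dp, study_id = g$study$study_id)
  expect_identical(back$genes, g$study$genes)
  expect_identical(back$samples, g$study$samples)
  expect_equal(back$values, g$study$values, tolerance = 1e-12)
  expect_equal(back$design$condition, g$study$design$condition)

  # canonicalized TSV is byte-stable under a second write(read(.))
  mp2 <- withr::local_tempfile(fileext = ".tsv")
  dp2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_study(back, mp2, dp2)
  expect_identical(readLines(mp), readLines(mp2))
})

test_that("study construction enforces its invariants", {
  values <- matrix(1:4, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  design <- data.frame(sample = c("s1", "s2"), condition = "A",
                       replicate = 1:2)
  expect_error(expression_study("x", values, design), "duplicate gene.*g1")

  values2 <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(
    expression_study("x", values2,
                     data.frame(sample = "s1", condition = "A",
                                replicate = 1)),
    "missing from design")
  expect_error(
    expression_study("x", values2,
                     data.frame(sample = c("s1", "s2", "s3"),
                                condition = "A", replicate = 1:3)),
    "missing from matrix")
  values2[1, 1] <- NA
  expect_error(expression_study("x", values2, design = data.frame(
    sample = c("s1", "s2"), condition = "A", replicate = 1:2)),
    "non-finite")
})

test_that("non-numeric matrix cells are reported with their location", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1.5\toops", "g2\t2\t3"), mp)
  writeLines(c("sample\tcondition\treplicate", "s1\tA\t1", "s2\tA\t2"), dp)
  expect_error(read_expression_study(mp, dp), "g1.*s2.*oops")
})

test_that("linear-scale input is floored at 1 and log2-transformed", {
  values <- matrix(c(0, 2, 8, 1024), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  design <- data.frame(sample = c("s1", "s2"), condition = "A",
                       replicate = 1:2)
  st <- expression_study("lin", values, design, linear_input = TRUE)
  expect_equal(unname(st$values), matrix(c(0, 1, 3, 10), 2))
})

test_that("presence filter implements the three policies", {
  # g1 present everywhere; g2 present in both reps of condition A only;
  # g3 absent everywhere
  dp <- matrix(c(0.01, 0.01, 0.01, 0.01,
                 0.01, 0.01, 0.90, 0.90,
                 0.90, 0.90, 0.90, 0.90),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"),
                               c("A_r1", "A_r2", "B_r1", "B_r2")))
  st <- toy_study()
  calls <- presence_calls(dp)
  expect_identical(
    apply_presence_filter(st, calls, "any_sample")$genes, c("g1", "g2"))
  expect_identical(
    apply_presence_filter(st, calls, "all_samples")$genes, "g1")
  expect_identical(
    apply_presence_filter(st, calls, "all_reps_of_any_condition")$genes,
    c("g1", "g2"))

  # all present -> no-op under any policy
  all_p <- presence_calls(matrix(0.01, 3, 4, dimnames = dimnames(dp)))
  for (pol in c("any_sample", "all_samples", "all_reps_of_any_condition"))
    expect_identical(apply_presence_filter(st, all_p, pol)$genes, st$genes)

  # misaligned calls are rejected
  bad <- presence_calls(dp[1:2, ])
  expect_error(apply_presence_filter(st, bad), "not aligned")
})

test_that("presence policies are monotone: all_samples <= all_reps <= any", {
  for (s in 1:20) {
    set.seed(s)
    g <- generate_study(40, conditions = c("A", "B"), reps = 3,
                        seed = s)
    dp <- matrix(runif(40 * 6), 40, 6,
                 dimnames = dimnames(g$study$values))
    calls <- presence_calls(dp)
    g_all <- apply_presence_filter(g$study, calls, "all_samples")$genes
    g_rep <- apply_presence_filter(g$study, calls,
                                   "all_reps_of_any_condition")$genes
    g_any <- apply_presence_filter(g$study, calls, "any_sample")$genes
    expect_true(all(g_all %in% g_rep))
    expect_true(all(g_rep %in% g_any))
  }
})

test_that("presence calls round-trip through the combined call:p TSV", {
  dp <- matrix(c(0.001, 0.03, 0.055, 0.4), 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  calls <- presence_calls(dp)
  expect_identical(unname(calls$call),
                   matrix(c("P", "P", "M", "A"), 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_presence_calls(calls, path)
  back <- read_presence_calls(path)
  expect_identical(back$call, calls$call)
  expect_equal(back$detection_p, calls$detection_p, tolerance = 1e-5)
})

test_that("bin annotation builds the ancestor closure and deduplicates", {
  tab <- data.frame(bin_path = c("10.2.1", "10.2.1", "3"),
                    bin_name = c("leaf", "leaf", "top3"),
                    gene_id = c("g1", "g1", "g2"))
  ann <- bin_annotation(tab)
  expect_setequal(ann$bins$path, c("10", "10.2", "10.2.1", "3"))
  # membership propagates to every ancestor and is deduplicated
  expect_identical(bin_members(ann, "10.2.1"), "g1")
  expect_identical(bin_members(ann, "10.2"), "g1")
  expect_identical(bin_members(ann, "10"), "g1")
  expect_identical(bin_members(ann, "3"), "g2")
  expect_identical(nrow(ann$direct), 2L)
  # parents recorded
  expect_identical(ann$bins$parent[ann$bins$path == "10.2.1"], "10.2")

  expect_error(bin_annotation(data.frame(bin_path = "10..1",
                                         bin_name = "x", gene_id = "g")),
               "malformed bin path")

  empty <- bin_annotation(data.frame())
  expect_identical(nrow(empty$bins), 0L)
})

test_that("bin annotation round-trips through TSV", {
  tab <- data.frame(bin_path = c("1.1", "1.2", "2"),
                    bin_name = c("a", "b", "c"),
                    gene_id = c("g1", "g2", "g1"))
  ann <- bin_annotation(tab)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bin_annotation(ann, path)
  back <- read_bin_annotation(path)
  expect_identical(back$bins, ann$bins)
  expect_identical(back$members, ann$members)
})

test_that("ancestor closure holds on generated annotations", {
  set.seed(9)
  genes <- sprintf("g%03d", 1:200)
  leaves <- as.vector(outer(1:5, 1:3, paste, sep = "."))
  tab <- data.frame(bin_path = sample(leaves, 400, TRUE),
                    bin_name = "x",
                    gene_id = sample(genes, 400, TRUE))
  ann <- bin_annotation(tab)
  for (b in ann$bins$path[!is.na(ann$bins$parent)]) {
    parent <- ann$bins$parent[ann$bins$path == b]
    expect_true(all(bin_members(ann, b) %in% bin_members(ann, parent)))
  }
})
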