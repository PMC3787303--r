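test_that("background sd pools squared sds over the rank window", {
  # constant sd field: any window returns the shared sd
  expect_equal(background_sd(rnorm(20), rep(0.5, 20), 5), rep(0.5, 20))
  # window of 1 degenerates to each gene's own sd
  sds <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(background_sd(1:5, sds, 1), sds)
  # hand-enumerated window of 3 around the middle gene
  bg <- background_sd(1:5, sds, 3)
  expect_equal(bg[3], sqrt((0.04 + 0.09 + 0.16) / 3))
  # edge windows are truncated, not shifted
  expect_equal(bg[1], sqrt((0.01 + 0.04) / 2))
  expect_equal(bg[5], sqrt((0.16 + 0.25) / 2))
  # ranking by means, not input order
  bg_perm <- background_sd(c(5, 4, 3, 2, 1), sds, 3)
  expect_equal(bg_perm[3], sqrt((0.04 + 0.09 + 0.16) / 3))
  expect_error(background_sd(1, 0.1, 3), "at least 2 genes")
})

test_that("regularized t matches direct arithmetic on a 3-gene study", {
  # window 3 covers all genes, so each group's background variance is the
  # mean of its three observed variances; everything below is recomputed
  # from the raw numbers with plain arithmetic
  values <- matrix(c(7.0, 7.2, 9.1, 8.9,
                     5.0, 5.1, 5.2, 4.9,
                     8.0, 8.3, 8.1, 8.2),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("A_r1", "A_r2", "B_r1", "B_r2")))
  st <- toy_study()
  spec <- contrast_spec("toy", "B v A", c("A_r1", "A_r2"),
                        c("B_r1", "B_r2"))
  v0 <- 2
  res <- cybert_contrast(st, spec, cybert_params(window_size = 3, v0 = v0))

  va <- apply(values[, 1:2], 1, var)      # observed within-group variances
  vb <- apply(values[, 3:4], 1, var)
  # window-3 background variances, enumerated by hand: the window is
  # centered on each gene in the ranking by group mean and truncated at the
  # edges, so the extreme-ranked genes pool over two genes, the middle one
  # over all three. Group A means rank g2 < g1 < g3; group B g2 < g3 < g1.
  s0a <- c(g1 = (va[["g2"]] + va[["g1"]] + va[["g3"]]) / 3,
           g2 = (va[["g2"]] + va[["g1"]]) / 2,
           g3 = (va[["g1"]] + va[["g3"]]) / 2)
  s0b <- c(g1 = (vb[["g3"]] + vb[["g1"]]) / 2,
           g2 = (vb[["g2"]] + vb[["g3"]]) / 2,
           g3 = (vb[["g2"]] + vb[["g3"]] + vb[["g1"]]) / 3)
  ra <- (v0 * s0a + 1 * va) / (v0 + 1)    # convex shrinkage, n - 1 = 1
  rb <- (v0 * s0b + 1 * vb) / (v0 + 1)
  m_diff <- rowMeans(values[, 3:4]) - rowMeans(values[, 1:2])
  t_exp <- m_diff / sqrt(ra / 2 + rb / 2)
  p_exp <- 2 * pt(abs(t_exp), df = 2 + 2 - 2 + 2 * v0, lower.tail = FALSE)
  expect_equal(res$t, unname(t_exp), tolerance = 1e-12)
  expect_equal(res$p, unname(p_exp), tolerance = 1e-12)
  expect_equal(res$log2fc, unname(m_diff), tolerance = 1e-12)
})

test_that("v0 = 0 reduces exactly to the classical Welch statistic", {
  g <- generate_study(200, seed = 5)
  st <- g$study
  spec <- contrast_spec(st$study_id, "t v c",
                        condition_samples(st, "control"),
                        condition_samples(st, "treatment"))
  res <- cybert_contrast(st, spec, cybert_params(v0 = 0))
  xa <- st$values[, spec$group_a]; xb <- st$values[, spec$group_b]
  tw <- (rowMeans(xb) - rowMeans(xa)) /
    sqrt(apply(xa, 1, var) / 3 + apply(xb, 1, var) / 3)
  expect_equal(res$t, unname(tw), tolerance = 1e-10)
})

test_that("identical groups give zero fold-change, zero t, p = 1", {
  values <- matrix(rep(c(5, 6, 5, 6), each = 2), nrow = 2,
                   dimnames = list(c("g1", "g2"),
                                   c("A_r1", "A_r2", "B_r1", "B_r2")))
  values[, 3:4] <- values[, 1:2]
  st <- expression_study("sym", values, data.frame(
    sample = colnames(values), condition = rep(c("A", "B"), each = 2),
    replicate = rep(1:2, 2)))
  res <- cybert_contrast(st, contrast_spec("sym", "B v A",
                                           c("A_r1", "A_r2"),
                                           c("B_r1", "B_r2")))
  expect_equal(res$log2fc, c(0, 0))
  expect_equal(res$t, c(0, 0))
  expect_equal(res$p, c(1, 1))
})

test_that("swapping groups negates log2fc and t and preserves p", {
  g <- generate_study(300, de_fraction = 0.2, seed = 8)
  st <- g$study
  a <- condition_samples(st, "control"); b <- condition_samples(st, "treatment")
  fwd <- cybert_contrast(st, contrast_spec(st$study_id, "f", a, b))
  rev <- cybert_contrast(st, contrast_spec(st$study_id, "r", b, a))
  expect_equal(rev$log2fc, -fwd$log2fc, tolerance = 1e-12)
  expect_equal(rev$t, -fwd$t, tolerance = 1e-12)
  expect_equal(rev$p, fwd$p, tolerance = 1e-12)
})

test_that("orientation -1 flips reported fold-changes only", {
  g <- generate_study(100, de_fraction = 0.2, seed = 12)
  st <- g$study
  a <- condition_samples(st, "control"); b <- condition_samples(st, "treatment")
  plus <- cybert_contrast(st, contrast_spec(st$study_id, "p", a, b, 1))
  minus <- cybert_contrast(st, contrast_spec(st$study_id, "m", a, b, -1))
  expect_equal(minus$log2fc, -plus$log2fc)
  expect_equal(minus$t, plus$t)
})

test_that("regularized variance lies between background and observed", {
  g <- generate_study(500, de_fraction = 0.1, seed = 21)
  st <- g$study
  xa <- st$values[, condition_samples(st, "control")]
  va <- pmax(apply(xa, 1, var), 1e-8)
  for (v0 in c(1, 5, 10, 50)) {
    s0 <- background_sd(rowMeans(xa), sqrt(va), 101)
    ra <- (v0 * s0^2 + 2 * va) / (v0 + 2)
    expect_true(all(ra >= pmin(s0^2, va) - 1e-12))
    expect_true(all(ra <= pmax(s0^2, va) + 1e-12))
  }
})

test_that("beta-uniform mixture recovers its own simulation truth", {
  set.seed(42)
  n <- 20000
  from_beta <- runif(n) > 0.7
  p <- ifelse(from_beta, rbeta(n, 0.3, 1), runif(n))
  f <- fit_bum_ppde(p)
  expect_lt(abs(f$fit$lambda - 0.7), 0.05)
  expect_lt(abs(f$fit$a - 0.3), 0.05)
})

test_that("uniform p-values yield a null-dominated fit with low PPDE", {
  set.seed(31)
  f <- fit_bum_ppde(runif(10000))
  expect_gte(f$fit$lambda, 0.95)
  expect_lte(median(f$ppde), 0.1)
})

test_that("ppde is non-increasing in p and tends to 1 as p tends to 0", {
  set.seed(13)
  p_train <- c(rbeta(2000, 0.3, 1), runif(4000))
  fit <- fit_bum_ppde(p_train)$fit
  grid <- sort(c(1e-10, 1e-6, 1e-4, 0.01, 0.1, 0.5, 1))
  fb <- fit$a * grid^(fit$a - 1)
  ppde <- (1 - fit$lambda) * fb / (fit$lambda + (1 - fit$lambda) * fb)
  expect_true(all(diff(ppde) <= 1e-12))
  expect_gt(ppde[1], 0.999)
})

test_that("the three-part call needs fold, p and ppde together", {
  res <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    log2fc = c(1.1, 0.9, -3, -1.5),
                    t = 0, p = c(0.01, 0.001, 0.2, 0.01),
                    ppde = c(0.99, 0.99, 0.5, 0.99))
  out <- call_de(res)
  expect_identical(out$call, c("up", "ns", "ns", "down"))
  expect_error(call_de(res[, setdiff(names(res), "ppde")]), "ppde")
})

test_that("step-wise contrasts pair each timepoint with its predecessor", {
  tc <- generate_timecourse(100, timepoints = 4, reps = 3, seed = 2)
  specs <- stepwise_contrasts(tc$study, "timecourse")
  expect_length(specs, 3)
  expect_identical(vapply(specs, `[[`, "", "name"),
                   c("2 v 1", "3 v 2", "4 v 3"))
  # earlier timepoint is always the reference
  d <- tc$study$design
  expect_setequal(specs[[1]]$group_a, d$sample[d$timepoint == 1])
  expect_setequal(specs[[1]]$group_b, d$sample[d$timepoint == 2])

  tc2 <- generate_timecourse(100, timepoints = 2, reps = 3, seed = 2)
  expect_length(stepwise_contrasts(tc2$study, "timecourse"), 1)

  # single timepoint -> empty list
  one <- tc$study
  one$design$timepoint <- 1L
  expect_length(stepwise_contrasts(one, "timecourse"), 0)

  # a timepoint with < 2 replicates is rejected
  crippled <- tc$study$design
  keep <- !(crippled$timepoint == 2 & crippled$replicate > 1)
  st <- expression_study("c", tc$study$values[, crippled$sample[keep]],
                         crippled[keep, ])
  expect_error(stepwise_contrasts(st, "timecourse"), "< 2 replicates")
})
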