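bins10 <- sprintf("%d.1", 1:10)

test_that("conserved categories demand a hit in every study", {
  o1 <- fake_ora(bins10, sig_up = c("1.1", "2.1", "3.1"), contrast = "s1")
  o2 <- fake_ora(bins10, sig_up = c("1.1", "3.1"), contrast = "s2")
  o3 <- fake_ora(bins10, sig_up = c("1.1", "2.1"), contrast = "s3")
  out <- conserved_categories(list(a = o1, b = o2, c = o3), "up")
  expect_identical(out$bin, "1.1")      # 2.1 and 3.1 miss one study each

  # identical single-bin tables are returned as conserved
  one <- fake_ora("9.9", sig_up = "9.9")
  expect_identical(conserved_categories(list(one, one), "up")$bin, "9.9")
  expect_error(conserved_categories(list(one), "up"), ">= 2")
})

test_that("timing detail records shared step intervals", {
  # a bin significant at the same interval in two designated studies
  mk <- function(intervals, nm) {
    do.call(rbind, lapply(intervals, function(iv)
      fake_ora("5.1", sig_up = "5.1", contrast = iv)))
  }
  aero <- mk(c("2 v 1"), "aero")
  anae <- mk(c("2 v 1", "3 v 2"), "anae")
  other <- fake_ora("5.1", sig_up = "5.1", contrast = "x")
  out <- conserved_categories(list(aero = aero, anae = anae, ext = other),
                              "up", timing_pair = c("aero", "anae"))
  expect_true(out$timing_match)
  expect_identical(out$intervals.anae, "2 v 1,3 v 2")

  # different intervals -> no timing match
  anae2 <- mk(c("3 v 2"), "anae")
  out2 <- conserved_categories(list(aero = aero, anae = anae2, ext = other),
                               "up", timing_pair = c("aero", "anae"))
  expect_false(out2$timing_match)
})

test_that("condition-specific rule equals (T intersect C) minus union(E)", {
  # the worked example: in target and corequired, absent from excluded
  t1 <- fake_ora(bins10, sig_up = c("1.1", "2.1"))
  c1 <- fake_ora(bins10, sig_up = c("1.1", "2.1", "3.1"))
  e1 <- fake_ora(bins10, sig_up = "2.1")
  expect_identical(
    condition_specific_categories(t1, c1, list(e1), "up"), "1.1")

  # brute-force set algebra on random instances
  set.seed(41)
  for (i in 1:200) {
    pick <- function() bins10[runif(10) < 0.4]
    st <- pick(); sc <- pick(); se1 <- pick(); se2 <- pick()
    got <- condition_specific_categories(
      fake_ora(bins10, sig_up = st), fake_ora(bins10, sig_up = sc),
      list(fake_ora(bins10, sig_up = se1), fake_ora(bins10, sig_up = se2)),
      "up")
    expect_setequal(got, setdiff(intersect(st, sc), union(se1, se2)))
  }
})

test_that("species consensus matches the hand truth table exhaustively", {
  # quorums 3-of-4 (species a) and 4-of-5 (species b)
  truth <- function(ca, cb) {
    if (ca >= 3 && cb == 0) "a_only"
    else if (cb >= 4 && ca == 0) "b_only"
    else if (ca >= 1 && cb >= 1) "both"
    else "neither"
  }
  for (ca in 0:4) for (cb in 0:5)
    expect_identical(classify_consensus(ca, cb, 3, 4), truth(ca, cb),
                     info = sprintf("count_a=%d count_b=%d", ca, cb))
})

test_that("species consensus counts hits per comparison correctly", {
  mem <- function(contrast, sig)
    list(study_id = "s", contrast = contrast,
         ora = fake_ora(bins10, sig_up = sig))
  set_a <- study_set("a", list(mem("a1", c("1.1", "2.1")),
                               mem("a2", "1.1"), mem("a3", "1.1"),
                               mem("a4", "3.1")))
  set_b <- study_set("b", list(mem("b1", "3.1"), mem("b2", "3.1"),
                               mem("b3", "3.1"), mem("b4", "3.1"),
                               mem("b5", character())))
  out <- species_consensus(set_a, set_b, 3, 4, "up")
  expect_identical(out$class[out$bin == "1.1"], "a_only")   # 3 of 4, 0
  expect_identical(out$class[out$bin == "2.1"], "neither")  # 1 of 4, 0
  expect_identical(out$class[out$bin == "3.1"], "both")     # 1 and 4
  # permutation of members does not change the classification
  out_p <- species_consensus(
    study_set("a", rev(set_a$members)),
    study_set("b", rev(set_b$members)), 3, 4, "up")
  expect_identical(out_p[order(out_p$bin), ], out[order(out$bin), ])
  expect_error(species_consensus(set_a, set_b, 5, 4), "quorum exceeds")
})

test_that("duplicate contrast names within a study set are rejected", {
  mem <- list(study_id = "s", contrast = "c1",
              ora = fake_ora(bins10, sig_up = "1.1"))
  expect_error(study_set("dup", list(mem, mem)), "duplicate contrast")
})

test_that("overlap counts equal brute-force intersections in both modes", {
  genes <- sprintf("g%03d", 1:60)
  set.seed(19)
  for (i in 1:100) {
    de_lo <- lapply(1:2, function(j)
      fake_de(genes, up = sample(genes, 10), down = sample(genes, 8)))
    de_ab <- lapply(1:3, function(j)
      fake_de(genes, up = sample(genes, 12), down = sample(genes, 5)))
    lo <- study_set("lo", lapply(seq_along(de_lo), function(j)
      list(study_id = "s", contrast = paste0("l", j), de = de_lo[[j]])))
    ab <- study_set("ab", lapply(seq_along(de_ab), function(j)
      list(study_id = "s", contrast = paste0("a", j), de = de_ab[[j]])))
    any_mode <- overlap_counts(lo, ab, "any_direction")
    matched <- overlap_counts(lo, ab, "matched")
    for (x in 1:2) for (y in 1:3) {
      dl <- de_lo[[x]]; da <- de_ab[[y]]
      expect_identical(any_mode[x, y], length(intersect(
        dl$gene[dl$call != "ns"], da$gene[da$call != "ns"])))
      expect_identical(matched[x, y],
        length(intersect(dl$gene[dl$call == "up"],
                         da$gene[da$call == "up"])) +
        length(intersect(dl$gene[dl$call == "down"],
                         da$gene[da$call == "down"])))
    }
  }
  # pinned corner cases: disjoint and identical DE sets
  lo1 <- study_set("lo", list(list(study_id = "s", contrast = "l",
                                   de = fake_de(genes, up = genes[1:10]))))
  ab_dis <- study_set("ab", list(list(study_id = "s", contrast = "a",
                                      de = fake_de(genes, up = genes[11:20]))))
  ab_same <- study_set("ab", list(list(study_id = "s", contrast = "a",
                                       de = fake_de(genes, up = genes[1:10]))))
  expect_identical(overlap_counts(lo1, ab_dis)[1, 1], 0L)
  expect_identical(overlap_counts(lo1, ab_same)[1, 1], 10L)
})

test_that("marker rule applies fold quorum and abiotic exclusion", {
  genes <- c("m1", "m2", "m3", "weak")
  lfc <- function(folds) log2(folds)
  # m1: 60-fold in 2 of 4; m2: 60-fold twice but abiotic-up; m3: 60-fold
  # once only; weak: 49-fold everywhere
  de <- list(
    fake_de(genes, up = c("m1", "m2", "m3", "weak"),
            log2fc = lfc(c(60, 60, 60, 49)), contrast = "c1"),
    fake_de(genes, up = c("m1", "m2", "weak"),
            log2fc = lfc(c(70, 55, 1, 49)), contrast = "c2"),
    fake_de(genes, up = "weak", log2fc = lfc(c(1, 1, 1, 49)),
            contrast = "c3"),
    fake_de(genes, log2fc = c(0, 0, 0, 0), contrast = "c4"))
  lo <- study_set("lo", lapply(seq_along(de), function(j)
    list(study_id = "s", contrast = paste0("c", j), de = de[[j]])))
  ab <- study_set("ab", list(list(study_id = "s", contrast = "salt",
                                  de = fake_de(genes, up = "m2",
                                               log2fc = lfc(c(1, 3, 1, 1))))))
  out <- find_marker_genes(lo, fold_min = 50, k_min = 2, abiotic = ab,
                           exclude_abiotic_up = TRUE)
  expect_identical(out$gene, "m1")
  expect_identical(out$n_passing, 2L)
  expect_equal(out$max_fold, 70)
  # without the exclusion m2 qualifies too, sorted by fold within quorum
  out2 <- find_marker_genes(lo, fold_min = 50, k_min = 2, abiotic = ab,
                            exclude_abiotic_up = FALSE)
  expect_identical(out2$gene, c("m1", "m2"))
  expect_true(out2$abiotic_up[out2$gene == "m2"])
})

test_that("degenerate marker parameters return the union of up calls", {
  genes <- sprintf("g%03d", 1:50)
  set.seed(23)
  de <- lapply(1:3, function(j) fake_de(genes, up = sample(genes, 8),
                                        down = sample(genes, 5)))
  lo <- study_set("lo", lapply(seq_along(de), function(j)
    list(study_id = "s", contrast = paste0("c", j), de = de[[j]])))
  out <- find_marker_genes(lo, fold_min = 2, k_min = 1,
                           exclude_abiotic_up = FALSE)
  expect_setequal(out$gene,
                  unique(unlist(lapply(de, function(d)
                    d$gene[d$call == "up"]))))
})

test_that("marker finder agrees with a brute-force reimplementation", {
  genes <- sprintf("g%03d", 1:40)
  set.seed(29)
  for (i in 1:100) {
    de <- lapply(1:4, function(j) {
      up <- sample(genes, 6)
      fake_de(genes, up = up,
              log2fc = ifelse(genes %in% up, runif(40, 1.1, 7), 0),
              contrast = paste0("c", j))
    })
    lo <- study_set("lo", lapply(seq_along(de), function(j)
      list(study_id = "s", contrast = paste0("c", j), de = de[[j]])))
    ab_up <- sample(genes, 5)
    ab <- study_set("ab", list(list(study_id = "s", contrast = "a",
                                    de = fake_de(genes, up = ab_up))))
    got <- find_marker_genes(lo, fold_min = 8, k_min = 2, abiotic = ab,
                             exclude_abiotic_up = TRUE)
    # brute force: count per gene the comparisons with up call above fold
    brute <- vapply(genes, function(g) {
      sum(vapply(de, function(d)
        d$call[d$gene == g] == "up" && d$log2fc[d$gene == g] > log2(8),
        TRUE))
    }, 0L)
    expected <- setdiff(names(brute)[brute >= 2], ab_up)
    expect_setequal(got$gene, expected)
  }
})
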