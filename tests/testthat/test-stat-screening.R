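test_that("window statistics match a loop-based recomputation", {
  m <- matrix(10, 50, 36, dimnames = list(NULL, feature_names()))
  st <- window_stats(m)
  expect_length(st, 108)
  expect_equal(st[["avgBTL_Mean"]], 10)
  expect_equal(st[["avgBTL_Std"]], 0)
  expect_equal(st[["avgBTL_Max"]], 10)

  m2 <- m; m2[, "aTHR"] <- 1:50
  st2 <- window_stats(m2)
  expect_equal(st2[["aTHR_Mean"]], 25.5)
  expect_equal(st2[["aTHR_Max"]], 50)

  set.seed(3)
  m3 <- matrix(rnorm(50 * 36), 50, 36, dimnames = list(NULL, feature_names()))
  m3[sample(length(m3), 60)] <- NA  # missing COP-style entries
  expect_equal(window_stats(m3), oracle_window_stats(m3))
})

test_that("Lilliefors test holds its level, has power, and flags degeneracy", {
  cfgs <- screening_config(lilliefors_mc_reps = 2000, seed = 99)
  set.seed(11)
  h_null <- replicate(100, lilliefors_test(rnorm(25), cfgs)$h)
  expect_gte(mean(h_null == 0), 0.9)

  h_exp <- replicate(100, lilliefors_test(rexp(25), cfgs)$h)
  expect_gt(mean(h_exp == 1), 0.5)

  deg <- lilliefors_test(rep(4, 10), cfgs)
  expect_equal(deg$h, 1L)
  expect_true(deg$degenerate)

  expect_error(lilliefors_test(rnorm(4), cfgs), "n >= 5")
})

test_that("Lilliefors agrees with an independent implementation", {
  skip_if_not_installed("nortest")
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(50, 3, 2)
    ours <- lilliefors_test(x, screening_config(lilliefors_mc_reps = 20000,
                                                seed = 5))
    ref <- nortest::lillie.test(x)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 0.05)
  }
})

test_that("signed-rank p equals exhaustive enumeration, ties and zeros included", {
  set.seed(17)
  cases <- c(
    lapply(5:12, function(n) rnorm(n)),                  # continuous
    lapply(5:12, function(n) sample(-3:3, n, TRUE)),     # heavy ties + zeros
    list(c(2, 2, 2, -2), c(1, 1, 1, 1, -1), rep(0.5, 8))
  )
  for (d in cases) {
    got <- signed_rank_test(d)
    expect_true(got$exact)
    expect_equal(got$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  # tie-free case against the stats reference
  d <- rnorm(12)
  expect_equal(signed_rank_test(d)$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("signed-rank exact path extends to n = 25 without ties", {
  set.seed(29)
  for (i in 1:5) {
    d <- rnorm(25)
    expect_equal(signed_rank_test(d)$p_value,
                 stats::wilcox.test(d, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_equal(signed_rank_test(rep(0, 10))$p_value, 1)
})

test_that("effect sizes follow their definitions and degeneracy conventions", {
  expect_true(is.na(cohens_d_paired(c(1, 1, 1, 1))))
  expect_equal(cohens_d_paired(c(0, 2, 4)), 2 / 2)
  # |d| = (2,2,2,2): average ranks 2.5 each; W+ = 7.5, W- = 2.5
  expect_equal(rank_biserial(c(2, 2, 2, -2)), 0.5)
  expect_equal(rank_biserial(c(3, 1, 2)), 1)
  expect_equal(rank_biserial(-c(3, 1, 2)), -1)
  expect_true(is.na(rank_biserial(c(0, 0))))
  set.seed(31)
  d_hat <- replicate(500, cohens_d_paired(rnorm(25, 1, 1)))
  expect_equal(mean(d_hat), 1, tolerance = 0.15)
})

test_that("the paired screen gates by normality, flags significance and ranks by effect", {
  set.seed(5)
  n <- 25
  D <- cbind(
    shifted = rnorm(n, 2, 1),            # strong planted effect
    null = rnorm(n),                     # no effect
    zeros = rep(0, n),                   # degenerate
    skewed = rexp(n) - log(2),           # non-normal, ~zero median
    big = rnorm(n, 5, 1)                 # even stronger effect
  )
  rec <- paired_screen(D, screening_config(seed = 2))
  expect_equal(nrow(rec), 5)
  z <- rec[rec$feature == "zeros", ]
  expect_equal(z$test_used, "wilcoxon_signed_rank")
  expect_equal(z$p_value, 1)
  expect_false(z$significant)
  expect_true(rec[rec$feature == "shifted", "significant"])
  expect_lt(rec[rec$feature == "shifted", "p_value"], 0.005)
  expect_false(rec[rec$feature == "null", "significant"])
  # branch bookkeeping: paired_t iff normality not rejected
  expect_true(all((rec$test_used == "paired_t") == (rec$normality_h == 0),
                  na.rm = TRUE))
  # ranking by |effect| among significant features: 'big' before 'shifted'
  expect_lt(rec[rec$feature == "big", "rank"],
            rec[rec$feature == "shifted", "rank"])
})

test_that("planted-shift screening power is essentially one", {
  set.seed(7)
  cfgs <- screening_config(lilliefors_mc_reps = 2000, seed = 3)
  hits <- replicate(200, {
    D <- matrix(rnorm(25, 2, 1), ncol = 1, dimnames = list(NULL, "avgTHL_Mean"))
    paired_screen(D, cfgs)$significant
  })
  expect_gte(mean(hits), 0.99)
})

test_that("forcing either branch rarely flips significance on strong effects", {
  set.seed(13)
  agree <- replicate(100, {
    d <- rnorm(25, 1.2, 1)
    (stats::t.test(d)$p.value < 0.005) ==
      (signed_rank_test(d)$p_value < 0.005)
  })
  expect_gte(mean(agree), 0.95)
})

test_that("region summaries count significant features per region", {
  rec <- data.frame(
    feature = c(paste0("avgTHL_f", 1:11), paste0("avgBTR_f", 1:9),
                paste0("avgLB_f", 1:20), paste0("avgUB_f", 1:5)),
    significant = c(rep(TRUE, 40), rep(FALSE, 5)))
  rec$region <- feature_region(rec$feature)
  rs <- region_summary(rec)
  expect_equal(sum(rs$n_significant), 40)
  expect_equal(rs$share[rs$region == "THL"], 11 / 40)
  expect_equal(sum(rs$share), 1)

  none <- region_summary(data.frame(feature = "avgTHL_Mean", region = "THL",
                                    significant = FALSE))
  expect_equal(nrow(none), 0)
})

test_that("the volcano table maps p-values and flags missing entries", {
  rec <- data.frame(feature = c("a_THL", "b_LB", "c_UB"),
                    region = c("THL", "LB", "UB"),
                    effect_size = c(1.2, -0.5, NA),
                    p_value = c(0.005, 1e-6, NA),
                    significant = c(FALSE, TRUE, FALSE))
  v <- volcano_table(rec)
  expect_equal(nrow(v), 3)
  expect_equal(v$neg_log10_p[1], -log10(0.005), tolerance = 1e-12)
  expect_equal(v$neg_log10_p[1], 2.3010, tolerance = 1e-4)
  expect_true(v$missing[3])
})

test_that("SAM validation reports medians, quartiles and exact paired p-values", {
  calm <- data.frame(subject = paste0("S", 1:6),
                     valence = c(5, 6, 5, 5, 4, 6),
                     arousal = c(2, 3, 2, 2, 3, 2),
                     dominance = c(8, 7, 8, 8, 7, 8))
  anx <- data.frame(subject = paste0("S", 1:6),
                    valence = c(2, 3, 1, 2, 2, 3),
                    arousal = c(8, 8, 9, 8, 7, 8),
                    dominance = c(2, 3, 2, 2, 3, 2))
  sv <- sam_validation(calm, anx)
  expect_equal(sv$dimension, c("valence", "arousal", "dominance"))
  expect_equal(sv$median_calm[1], 5)
  expect_equal(sv$median_anxious[2], 8)
  for (i in 1:3) {
    dcol <- sv$dimension[i]
    expect_equal(sv$p_value[i],
                 oracle_signed_rank_p(anx[[dcol]] - calm[[dcol]]),
                 tolerance = 1e-12)
  }

  same <- sam_validation(calm, calm)
  expect_true(all(same$p_value == 1))
  expect_equal(same$median_calm, same$median_anxious)
})

test_that("generated SAM cohorts separate strongly in all three dimensions", {
  ok <- replicate(20, {
    s <- sample.int(1e6, 2)
    sv <- sam_validation(generate_sam_records(30, "calm", s[1]),
                         generate_sam_records(30, "anxious", s[2]))
    all(sv$p_value < 0.001)
  })
  expect_gte(mean(ok), 0.95)
})
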