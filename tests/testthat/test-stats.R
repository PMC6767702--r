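test_that("one-way ANOVA matches the hand-computed decomposition", {
  res <- anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  # SS_between = 13.5 on 1 df, SS_within = 4 on 4 df -> F = 13.5
  expect_equal(res$f, 13.5)
  expect_equal(res$df, c(1, 4))
  expect_equal(res$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
})

test_that("identical groups give F = 0, p = 1; zero variance is flagged undefined", {
  same <- anova_oneway(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)
  const <- anova_oneway(list(a = c(1, 1), b = c(2, 2)))
  expect_true(is.na(const$f))
})

test_that("two-group ANOVA equals the squared pooled t test", {
  set.seed(7)
  for (i in 1:5) {
    g1 <- rnorm(6); g2 <- rnorm(8, mean = 0.5)
    res <- anova_oneway(list(a = g1, b = g2))
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("group label permutation leaves the ANOVA unchanged", {
  g <- list(a = c(5, 6, 7), b = c(1, 3, 2), c = c(9, 9.5, 8))
  r1 <- anova_oneway(g)
  r2 <- anova_oneway(g[c("c", "a", "b")])
  expect_equal(r2$f, r1$f)
  expect_equal(r2$p, r1$p)
})

test_that("null p-values are approximately uniform", {
  set.seed(11)
  p <- replicate(2000, {
    anova_oneway(list(a = rnorm(5), b = rnorm(5), c = rnorm(5)))$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("subject aggregation reduces to ANOVA on the subject means", {
  values <- c(10, 10, 12, 12, 20, 20, 22, 22)
  group <- rep(c("young", "old"), each = 4)
  subject <- rep(c("s1", "s2", "s3", "s4"), each = 2)
  res <- anova_subject_aware(values, group, subject)
  by_hand <- anova_oneway(list(young = c(10, 12), old = c(20, 22)))
  expect_equal(res$f, by_hand$f)
  expect_equal(res$df, by_hand$df)
  expect_equal(unname(res$subjects_per_group), c(2, 2), ignore_attr = TRUE)
})

test_that("single-subject groups are retained but flagged", {
  expect_warning(
    res <- anova_subject_aware(c(1, 2, 3, 4, 5, 6),
                               group = c("a", "a", "a", "a", "b", "b"),
                               subject = c("s1", "s1", "s2", "s2", "s3", "s3")),
    "single subject")
  expect_identical(res$flagged_groups, "b")
})

test_that("subject-aware ANOVA detects a large between-group effect", {
  # group means two observation-level SDs apart (d = 2), modest
  # between-subject variability, 3 subjects per group: power > 0.8
  set.seed(13)
  hits <- mean(replicate(400, {
    subj_effect <- rnorm(6, sd = 0.3)
    group_effect <- rep(c(0, 2), each = 3)
    values <- rep(group_effect + subj_effect, each = 10) + rnorm(60, sd = 1)
    anova_subject_aware(values, rep(c("a", "b"), each = 30),
                        rep(1:6, each = 10))$p < 0.05
  }))
  expect_gt(hits, 0.8)
})

test_that("naive pooling inflates type-I error where aggregation does not", {
  set.seed(17)
  reps <- 500
  p_pooled <- numeric(reps)
  p_agg <- numeric(reps)
  for (i in seq_len(reps)) {
    # no group effect, strong subject effect, many observations per subject
    subj_means <- rnorm(6, sd = 1)
    values <- rep(subj_means, each = 15) + rnorm(90, sd = 0.5)
    group <- rep(c("a", "b"), each = 45)
    subject <- rep(1:6, each = 15)
    p_pooled[i] <- anova_oneway(split(values, group))$p
    p_agg[i] <- suppressWarnings(
      anova_subject_aware(values, group, subject)$p)
  }
  expect_gt(mean(p_pooled < 0.05), 0.15)   # pooling is badly anticonservative
  expect_lt(mean(p_agg < 0.05), 0.09)      # aggregation near nominal (MC error)
})

test_that("Bonferroni pairwise tables have the right combinatorics", {
  g <- list(a = c(1, 2), b = c(2, 3), c = c(3, 4), d = c(4, 5))
  tab <- bonferroni_pairwise(g)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$p_corrected >= tab$p_raw))
  expect_true(all(tab$p_corrected <= 1))
  raw <- bonferroni_pairwise(g, planned = TRUE)
  expect_equal(raw$p_raw, tab$p_raw)
  expect_equal(raw$p_corrected, raw$p_raw)
  # correction factor is the number of pairs wherever the cap is not hit
  free <- tab$p_corrected < 1
  expect_equal(tab$p_corrected[free], pmin(1, tab$p_raw[free] * 6))
})

test_that("significance stars follow the 0.05 / 0.01 thresholds", {
  expect_identical(cochleaq:::sig_stars(c(0.2, 0.04, 0.009)), c("", "*", "**"))
})
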