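test_that("identical groups give H = 0, p = 1", {
  g <- list(a = c(5, 5, 5), b = c(5, 5, 5), c = c(5, 5, 5))
  out <- kruskal_wallis(g)
  expect_equal(out$H, 0)
  expect_equal(out$p_chisq, 1)
  expect_equal(out$p_exact, 1)
})

test_that("H and the exact p match full enumeration on separated groups", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  out <- kruskal_wallis(g)
  # independent oracle: kruskal.test over every distinct assignment of the
  # pooled values to the three group sizes
  vals <- unlist(g)
  H_obs <- unname(stats::kruskal.test(vals, factor(rep(1:3, each = 3)))$statistic)
  expect_equal(out$H, H_obs)
  count <- 0L; total <- 0L
  for (a in utils::combn(9, 3, simplify = FALSE)) {
    rest <- setdiff(1:9, a)
    for (b in utils::combn(rest, 3, simplify = FALSE)) {
      grp <- integer(9); grp[a] <- 1L; grp[b] <- 2L; grp[grp == 0L] <- 3L
      H <- unname(stats::kruskal.test(vals, factor(grp))$statistic)
      total <- total + 1L
      if (H >= H_obs - 1e-9) count <- count + 1L
    }
  }
  expect_equal(total, 1680L)
  expect_equal(out$p_exact, count / total)
})

test_that("exact enumeration agrees with the chi-square engine on random fixtures", {
  set.seed(7)
  for (i in 1:3) {
    g <- list(a = rnorm(4), b = rnorm(4), c = rnorm(4))
    out <- kruskal_wallis(g)
    expect_equal(out$H,
                 unname(stats::kruskal.test(unlist(g),
                                            factor(rep(1:3, each = 4)))$statistic))
    expect_true(out$p_exact >= 0 && out$p_exact <= 1)
  }
})

test_that("omnibus type-I error is near nominal under the null", {
  set.seed(1)
  rejections <- vapply(seq_len(2000), function(i) {
    g <- list(a = rnorm(9), b = rnorm(9), c = rnorm(9))
    kruskal_wallis(g, exact_n_max = 0)$p_chisq < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("Bonferroni adjustment caps at 1 and scales by 3", {
  g <- list(lesion = c(10, 11, 12, 13), away_3mm = c(10.5, 11.5, 12.5, 13.5),
            contralateral = c(1, 2, 3, 4))
  pw <- pairwise_bonferroni(g)
  expect_equal(pw$p_adj, pmin(1, 3 * pw$p_raw))
  expect_equal(nrow(pw), 3L)
  same <- list(a = rep(1, 4), b = rep(1, 4), c = rep(1, 4))
  expect_true(all(pairwise_bonferroni(same)$p_adj == 1))
})

test_that("percentage-point differences match the reference contrasts", {
  expect_equal(diff_pp(c(60, 72), c(36, 48)), 24)   # blunt lesion vs contralateral
  expect_equal(diff_pp(c(50, 58), c(35, 43)), 15)   # sharp lesion vs contralateral
  expect_equal(diff_pp(1:5, 1:5), 0)
  expect_equal(diff_pp(c(0.79, 0.81), c(1.15, 1.17), digits = 2), -0.36)
  expect_error(diff_pp(numeric(0), 1:3), "empty")
})

test_that("a cohort at the reference moments separates the locations", {
  # combined-arm simulation at the reference group moments, n = 17 per
  # location: omnibus and lesion-vs-contralateral significance in >= 90 %
  set.seed(11)
  hits_omni <- 0L; hits_pair <- 0L
  reps <- 400
  for (i in seq_len(reps)) {
    g <- list(
      lesion = c(rnorm(9, 66, 18), rnorm(8, 54, 7)),
      away_3mm = c(rnorm(9, 45, 11), rnorm(8, 43, 5)),
      contralateral = c(rnorm(9, 42, 9), rnorm(8, 39, 12))
    )
    if (kruskal_wallis(g, exact_n_max = 0)$p_chisq < 0.05) hits_omni <- hits_omni + 1L
    pw <- pairwise_bonferroni(g)
    p_lc <- pw$p_adj[pw$group_a == "lesion" & pw$group_b == "contralateral"]
    if (p_lc < 0.01) hits_pair <- hits_pair + 1L
  }
  expect_gte(hits_omni / reps, 0.9)
  # the lesion-contralateral rejection rate at p < 0.01 is ~0.91; allow two
  # binomial standard errors of Monte-Carlo slack around the 0.9 claim
  expect_gte(hits_pair / reps, 0.9 - 2 * sqrt(0.9 * 0.1 / reps))
})

test_that("Monte-Carlo power behaves at the null and at saturation", {
  # unadjusted test at equal means: size ~ alpha
  p0 <- retrospective_power(50, 10, 9, 50, 10, 9, m = 1, reps = 2000, seed = 2)
  expect_within(p0, 0.05, 0.02)
  # effect of ten SDs: power ~ 1
  p1 <- retrospective_power(100, 5, 9, 50, 5, 9, reps = 1000, seed = 3)
  expect_gte(p1, 0.999)
  expect_error(retrospective_power(1, 0, 9, 2, 1, 9), "positive")

  # reference blunt lesion-vs-contralateral moments at n = 9: high power,
  # recorded without asserting an externally reported band
  p_blunt <- retrospective_power(66, 18, 9, 42, 9, 9, reps = 2000, seed = 4)
  expect_gte(p_blunt, 0.5)
  expect_lte(p_blunt, 1)
})

test_that("compare_locations wraps omnibus + pairwise with broom verbs", {
  df <- tibble::tibble(
    role = rep(c("lesion", "away_3mm", "contralateral"), each = 6),
    mean_partition_pct = c(rnorm(6, 66, 5), rnorm(6, 45, 5), rnorm(6, 42, 5))
  )
  cmp <- compare_locations(df, mean_partition_pct)
  gl <- glance(cmp)
  expect_named(gl, c("H", "df", "p_chisq", "p_exact", "n"))
  expect_equal(gl$n, 18L)
  td <- tidy(cmp)
  expect_equal(nrow(td), 3L)
  expect_true(all(td$p_adj >= td$p_raw - 1e-12))
})
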