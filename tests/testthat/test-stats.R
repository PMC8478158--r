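test_that("star coding uses inclusive thresholds", {
  expect_equal(star_code(c(0.03, 0.0005, 0.2)), c("*", "***", "ns"))
  expect_equal(star_code(c(0.05, 0.01, 0.001, 0.0001)),
               c("*", "**", "***", "****"))
  expect_equal(star_code(c(0.050001, 1, 0)), c("ns", "ns", "****"))
  expect_error(star_code(1.2), "validation")
})

test_that("Sidak adjustment matches its closed form and is monotone", {
  expect_equal(sidak_pairs(0.04), 0.04)
  expect_equal(sidak_pairs(c(0.05, 0.5))[1], 1 - 0.95^2)
  expect_equal(sidak_pairs(c(0, 1, 0.3))[1:2], c(0, 1))
  p <- 0.02
  adj_m <- vapply(1:10, function(m) sidak_pairs(p, m = m), numeric(1))
  expect_true(all(diff(adj_m) > 0))
  ps <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_pairs(ps, m = 4)) >= 0))
  expect_error(sidak_pairs(c(0.1, 1.4)), "validation")
})

test_that("Student's t matches the closed form and its conventions", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  res <- students_t(a, b)
  # closed form: pooled sd 1, se = sqrt(2/3), t = -1/se
  expect_equal(res$statistic, -1 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(res$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_equal(res$p_raw, 0.288, tolerance = 0.005)

  swapped <- students_t(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_raw, res$p_raw)

  same <- students_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)
})

test_that("Tukey on two groups reduces to the pooled t test", {
  set.seed(51)
  d <- data.frame(y = rnorm(24), A = rep(c("g1", "g2"), each = 12),
                  B = rep(c("b1", "b2"), 12))
  res <- two_way_anova_tukey(d, "y", "A", "B", within = NA)
  sub <- d
  tt <- stats::t.test(y ~ A, data = sub, var.equal = TRUE)
  # q = |t| * sqrt(2) on the pooled MSE; with 2 groups p_tukey = p_t when
  # the residual df agree, so compare against a t test using the ANOVA df
  q <- res$comparisons$statistic
  t_from_q <- q / sqrt(2)
  p_manual <- 2 * stats::pt(-t_from_q, df = res$df_residual)
  expect_equal(res$comparisons$p_adjusted, p_manual, tolerance = 1e-9)
})

test_that("Tukey comparisons agree with an independent implementation", {
  skip_if_not_installed("emmeans")
  set.seed(52)
  d <- expand.grid(donor = 1:6, A = c("P1", "P2", "P3"),
                   B = c("t1", "t4", "t8"))
  d$y <- rnorm(nrow(d)) + (d$A == "P3") * 1.5
  res <- two_way_anova_tukey(d, "y", "A", "B")
  fit <- stats::aov(y ~ A * B, data = d)
  em <- summary(emmeans::emmeans(fit, pairwise ~ A | B,
                                 adjust = "tukey")$contrasts)
  ours <- res$comparisons[!res$comparisons$skipped, ]
  key_ours <- paste(gsub(" ", "", ours$comparison))
  for (i in seq_len(nrow(em))) {
    lab <- paste0(gsub(" - ", "vs", em$contrast[i]), "@", em$B[i])
    j <- match(lab, key_ours)
    expect_false(is.na(j), info = lab)
    expect_equal(ours$p_adjusted[j], em$p.value[i], tolerance = 1e-6,
                 info = lab)
  }
})

test_that("three well-separated groups are detected, identical ones not", {
  set.seed(53)
  vals <- c(rnorm(4, 0, 1), rnorm(4, 0, 1), rnorm(4, 5, 1))
  d <- data.frame(y = rep(vals, 2),
                  A = rep(rep(c("g1", "g2", "g3"), each = 4), 2),
                  B = rep(c("b1", "b2"), each = 12))
  res <- two_way_anova_tukey(d, "y", "A", "B")
  cmp <- res$comparisons
  far <- grepl("g3", cmp$comparison)
  expect_true(all(cmp$p_adjusted[far] <= 0.001))
  expect_true(all(cmp$p_adjusted[!far & !cmp$skipped] > 0.05))
})

test_that("identical cells give zero statistics and p = 1", {
  d <- expand.grid(rep = 1:3, A = c("g1", "g2"), B = c("b1", "b2"))
  d$y <- 2
  # base R warns that F tests on a perfect fit are unreliable; the
  # zero-variance convention is exactly what is under test here
  res <- suppressWarnings(two_way_anova_tukey(d, "y", "A", "B"))
  cmp <- res$comparisons[!res$comparisons$skipped, ]
  expect_true(all(cmp$p_adjusted == 1))
})
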