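# Group-comparison statistics: hand-checkable cases, algebraic identities,
# cross-checks against reference implementations and null calibration.

test_that("ANOVA F matches hand computation and the classical identities", {
  # {1,2,3} vs {2,3,4}: SSB = 1.5, SSW = 4, F = 1.5 with df (1, 4)
  r <- anova_f(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(r$statistic, 1.5)
  expect_identical(r$df, c(1, 4))
  # identical groups: F = 0, p = 1
  r0 <- anova_f(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # two-group F equals the squared pooled-variance t statistic
  set.seed(2)
  x <- rnorm(8); y <- rnorm(9) + 0.4
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(anova_f(list(x, y))$statistic, unname(tt$statistic)^2)
  # k-group F agrees with the linear-model ANOVA
  g <- list(rnorm(5), rnorm(7) + 1, rnorm(6) - 0.5)
  v <- unlist(g); f <- factor(rep(seq_along(g), lengths(g)))
  expect_equal(anova_f(g)$statistic, anova(lm(v ~ f))$`F value`[1])
  # invariance under a constant shift and group relabelling
  base <- anova_f(g)
  expect_equal(anova_f(lapply(g, `+`, 100))$statistic, base$statistic)
  expect_equal(anova_f(rev(g))$statistic, base$statistic)
  # degenerate: zero within-group variance with distinct means
  expect_warning(rz <- anova_f(list(c(1, 1), c(2, 2))), "zero within-group")
  expect_equal(rz$p_value, 0)
  expect_error(anova_f(list(1:3)), "at least 2 groups")
  expect_error(anova_f(list(1, 2)), "at least 2 values")
})

test_that("the Lilliefors statistic matches hand evaluation and a
          reference implementation", {
  x4 <- c(-1.5, -0.5, 0.5, 1.5)
  z <- sort(x4) / sd(x4) # mean is 0
  p <- pnorm(z); i <- 1:4
  expect_equal(osteovasc:::.lilliefors_stat(x4),
               max(pmax(i / 4 - p, p - (i - 1) / 4)))
  skip_if_not_installed("nortest")
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(sample(10:60, 1))
    expect_equal(osteovasc:::.lilliefors_stat(x),
                 unname(nortest::lillie.test(x)$statistic))
  }
})

test_that("the Lilliefors Monte-Carlo test is deterministic, rejects
          uniform data, and validates its inputs", {
  x <- c(0.1, 0.2, 0.5, 0.9, 1.4, 2.2)
  a <- lilliefors_test(x, n_montecarlo = 1000, seed = 7)
  b <- lilliefors_test(x, n_montecarlo = 1000, seed = 7)
  expect_identical(a$p_value, b$p_value)
  expect_error(lilliefors_test(c(1, 2, 3)), "at least 4")
  expect_error(lilliefors_test(rep(1, 10)), "constant")
  expect_error(lilliefors_test(rnorm(10), n_montecarlo = 10), "1000")
  # power against a uniform alternative at n = 200
  set.seed(11)
  rej <- vapply(1:100, function(i) {
    lilliefors_test(runif(200), n_montecarlo = 1000, seed = i)$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.9)
})

test_that("Bartlett's test flags gross heterogeneity and is exact on
          identical groups", {
  r0 <- variance_homogeneity(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # cross-check against the base implementation on unequal variances
  set.seed(5)
  g <- list(rnorm(50, sd = 1), rnorm(50, sd = 10))
  ref <- bartlett.test(g)
  r <- variance_homogeneity(g)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_lt(r$p_value, 0.001)
  expect_error(variance_homogeneity(list(c(1, 1, 1), c(1, 2, 3))),
               "zero-variance")
})

test_that("significance tiers partition p-values monotonically", {
  ps <- c(1e-5, 0.0009, 0.001, 0.009, 0.01, 0.049, 0.05, 0.2, 1)
  tiers <- vapply(ps, significance_tier, "")
  expect_identical(tiers,
                   c("p<0.001", "p<0.001", "p<0.01", "p<0.01", "p<0.05",
                     "p<0.05", "ns", "ns", "ns"))
  # tier is monotone in p
  rank <- match(tiers, c("p<0.001", "p<0.01", "p<0.05", "ns"))
  expect_true(all(diff(rank) >= 0))
  expect_true(is.na(significance_tier(0.01, numeric(0))))
})

test_that("null ANOVA p-values are uniform and calibrated at the 5% level", {
  set.seed(40)
  ps <- vapply(1:2000, function(i) {
    anova_f(list(rnorm(10), rnorm(10)))$p_value
  }, 0)
  expect_lt(suppressWarnings(ks.test(ps, "punif")$statistic), 0.05)
  expect_gt(mean(ps < 0.05), 0.035)
  expect_lt(mean(ps < 0.05), 0.065)
})

test_that("the study comparison battery runs both families, records
          assumption checks and reports missing inputs", {
  set.seed(21)
  mk_rows <- function(id, tp, grp, metrics, values) {
    data.frame(sample_id = id, timepoint = tp, group = grp,
               metric = metrics, value = values, stringsAsFactors = FALSE)
  }
  metrics_g <- c("BV/TV", "VV/TV", "V.Th", "Me.V/TV")
  metrics_l <- c("local VV/TV", "local V.Th")
  tab <- do.call(rbind, c(
    lapply(1:8, function(i) mk_rows(paste0("T1_", i), "T1", "T1",
                                    c(metrics_g, metrics_l),
                                    rnorm(6, 10))),
    lapply(1:7, function(i) mk_rows(paste0("P", i), "T2", "P",
                                    c(metrics_g, metrics_l), rnorm(6, 10))),
    lapply(1:7, function(i) mk_rows(paste0("C", i), "T2", "C",
                                    c(metrics_g, metrics_l),
                                    rnorm(6, 10) - c(0, 0, 0, 0, 3, 3)))))
  res <- run_study_comparisons(tab)
  expect_identical(nrow(res), 6L)
  expect_setequal(res$family, c("timepoint", "treatment"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # the injected local deficit in group C is detected
  loc <- res[res$family == "treatment", ]
  expect_true(all(loc$p_value < 0.05))
  expect_true(all(c("normality_ok", "variance_ok") %in% names(res)))
  # empty tier list: p-values still reported, tiers absent
  res0 <- run_study_comparisons(tab, tiers = numeric(0))
  expect_true(all(is.na(res0$tier)))
  expect_false(any(is.na(res0$p_value)))
  expect_error(run_study_comparisons(tab[tab$metric != "V.Th", ]),
               "V.Th")
})

test_that("null cohort tables flag treatment differences at roughly the
          nominal rate", {
  flag <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    tab <- do.call(rbind, lapply(c("P", "B", "V", "C"), function(g) {
      do.call(rbind, lapply(1:7, function(i) {
        data.frame(sample_id = paste0(g, i), timepoint = "T2", group = g,
                   metric = "local V.Th", value = rnorm(1, 15, 2),
                   stringsAsFactors = FALSE)
      }))
    }))
    res <- run_study_comparisons(tab, timepoints = c("none", "T2"),
                                 global_metrics = character(0),
                                 local_metrics = "local V.Th",
                                 lilliefors_mc = 1000, seed = s)
    res$p_value[1] < 0.05
  }, TRUE)
  expect_lt(mean(flag), 0.11)
  expect_gte(mean(flag), 0)
})
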