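test_that("relative deviations follow the sign convention", {
  rd <- relative_deviation(c(10, 10), 10, "higher_better")
  expect_equal(rd$deviations, c(0, 0))
  rd2 <- relative_deviation(9, 10, "lower_better")
  expect_equal(rd2$deviations, -0.1)
  expect_equal(rd2$aligned, 0.1)
  expect_true(rd2$median_better)
  rd3 <- relative_deviation(11, 10, "lower_better")
  expect_false(rd3$median_better)
  expect_error(relative_deviation(1:3, 0), "non-zero")
})

test_that("signed-rank test matches the full enumeration oracle", {
  # n = 14, all positive: most extreme configuration, p = 2/2^14
  x <- seq(0.01, 0.14, by = 0.01)
  res <- wilcoxon_signed_rank(x)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 2 / 2^14)
  # antisymmetric vector sits at the null centre
  y <- c(-0.2, 0.2, -0.5, 0.5, -0.9, 0.9)
  expect_equal(wilcoxon_signed_rank(y)$p_value, 1)
  # random vectors, including ties, match 2^n enumeration exactly
  set.seed(14)
  for (i in 1:6) {
    z <- round(stats::rnorm(10), 1)
    z <- z[z != 0]
    if (length(z) < 3) next
    expect_equal(wilcoxon_signed_rank(z)$p_value, oracle_wilcoxon_p(z))
  }
  # agreement with the reference implementation on tie-free data
  set.seed(15)
  w <- stats::rnorm(12) + 0.4
  expect_equal(wilcoxon_signed_rank(w)$p_value,
               stats::wilcox.test(w)$p.value, tolerance = 1e-12)
})

test_that("signed-rank p is scale-invariant and sign-symmetric (property)", {
  set.seed(21)
  for (i in 1:5) {
    x <- stats::rnorm(9)
    p0 <- wilcoxon_signed_rank(x)$p_value
    expect_equal(wilcoxon_signed_rank(37.5 * x)$p_value, p0)
    expect_equal(wilcoxon_signed_rank(-x)$p_value, p0)
  }
})

test_that("exact and approximate signed-rank branches agree near the cutover", {
  set.seed(33)
  for (i in 1:10) {
    x <- stats::rnorm(20, mean = stats::runif(1, -0.5, 0.5))
    pe <- wilcoxon_signed_rank(x, exact_max = 20)$p_value
    pa <- wilcoxon_signed_rank(x, exact_max = 5)$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("degenerate signed-rank inputs error", {
  expect_error(wilcoxon_signed_rank(c(0, 0, 0, 0)), "non-zero")
  expect_error(wilcoxon_signed_rank(c(0.1, -0.2)), "at least 3")
})

test_that("Spearman matrix matches the average-rank formula oracle", {
  set.seed(8)
  n <- 8
  tab <- data.frame(
    a = round(stats::rnorm(n), 1),       # rounding forces ties
    b = round(stats::rnorm(n), 1),
    c = stats::rnorm(n)
  )
  res <- spearman_matrix(rbind(tab, tab[1:2, ]))  # 10 rows with duplicates
  tab10 <- rbind(tab, tab[1:2, ])
  for (k in seq_len(nrow(res))) {
    r_oracle <- oracle_spearman(tab10[[res$field_a[k]]], tab10[[res$field_b[k]]])
    expect_equal(res$rho[k], r_oracle, tolerance = 1e-12)
  }
  # perfect monotone pairs
  mono <- data.frame(x = 1:6, y = c(2, 4, 7, 8, 20, 21), z = -(1:6))
  rm <- spearman_matrix(mono)
  expect_equal(rm$rho[rm$field_a == "x" & rm$field_b == "y"], 1)
  expect_equal(rm$rho[rm$field_a == "x" & rm$field_b == "z"], -1)
})

test_that("Spearman rho is invariant under strictly monotone transforms (property)", {
  set.seed(9)
  x <- stats::rnorm(15); y <- stats::rnorm(15)
  base <- oracle_spearman(x, y)
  tab <- data.frame(x = exp(x), y = y^3 + 5 * y)
  res <- spearman_matrix(tab)
  expect_equal(res$rho[1], base, tolerance = 1e-12)
})

test_that("constant columns are reported as not computable, not as zero", {
  tab <- data.frame(a = 1:6, b = rep(3, 6), c = stats::rnorm(6))
  res <- spearman_matrix(tab)
  bad <- res[res$field_a == "b" | res$field_b == "b", ]
  expect_true(all(!bad$computable))
  expect_true(all(is.na(bad$rho)))
})

test_that("strength classification uses strict cutoffs at 0.5 and 0.7", {
  expect_equal(classify_strength(0.76), "strong")
  expect_equal(classify_strength(-0.55), "moderate")
  expect_equal(classify_strength(0.5), "weak")
  expect_equal(classify_strength(0.7), "moderate")
  expect_equal(classify_strength(c(-0.9, 0.2)), c("strong", "weak"))
  expect_error(classify_strength(1.2), "\\[-1, 1\\]")
})

test_that("trade-off fit recovers exact linear data and matches OLS closed form", {
  tab <- data.frame(oar_points = c(60, 65, 70, 71), y = 2 * c(60, 65, 70, 71) + 1)
  fit <- tradeoff_fit(tab, "oar_points", "y")
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  band <- fit$band(c(62, 68))
  expect_equal(band$fit, band$lwr, tolerance = 1e-7)  # zero-width band
  # random data vs normal equations
  set.seed(10)
  tab2 <- data.frame(oar_points = stats::rnorm(20, 70, 2),
                     y = stats::rnorm(20, 50, 3))
  f2 <- tradeoff_fit(tab2, "oar_points", "y")
  X <- cbind(1, tab2$oar_points)
  beta <- solve(t(X) %*% X, t(X) %*% tab2$y)
  expect_equal(f2$intercept, beta[1], tolerance = 1e-9)
  expect_equal(f2$slope, beta[2], tolerance = 1e-9)
  expect_error(tradeoff_fit(tab2[1:2, ], "oar_points", "y"), "at least 3")
  tab3 <- data.frame(oar_points = rep(70, 5), y = stats::rnorm(5))
  expect_error(tradeoff_fit(tab3, "oar_points", "y"), "constant")
})

test_that("deviation analysis covers every scheme metric with thresholds", {
  scheme <- load_scheme()
  co <- calibrated_cohort_500()$table
  dev <- deviation_analysis(co[1:50, ], scheme)
  expect_equal(nrow(dev), 16)
  expect_equal(dev$threshold, unname(ideal_thresholds(scheme)))
  expect_true(all(is.finite(dev$p_value)))
})
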