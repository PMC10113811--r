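test_that("independence GEE reproduces the pooled logistic MLE", {
  for (seed in c(51, 52)) {
    tab <- with_noise_col(make_presence_table(n_days = 60, seed = seed),
                          seed = seed)
    f <- fit_gee(tab, model_spec("independence"))
    g <- glm(presence ~ relevel(factor(regime), "dawn"), data = tab,
             family = binomial())
    expect_lt(max(abs(unname(f$beta) - unname(coef(g)))), 1e-6)

    fn <- fit_gee(tab, model_spec("independence", include_noise = TRUE))
    tab$noise_c <- tab$noise_p20_db - mean(tab$noise_p20_db)
    gn <- glm(presence ~ relevel(factor(regime), "dawn") +
                relevel(factor(regime), "dawn"):noise_c,
              data = tab, family = binomial())
    expect_lt(max(abs(sort(unname(fn$beta)) - sort(unname(coef(gn))))), 1e-6)
  }
})

test_that("degenerate responses fail with a separation error", {
  tab <- make_presence_table(n_days = 5, seed = 53)
  tab$presence <- 1L
  expect_error(fit_gee(tab), "separation")
})

test_that("the AR1 working correlation tracks the generator dependence", {
  alphas <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    tab <- make_presence_table(n_days = 150, rho = rho, seed = 55)
    fit_gee(tab, model_spec("ar1"))$ar1_alpha
  }, numeric(1))
  expect_true(all(diff(alphas) > 0))
  expect_true(all(abs(alphas) < 1))
})

test_that("Wald contrasts are antisymmetric and recover known differences", {
  tab <- make_presence_table(n_days = 200, seed = 56)
  f <- fit_gee(tab, model_spec("ar1"))

  self <- wald_contrast(f, c("day", "day"))
  expect_equal(self$estimate, 0)
  expect_equal(self$p.value, 1)

  ab <- wald_contrast(f, c("night", "day"))
  ba <- wald_contrast(f, c("day", "night"))
  expect_equal(ab$estimate, -ba$estimate)
  expect_equal(ab$p.value, ba$p.value)

  # true night - day logit difference is 1.0
  expect_lt(abs(ab$estimate - 1.0), 3 * ab$std.error)

  expect_error(wald_contrast(f, c("day", "twilight")), "absent")
})

test_that("tidy and glance expose robust inference and fit metadata", {
  tab <- make_presence_table(n_days = 60, seed = 57)
  f <- fit_gee(tab)
  td <- tidy(f, conf.int = TRUE)
  expect_identical(nrow(td), 4L)
  expect_true(all(c("estimate", "std.error", "p.value", "conf.low")
                  %in% names(td)))
  expect_equal(td$std.error, sqrt(diag(f$robust_cov)), ignore_attr = TRUE)
  gl <- glance(f)
  expect_identical(gl$n_clusters, 60L)
  expect_true(gl$converged)
  expect_lt(abs(gl$ar1_alpha), 1)
})

test_that("letter displays satisfy the share-iff-nonsignificant invariant on
           all 64 patterns", {
  pairs <- utils::combn(c("dawn", "day", "dusk", "night"), 2)
  for (bits in 0:63) {
    ct <- pattern_contrasts(bits)
    ld <- letter_display(ct, alpha_level = 0.05)
    lets <- setNames(strsplit(ld$letters, ""), ld$regime)
    for (k in seq_len(ncol(pairs))) {
      share <- length(intersect(lets[[pairs[1, k]]], lets[[pairs[2, k]]])) > 0
      nonsig <- ct$p.value[k] >= 0.05
      expect_identical(share, nonsig)
    }
    expect_true(all(nchar(ld$letters) > 0))
  }
  # the two canonical extremes
  all_same <- letter_display(pattern_contrasts(0))
  expect_identical(unique(all_same$letters), "a")
  all_diff <- letter_display(pattern_contrasts(63))
  expect_identical(sort(all_diff$letters), c("a", "b", "c", "d"))
})

test_that("Durbin-Watson matches closed forms and its asymptotic centre", {
  expect_equal(durbin_watson(rep(2, 50)), 0)
  n <- 101
  alt <- rep(c(1, -1), length.out = n)
  expect_equal(durbin_watson(alt), 4 * (n - 1) / n)
  set.seed(58)
  expect_lt(abs(durbin_watson(rnorm(10000)) - 2), 0.1)
  expect_error(durbin_watson(numeric(10)), "all-zero")
  # cluster boundaries break the differencing
  e <- c(1, -1, 1, -1)
  expect_equal(durbin_watson(e, cluster = c(1, 1, 2, 2)), 2 * 4 / 4)
})

test_that("the sample ACF is exact at lag 0 and consistent for AR1 noise", {
  set.seed(59)
  x <- rnorm(10000)
  a_white <- acf_values(x, max_lag = 5)
  expect_identical(a_white$acf[1], 1)
  expect_lt(abs(a_white$acf[2]), 0.05)

  z <- numeric(10000)
  e <- rnorm(10000)
  for (t in 2:10000) z[t] <- 0.6 * z[t - 1] + e[t]
  a_ar <- acf_values(z, max_lag = 3)
  expect_lt(abs(a_ar$acf[2] - 0.6), 0.05)
  expect_error(acf_values(rep(1, 100), 5), "zero-variance")
})

test_that("robust contrasts hold their nominal size under the null", {
  # sandwich standard errors are asymptotic in the number of clusters;
  # 200 detection-day clusters puts the test in their working regime.
  # Each of the six unadjusted pairwise tests should reject ~5% of the
  # time; across six correlated tests the familywise rate then sits
  # around 0.2 (bounded above by the Bonferroni sum 0.30).
  n_rep <- 200L
  per <- matrix(FALSE, n_rep, 6)
  for (i in seq_len(n_rep)) {
    tab <- make_presence_table(
      n_days = 200, effects = c(dawn = 0, day = 0, dusk = 0, night = 0),
      intercept = 0, rho = 0.6, seed = 1000 + i)
    f <- fit_gee(tab, model_spec("ar1"))
    ct <- regime_contrasts(f)
    per[i, ] <- ct$p.value < 0.05
  }
  # per-test size near nominal: binomial 3-sigma band around 0.05
  expect_true(all(colMeans(per) <= 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep)))
  expect_gt(mean(per), 0.01)                  # not vacuously conservative
  expect_lte(mean(apply(per, 1, any)), 6 * 0.05)
})

test_that("GEE diagnostics expose residual serial structure", {
  strong <- make_presence_table(n_days = 100, rho = 0.85, seed = 60)
  weak <- make_presence_table(n_days = 100, rho = 0, seed = 60)
  f_s <- fit_gee(strong, model_spec("independence"))
  f_w <- fit_gee(weak, model_spec("independence"))
  d_s <- gee_diagnostics(f_s)
  d_w <- gee_diagnostics(f_w)
  expect_lt(d_s$dw, d_w$dw)         # positive serial correlation lowers DW
  expect_gt(d_s$acf$acf[2], d_w$acf$acf[2])
  expect_identical(d_s$acf$acf[1], 1)
})
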