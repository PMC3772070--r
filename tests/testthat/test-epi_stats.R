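test_that("crosstab recovers per-category smoking prevalence", {
  set.seed(31)
  n <- c(a = 700, b = 500)
  p <- c(a = 0.65, b = 0.45)
  df <- data.frame(
    grp = rep(names(n), n),
    status = unlist(lapply(names(n), function(g) {
      ifelse(stats::runif(n[[g]]) < p[[g]], "current", "never")
    })))
  ct <- crosstab(df, "grp")
  expect_identical(ct$n, as.integer(unname(n)))
  for (g in names(n)) {
    se <- sqrt(p[[g]] * (1 - p[[g]]) / n[[g]])
    expect_lt(abs(ct$n_current[ct$category == g] / n[[g]] - p[[g]]), 2 * se)
  }

  # single-category factor: one row, nothing to test against
  one <- crosstab(data.frame(grp = "a", status = c("current", "never")),
                  "grp")
  expect_identical(nrow(one), 1L)

  # unknowns dropped (complete-case)
  df$grp[1:10] <- "unknown"
  expect_identical(sum(crosstab(df, "grp")$n), as.integer(sum(n) - 10L))
})

test_that("Pearson heterogeneity test matches hand computation", {
  flat <- rbind(c(30, 60), c(10, 20))  # identical row proportions
  r0 <- pearson_chi2(flat)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  # hand-computed expected counts: X2 = 25/15+25/5+25/15+25/5 = 13.333, df 1
  r1 <- pearson_chi2(rbind(c(10, 10), c(20, 0)))
  expect_equal(r1$statistic, 40 / 3, tolerance = 1e-12)
  expect_identical(r1$df, 1L)

  expect_error(pearson_chi2(rbind(c(0, 0), c(5, 5))), "marginal")
  expect_error(pearson_chi2(matrix(1:2)), "2 rows")
})

test_that("Cochran-Armitage trend test: oracle equality, affine invariance,
           and the heterogeneity/trend decomposition", {
  flat <- rbind(c(10, 20, 30), c(10, 20, 30))
  r0 <- cochran_armitage(flat)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  expect_error(cochran_armitage(rbind(c(1, 2), c(3, 4))), "3 ordered")

  set.seed(7)
  for (i in 1:250) {
    k <- sample(3:5, 1)
    tab <- random_2xk(k)
    ca <- cochran_armitage(tab)
    oracle <- stats::prop.trend.test(tab[1, ], colSums(tab), 0:(k - 1))
    expect_equal(ca$statistic, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(ca$p.value, oracle$p.value, tolerance = 1e-10)
    # affine score invariance
    ca2 <- cochran_armitage(tab, scores = 3 + 7 * (0:(k - 1)))
    expect_equal(ca2$statistic, ca$statistic, tolerance = 1e-9)
    # X2(heterogeneity) >= X2(trend) for the standard decomposition
    expect_gte(pearson_chi2(tab)$statistic + 1e-9, ca$statistic)
  }
})

test_that("odds ratios use the cross-product with Woolf intervals", {
  r <- odds_ratio(c(1, 1, 1, 1))
  expect_equal(r$estimate, 1)
  expect_equal(r$ci_low * r$ci_high, 1, tolerance = 1e-12)  # symmetric CI

  expect_error(odds_ratio(c(3, 0, 2, 5)), "continuity")
  rc <- odds_ratio(c(3, 0, 2, 5), continuity = TRUE)
  expect_equal(rc$estimate, (3.5 * 5.5) / (0.5 * 2.5))

  # OR equals the exponentiated logistic coefficient to >= 6 significant
  # figures, and the Woolf CI equals the Wald CI
  set.seed(11)
  for (i in 1:40) {
    tab <- random_2xk(2)[, 1:2]        # 2x2 with positive cells
    tab <- t(tab)
    or <- odds_ratio(tab)
    df <- data.frame(succ = tab[, 1], fail = tab[, 2], x = c(1, 0))
    fit <- fit_logistic(cbind(succ, fail) ~ x, df)
    expect_equal(or$estimate, unname(exp(coef(fit)["x"])),
                 tolerance = 1e-7)
    # CI bounds agree to IRLS convergence precision (coefficients are only
    # solved to ~1e-6 relative accuracy)
    expect_equal(c(or$ci_low, or$ci_high),
                 unname(unlist(fit$or_table[2, c("ci_low", "ci_high")])),
                 tolerance = 1e-4)
  }
})

test_that("logistic fits agree between grouped and expanded data and flag
           separation", {
  set.seed(13)
  for (i in 1:10) {
    g <- data.frame(succ = sample(3:20, 3), fail = sample(3:20, 3),
                    x = c(0, 1, 2))
    fit_g <- fit_logistic(cbind(succ, fail) ~ x, g)
    ind <- do.call(rbind, lapply(1:3, function(j) {
      data.frame(y = rep(c(1, 0), c(g$succ[j], g$fail[j])), x = g$x[j])
    }))
    fit_i <- fit_logistic(y ~ x, ind)
    expect_equal(coef(fit_g), coef(fit_i), tolerance = 1e-8)
    expect_identical(fit_g$n, fit_i$n)
  }

  # complete separation: no estimates reported
  sep <- data.frame(y = rep(c(0, 1), each = 10), x = rep(c(0, 1), each = 10))
  fit_s <- fit_logistic(y ~ x, sep)
  expect_false(fit_s$converged)
  expect_null(fit_s$or_table)
  expect_null(coef(fit_s))
})

test_that("heterogeneity and trend tests hold their type-I error under the
           null", {
  set.seed(17)
  n_tab <- 600  # scaled-down null simulation; acceptance runs 2000
  rej <- matrix(FALSE, n_tab, 2)
  for (i in seq_len(n_tab)) {
    tab <- rbind(stats::rbinom(4, 60, 0.35))
    tab <- rbind(tab, 60 - tab)
    rej[i, 1] <- pearson_chi2(tab)$p.value < 0.05
    rej[i, 2] <- cochran_armitage(tab)$p.value < 0.05
  }
  rates <- colMeans(rej)
  # 3.5 binomial s.e. around 0.05 at n = 600 ~ +/- 0.031
  expect_true(all(rates > 0.019 & rates < 0.081))
})

test_that("missingness tables mirror the cohort's ascertainment patterns", {
  # constructed cohort: females missing more often
  set.seed(19)
  n <- 800
  coh <- data.frame(patient_id = sprintf("m%04d", 1:n),
                    sex = rep(c("male", "female"), each = n / 2))
  p_miss <- ifelse(coh$sex == "female", 0.42, 0.30)
  miss <- stats::runif(n) < p_miss
  resolved <- data.frame(patient_id = coh$patient_id[!miss],
                         status = "current")
  mt <- missingness_table(coh, resolved, "sex")
  tab <- mt$sex$table
  expect_identical(tab$n_missing[tab$category == "female"],
                   as.integer(sum(miss[coh$sex == "female"])))
  expect_lt(mt$sex$p_heterogeneity, 0.05)

  # no missingness anywhere: 0% everywhere, degenerate test -> p = 1
  mt0 <- missingness_table(coh, data.frame(patient_id = coh$patient_id,
                                           status = "never"), "sex")
  expect_equal(mt0$sex$table$pct_missing, c(0, 0))
  expect_equal(mt0$sex$p_heterogeneity, 1)

  # generator realism: stratum-specific missingness produces a detectable
  # female and bipolar excess at moderate n (patient layer only)
  set.seed(23)
  pats <- simulate_patients(simulation_config(n_patients = 3000))
  resolved2 <- data.frame(patient_id = pats$patient_id[pats$ascertainable],
                          status = "current")
  mt2 <- missingness_table(pats, resolved2, c("sex", "diagnosis"))
  expect_lt(mt2$sex$p_heterogeneity, 0.01)
  expect_lt(mt2$diagnosis$p_heterogeneity, 0.01)
  f <- mt2$sex$table
  expect_gt(f$pct_missing[f$category == "female"],
            f$pct_missing[f$category == "male"])
})
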