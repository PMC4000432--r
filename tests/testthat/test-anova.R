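test_that("ANOVA decomposition matches the brute-force oracle exactly", {
  toy <- toy_dataset()
  vc <- fit_oneway_anova(toy)
  expect_equal(vc$SSB, 54)
  expect_equal(vc$MSB, 27)
  expect_equal(vc$SSW, 6)
  expect_equal(vc$MSW, 1)
  expect_equal(vc$F, 27)
  expect_equal(vc$n0, 3)
  set.seed(101)
  for (i in 1:25) {
    d <- random_unbalanced_dataset(a = sample(2:6, 1), m_range = c(1, 6))
    if (d$N <= d$a) next
    vc <- fit_oneway_anova(d)
    o <- oracle_anova(d$value, d$cluster)
    expect_equal(vc$MSB, o$MSB, tolerance = 1e-12)
    expect_equal(vc$MSW, o$MSW, tolerance = 1e-12)
    expect_equal(vc$F, o$F, tolerance = 1e-12)
    expect_equal(vc$n0, o$n0, tolerance = 1e-12)
    expect_true(vc$n0 >= 1 && vc$n0 <= max(d$n_i))
  }
})

test_that("Kish, F-formula and textbook moment forms agree", {
  set.seed(202)
  for (i in 1:60) {
    d <- if (i %% 2) random_balanced_dataset(sample(3:8, 1), sample(2:10, 1))
         else random_unbalanced_dataset(sample(3:8, 1))
    vc <- fit_oneway_anova(d)
    k <- icc_kish(vc)$rho_raw
    f <- icc_from_F(vc)$rho_raw
    expect_equal(k, f, tolerance = 1e-12)
    expect_equal(k, oracle_icc(vc$MSB, vc$MSW, vc$n0), tolerance = 1e-12)
  }
  expect_equal(icc_kish(toy_dataset())$rho, 26 / 29, tolerance = 1e-14)
  expect_equal(icc_from_F(toy_dataset())$rho, 26 / 29, tolerance = 1e-14)
})

test_that("degenerate data raise classed errors", {
  expect_error(fit_oneway_anova(cluster_dataset(rep(3, 6), rep(1:2, each = 3))),
               class = "clustericc_degenerate_error")
  expect_error(fit_oneway_anova(cluster_dataset(1:4, 1:4)),  # all singletons
               class = "clustericc_degenerate_error")
  expect_error(fit_oneway_anova(1:3), class = "clustericc_input_error")
})

test_that("zero within-cluster variance gives ICC 1; equal cluster means truncate to 0", {
  d <- cluster_dataset(c(0, 0, 1, 1), c("A", "A", "B", "B"))
  vc <- fit_oneway_anova(d)
  expect_identical(vc$F, Inf)
  expect_equal(icc_kish(vc)$rho, 1)
  expect_equal(icc_from_F(vc)$rho, 1)
  ci <- icc_confidence_interval(vc)
  expect_equal(ci$ci_high, 1)
  # identical cluster means but within-cluster spread: raw estimate <= 0
  d2 <- cluster_dataset(c(1, 3, 1, 3, 1, 3), rep(1:3, each = 2))
  est <- icc_kish(d2)
  expect_true(est$rho_raw < 0)
  expect_equal(est$rho, 0)
  est <- icc_confidence_interval(d2, est)
  expect_equal(est$ci_low, 0)
})

test_that("raw ICC is monotone in the between-cluster variance component", {
  set.seed(303)
  a <- 10; m <- 8
  u <- rnorm(a)
  g <- rep(seq_len(a), each = m)
  e <- rnorm(a * m)
  e <- e - ave(e, g)  # center within clusters: MSW fixed as k varies
  prev <- -Inf
  for (k in c(0, 0.2, 0.5, 1, 2, 5)) {
    d <- cluster_dataset(k * u[g] + e, g)
    cur <- icc_kish(d)$rho_raw
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("confidence intervals bracket the estimate and respect alpha limits", {
  set.seed(404)
  for (i in 1:20) {
    d <- random_unbalanced_dataset(sample(4:10, 1))
    for (meth in c("fpivot", "wald")) {
      est <- icc_confidence_interval(d, alpha = 0.05, ci_method = meth)
      expect_true(est$ci_low <= est$rho && est$rho <= est$ci_high)
      expect_true(est$ci_low >= 0 && est$ci_high <= 1)
      expect_gte(est$se, 0)
    }
  }
  # alpha -> 1 collapses the Wald interval onto the point estimate
  d <- toy_dataset()
  est <- icc_confidence_interval(d, alpha = 1, ci_method = "wald")
  expect_equal(est$ci_low, est$rho)
  expect_equal(est$ci_high, est$rho)
  expect_error(icc_confidence_interval(d, alpha = 0),
               class = "clustericc_input_error")
  # narrower alpha gives wider interval
  wide <- icc_confidence_interval(d, alpha = 0.01)
  narrow <- icc_confidence_interval(d, alpha = 0.2)
  expect_lte(wide$ci_low, narrow$ci_low)
  expect_gte(wide$ci_high, narrow$ci_high)
})

test_that("icc_anova wraps fit + estimate + interval consistently", {
  d <- toy_dataset()
  est <- icc_anova(d, alpha = 0.05)
  manual <- icc_confidence_interval(fit_oneway_anova(d), icc_kish(d), alpha = 0.05)
  expect_equal(est$rho, manual$rho)
  expect_equal(est$ci_low, manual$ci_low)
  expect_equal(est$ci_high, manual$ci_high)
  expect_equal(icc_anova(d, method = "f_formula")$rho, est$rho, tolerance = 1e-12)
})

test_that("ANOVA ICC matches the REML random-intercept ICC on balanced data", {
  set.seed(505)
  for (i in 1:3) {
    a <- 12; m <- 25
    g <- rep(seq_len(a), each = m)
    y <- rnorm(a)[g] * 0.6 + rnorm(a * m)
    d <- cluster_dataset(y, g)
    fit <- lme4::lmer(y ~ 1 + (1 | g), data = data.frame(y = y, g = factor(g)),
                      REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))$vcov
    icc_reml <- vc[1] / sum(vc)
    expect_equal(icc_kish(d)$rho, icc_reml, tolerance = 1e-6)
  }
})
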