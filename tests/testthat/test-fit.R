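test_that("Egger regression interpolates an exact line with zero residuals", {
  s <- c(0.2, 0.5, 0.9, 1.3)
  y <- 0.3 + 1.7 * s
  f <- fit_egger(y, s)
  expect_equal(unname(coef(f)), c(0.3, 1.7), tolerance = 1e-12)
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-12)
})

test_that("two studies give a saturated Egger fit with finite covariance", {
  f <- fit_egger(c(0.1, 0.8), c(0.3, 0.7))
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-12)
  expect_true(all(is.finite(f$cov_theta)))
  expect_true(all(diag(f$cov_theta) > 0))
})

test_that("Egger fit matches a brute-force weighted normal-equations oracle", {
  set.seed(21)
  d <- random_ys(10)
  f <- fit_egger(d$y, d$s)
  # independent solve of (X' W X) theta = X' W y on the raw scale
  X <- cbind(1, d$s); W <- diag(1 / d$s^2)
  theta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% d$y)
  expect_equal(unname(coef(f)), drop(theta), tolerance = 1e-10)
  expect_equal(unname(f$cov_theta), solve(t(X) %*% W %*% X),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(f$chi2, drop(theta)[2]^2 / solve(t(X) %*% W %*% X)[2, 2],
               tolerance = 1e-10)
})

test_that("transformed OLS equals direct GLS with covariance sigma^2 diag(tau2 + s^2)", {
  set.seed(31)
  for (rep in 1:20) {
    d <- random_ys(sample(5:50, 1))
    f <- fit_flexible_hybrid(d$y, d$s)
    X <- cbind(1, d$s)
    Vinv <- diag(1 / (f$tau2 + d$s^2))
    theta_gls <- solve(t(X) %*% Vinv %*% X, t(X) %*% Vinv %*% d$y)
    expect_equal(unname(coef(f)), drop(theta_gls), tolerance = 1e-8)
    expect_equal(unname(f$cov_theta),
                 f$sigma^2 * solve(t(X) %*% Vinv %*% X),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("point estimates do not depend on sigma; Wald chi^2 is scale invariant", {
  set.seed(41)
  d <- random_ys(25)
  f1 <- fit_flexible_hybrid(d$y, d$s)
  # rescale all effects: estimates scale linearly, chi^2 unchanged
  c0 <- 3.7
  f2 <- fit_flexible_hybrid(c0 * d$y, d$s, tau2 = c0^2 * f1$tau2)
  expect_equal(f2$alpha, c0 * f1$alpha, tolerance = 1e-10)
  expect_equal(f2$beta, c0 * f1$beta, tolerance = 1e-10)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-10)
  # and fixing sigma leaves the point estimates untouched
  f3 <- fit_flexible_hybrid(d$y, d$s, tau2 = f1$tau2, fix_sigma = TRUE)
  expect_equal(coef(f3), coef(f1), tolerance = 1e-12)
})

test_that("flexible hybrid with tau2 = 0 and sigma fixed at 1 is exactly Egger", {
  set.seed(51)
  for (rep in 1:10) {
    d <- random_ys(sample(4:30, 1))
    fh <- fit_flexible_hybrid(d$y, d$s, tau2 = 0, fix_sigma = TRUE)
    fe <- fit_egger(d$y, d$s)
    expect_identical(coef(fh), coef(fe))
    expect_identical(fh$cov_theta, fe$cov_theta)
    expect_identical(fh$chi2, fe$chi2)
    expect_identical(fh$p, fe$p)
  }
})

test_that("a zero-residual hybrid fit is flagged degenerate, not an error", {
  s <- c(0.2, 0.5, 0.9, 1.3)
  y <- 0.3 + 1.7 * s    # exactly linear in s, so zero residuals at any tau2
  f <- fit_flexible_hybrid(y, s)
  expect_true(f$degenerate)
  expect_equal(f$sigma, 0)
  expect_true(is.na(f$p))
  expect_true(f$p_star >= 0 && f$p_star <= 1)
})

test_that("identical standard errors raise a collinearity error naming the cause", {
  expect_error(fit_flexible_hybrid(c(1, 2, 3), rep(0.5, 3)),
               "standard errors are identical")
  expect_error(fit_egger(c(1, 2, 3), rep(0.5, 3)),
               "standard errors are identical")
})

test_that("the hybrid slope is unbiased under the null (simulation oracle)", {
  set.seed(61)
  cfg <- sim_config(J = 1, n = 500, tau2 = 0.2, beta_true = 0, seed = 61)
  betas <- vapply(1:60, function(r) {
    cfg$seed <- 61 + r
    d <- simulate_dataset(cfg)
    fit_small_study(d, model = "hybrid")$beta
  }, numeric(1))
  mc_se <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas)), 3 * mc_se)
})

test_that("fit accessors and dataset interface are coherent", {
  set.seed(71)
  d <- two_outcome_dataset(n1 = 10, n2 = 8, n_overlap = 6)
  f <- fit_small_study(d, outcome = 2)
  expect_equal(f$n, 8)
  expect_equal(length(f$study_ids), 8)
  expect_equal(f$outcome, "Y2")
  expect_equal(f$chi2, (f$beta / sqrt(vcov(f)[2, 2]))^2, tolerance = 1e-12)
  expect_equal(unname(vcov(f, fix_sigma = TRUE) * f$sigma^2),
               unname(vcov(f)), tolerance = 1e-12)
  expect_equal(predict(f, newdata = c(0.5)), f$alpha + 0.5 * f$beta)
  expect_output(print(f), "flexible hybrid")
  expect_error(fit_small_study(c(1, 2), c(0.1, 0.4), model = "hybrid"),
               "at least 3")
})
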