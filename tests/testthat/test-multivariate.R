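test_that("empty overlap yields the zero cross-covariance", {
  set.seed(201)
  d <- two_outcome_dataset(n1 = 8, n2 = 7, n_overlap = 0)
  f1 <- fit_small_study(d, outcome = 1)
  f2 <- fit_small_study(d, outcome = 2)
  cc <- cross_covariance(f1, f2, d)
  expect_equal(cc$overlap_n, 0)
  expect_equal(unname(cc$matrix), matrix(0, 2, 2))
})

test_that("cross-covariance matches a brute-force term-by-term sum over A", {
  set.seed(203)
  d <- two_outcome_dataset(n1 = 5, n2 = 4, n_overlap = 3)
  f1 <- fit_small_study(d, outcome = 1)
  f2 <- fit_small_study(d, outcome = 2)
  cc <- suppressWarnings(cross_covariance(f1, f2, d))
  expect_equal(cc$overlap_n, 3)

  # brute force: explicit bread and a term-by-term meat over i in A
  X1 <- cbind(f1$design$x0, f1$design$x1)
  X2 <- cbind(f2$design$x0, f2$design$x1)
  A <- intersect(f1$study_ids, f2$study_ids)
  meat <- matrix(0, 2, 2)
  for (id in A) {
    i1 <- match(id, f1$study_ids); i2 <- match(id, f2$study_ids)
    meat <- meat + (X1[i1, ] %o% X2[i2, ]) * f1$residuals[i1] * f2$residuals[i2]
  }
  expected <- solve(t(X1) %*% X1) %*% meat %*% solve(t(X2) %*% X2)
  expect_equal(unname(cc$matrix), expected, tolerance = 1e-10)
  # transpose symmetry of the pair
  cc_t <- suppressWarnings(cross_covariance(f2, f1, d))
  expect_equal(unname(cc_t$matrix), t(unname(cc$matrix)), tolerance = 1e-12)
})

test_that("a duplicated outcome reproduces its own sandwich covariance", {
  set.seed(205)
  d1 <- random_ys(12)
  d <- meta_dataset(cbind(d1$y, d1$y), cbind(d1$s, d1$s))
  f1 <- fit_small_study(d, outcome = 1)
  f2 <- fit_small_study(d, outcome = 2)
  cc <- cross_covariance(f1, f2, d)
  X <- cbind(f1$design$x0, f1$design$x1)
  bread <- solve(t(X) %*% X)
  sandwich <- bread %*% (t(X * f1$residuals) %*% (X * f1$residuals)) %*% bread
  expect_equal(unname(cc$matrix), sandwich, tolerance = 1e-8)
})

test_that("tiny overlap triggers the instability warning", {
  set.seed(207)
  d <- two_outcome_dataset(n1 = 8, n2 = 5, n_overlap = 2)
  f1 <- fit_small_study(d, outcome = 1)
  f2 <- fit_small_study(d, outcome = 2)
  expect_warning(cross_covariance(f1, f2, d), "overlapping studies")
})

test_that("slope covariance extraction matches brute-force index selection", {
  # J = 2, zero cross blocks: Cbeta is the diagonal of slope variances
  f1 <- fake_fit(0.5, matrix(c(0.04, 0.01, 0.01, 0.09), 2), "a")
  f2 <- fake_fit(-0.2, matrix(c(0.16, -0.02, -0.02, 0.25), 2), "b")
  asm <- assemble_beta_covariance(list(f1, f2), list(fake_cross(matrix(0, 2, 2))))
  expect_equal(unname(asm$cov_beta), diag(c(0.09, 0.25)))
  expect_equal(unname(asm$beta), c(0.5, -0.2))

  # J = 3, random PSD Ctheta: extraction equals direct index selection
  set.seed(211)
  M <- matrix(rnorm(36), 6); Ctheta <- crossprod(M)
  fits <- lapply(1:3, function(j)
    fake_fit(rnorm(1), Ctheta[(2 * j - 1):(2 * j), (2 * j - 1):(2 * j)],
             paste0("o", j)))
  crosses <- list(fake_cross(Ctheta[1:2, 3:4]), fake_cross(Ctheta[1:2, 5:6]),
                  fake_cross(Ctheta[3:4, 5:6]))
  asm <- assemble_beta_covariance(fits, crosses)
  bidx <- c(2, 4, 6)
  expect_equal(unname(asm$cov_beta), Ctheta[bidx, bidx], tolerance = 1e-12)
  expect_equal(unname(asm$cov_theta), Ctheta, tolerance = 1e-12)
  expect_error(assemble_beta_covariance(fits, crosses[1:2]), "expected 3")
})

test_that("global test matches closed forms and a brute-force inverse", {
  g <- global_beta_test(c(1, 1), diag(2))
  expect_equal(g$chi2, 2)
  expect_equal(g$p, exp(-1))
  expect_equal(g$df, 2)

  g0 <- global_beta_test(c(0, 0, 0), diag(3))
  expect_equal(g0$chi2, 0)
  expect_equal(g0$p, 1)

  set.seed(213)
  for (rep in 1:10) {
    J <- sample(2:4, 1)
    M <- matrix(rnorm(J * J), J); C <- crossprod(M) + diag(J) * 0.1
    b <- rnorm(J)
    g <- global_beta_test(b, C)
    expect_equal(g$chi2, drop(t(b) %*% solve(C) %*% b), tolerance = 1e-8)
    expect_true(g$psd_ok)
    expect_false(g$repaired)
  }

  expect_error(global_beta_test(c(1, 0), matrix(0, 2, 2)), "degenerate")
  expect_error(global_beta_test(c(1, 0), matrix(c(1, .5, .4, 1), 2)),
               "symmetric")
})

test_that("an indefinite slope covariance is repaired with reduced df", {
  C <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3 and -1
  g <- global_beta_test(c(1, 1), C)
  expect_false(g$psd_ok)
  expect_true(g$repaired)
  expect_equal(g$df, 1)
  expect_gte(g$chi2, 0)
  # pseudo-inverse keeps the eigenvector (1,1)/sqrt(2) with eigenvalue 3:
  # chi2 = (b'v)^2 / lambda = (2/sqrt(2))^2 / 3 = 2/3
  expect_equal(g$chi2, 2 / 3, tolerance = 1e-10)
})

test_that("no overlap makes the global chi^2 exactly additive", {
  set.seed(215)
  for (rep in 1:10) {
    d <- two_outcome_dataset(n1 = sample(6:20, 1), n2 = sample(6:20, 1),
                             n_overlap = 0)
    mv <- mv_small_study(d, mtp = FALSE)
    expect_equal(mv$global$chi2, mv$fits[[1]]$chi2 + mv$fits[[2]]$chi2,
                 tolerance = 1e-10)
  }
})

test_that("the analysis is invariant under permutation of outcome order", {
  set.seed(217)
  cfg <- sim_config(J = 3, n = 40, overlap = 40,
                    tau2 = c(0.1, 0.2, 0.3), seed = 217)
  d <- simulate_dataset(cfg)
  mv <- mv_small_study(d, mtp = FALSE)
  perm <- c(3, 1, 2)
  d2 <- meta_dataset(d$effects[, perm], d$std_errors[, perm],
                     study_ids = d$study_ids,
                     outcome_names = d$outcome_names[perm])
  mv2 <- mv_small_study(d2, mtp = FALSE)
  expect_equal(mv2$global$chi2, mv$global$chi2, tolerance = 1e-10)
  expect_equal(mv2$global$p, mv$global$p, tolerance = 1e-10)
  expect_equal(unname(mv2$beta), unname(mv$beta[perm]), tolerance = 1e-12)
})

test_that("reconstructing the published heart-failure global test from its inputs", {
  # printed inputs: slope estimates, their SEs, and the slope covariance
  Cb <- matrix(c(0.30^2, -0.0017, -0.0017, 0.91^2), 2)
  g <- global_beta_test(c(-0.62, 1.51), Cb)
  expect_lt(abs(g$chi2 - 7.04), 0.1)
  expect_lt(abs(g$p - 0.030), 0.002)
})

test_that("reconstructing the published neuroblastoma global test from its inputs", {
  Cb <- matrix(c(0.51^2, 0.051, 0.051, 1.43^2), 2)
  g <- global_beta_test(c(1.34, 0.87), Cb)
  expect_lt(abs(g$chi2 - 7.07), 0.1)
  expect_lt(abs(g$p - 0.029), 0.002)
})
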