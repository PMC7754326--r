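# shared fixture builders: everything is generated in code at test time

# one outcome's worth of (y, s) with mild heterogeneity and a known slope
random_ys <- function(n, alpha = 0.1, beta = 0.5, tau = 0.3,
                      s_range = c(0.1, 1)) {
  s <- runif(n, s_range[1], s_range[2])
  y <- alpha + beta * s + rnorm(n, sd = tau) + rnorm(n, sd = s)
  list(y = y, s = s)
}

# two-outcome dataset with a configurable overlap pattern:
# studies 1..n1 report outcome 1, studies (n1 - n_overlap + 1)..n report
# outcome 2, so the presence sets overlap in exactly n_overlap studies
two_outcome_dataset <- function(n1 = 12, n2 = 10, n_overlap = 5) {
  n <- n1 + n2 - n_overlap
  eff <- matrix(NA_real_, n, 2)
  se <- matrix(NA_real_, n, 2)
  d1 <- random_ys(n1); d2 <- random_ys(n2)
  idx1 <- seq_len(n1)
  idx2 <- (n1 - n_overlap + 1L):n
  eff[idx1, 1] <- d1$y; se[idx1, 1] <- d1$s
  eff[idx2, 2] <- d2$y; se[idx2, 2] <- d2$s
  meta_dataset(eff, se)
}

# minimal stand-ins for assembled objects, used by index-selection oracles
fake_fit <- function(beta, cov_theta, outcome) {
  structure(list(beta = beta, cov_theta = cov_theta, outcome = outcome),
            class = "ssfit")
}
fake_cross <- function(m) structure(list(matrix = m), class = "cross_covariance")
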