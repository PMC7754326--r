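#' Lin–Chu maximum-likelihood model
#'
#' Joint maximum likelihood of the model
#' \deqn{Y_i \sim N\big(\alpha + \beta\sqrt{\tau^2 + s_i^2},\;
#'       \tau^2 + s_i^2\big)}
#' over \eqn{(\alpha, \beta, \tau^2)} with \eqn{\tau^2 \ge 0}. The mean is
#' taken as \eqn{\alpha + \beta\sqrt{\tau^2 + s_i^2}} — the slope multiplies
#' the total standard deviation rather than the reported standard error, so
#' here \eqn{\tau^2} enters both the mean and the variance and the two are
#' not disconnected. Optimisation is bounded (L-BFGS-B, iteration cap 200)
#' and started from the flexible hybrid fit; the covariance of the parameter
#' estimates is the inverse observed information (numerical Hessian) at the
#' optimum and may be unreliable when \eqn{\hat\tau^2} sits on the boundary.
#'
#' @inheritParams estimate_tau2
#' @return an object of classes \code{linchu_fit} and \code{ssfit}: the usual
#'   \code{ssfit} components plus \code{loglik}, \code{cov_params} (3x3, order
#'   \eqn{\alpha, \beta, \tau^2}) and \code{converged}. The slope Wald test
#'   uses the observed-information standard error.
#' @export
fit_lin_chu <- function(effects, std_errors) {
  y <- as.numeric(effects); s <- as.numeric(std_errors)
  if (length(y) != length(s)) stop("'effects' and 'std_errors' lengths differ")
  if (length(y) < 3L)
    stop("Lin-Chu fit requires at least 3 studies, got ", length(y))
  if (any(s <= 0)) stop("all standard errors must be > 0")
  n <- length(y)

  nll <- function(par) {
    tau2 <- par[3L]
    v <- tau2 + s^2
    mu <- par[1L] + par[2L] * sqrt(v)
    0.5 * sum(log(2 * pi * v) + (y - mu)^2 / v)
  }

  start_fit <- fit_flexible_hybrid(y, s)
  start <- c(start_fit$alpha, start_fit$beta, max(start_fit$tau2, 1e-8))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(-Inf, -Inf, 0),
                      control = list(maxit = 200))
  converged <- opt$convergence == 0L

  # observed information; evaluate slightly inside the boundary so the
  # central differences stay in the feasible region
  hpar <- opt$par
  if (hpar[3L] < 1e-6) hpar[3L] <- 1e-6
  H <- stats::optimHess(hpar, nll)
  cov_params <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 3, 3))
  dimnames(cov_params) <- list(c("alpha", "beta", "tau2"),
                               c("alpha", "beta", "tau2"))

  alpha <- opt$par[1L]; beta <- opt$par[2L]; tau2 <- max(0, opt$par[3L])
  v <- tau2 + s^2
  cov_theta <- cov_params[1:2, 1:2]
  se_beta2 <- cov_params[2L, 2L]
  chi2 <- if (is.finite(se_beta2) && se_beta2 > 0) beta^2 / se_beta2 else NA_real_
  p <- if (is.na(chi2)) NA_real_ else chisq_upper_tail(chi2, 1L)

  # transformed-scale design and residuals, comparable with the other fits
  tr <- build_transform(y, s, tau2)
  fitted_star <- (alpha + beta * sqrt(v)) / sqrt(v)

  structure(list(
    outcome = "Y1", model_tag = "lin_chu", n = n,
    effects = y, std_errors = s,
    tau2 = tau2, tau2_estimate = NULL,
    alpha = alpha, beta = beta, sigma = 1,
    cov_theta = cov_theta, cov_theta_unit = cov_theta,
    chi2 = chi2, df = 1L, p = p, chi2_star = chi2, p_star = p,
    design = list(ystar = tr$ystar, x0 = tr$x0, x1 = tr$x1),
    fitted_star = fitted_star, residuals = tr$ystar - fitted_star,
    degenerate = FALSE,
    loglik = -opt$value, cov_params = cov_params, converged = converged,
    study_ids = paste0("S", seq_len(n))
  ), class = c("linchu_fit", "ssfit"))
}

#' @export
logLik.linchu_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}
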