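#' Fit a small-study-effect regression to one outcome
#'
#' The central model of the package regresses a study's effect estimate
#' \eqn{Y_i} on its standard error \eqn{s_i}; a nonzero slope \eqn{\beta} is
#' the regression signature of funnel-plot asymmetry. Three mean/variance
#' structures are available:
#'
#' \describe{
#'   \item{\code{"hybrid"} (flexible hybrid, the default)}{
#'     \eqn{Y_i \sim N(\alpha + \beta s_i,\; \sigma^2(\hat\tau^2 + s_i^2))},
#'     fitted in two steps: (1) \eqn{\hat\tau^2} from the marginal
#'     intercept-only random-effects model (see [estimate_tau2()]);
#'     (2) ordinary least squares of the transformed response \eqn{Y^*} on
#'     the two transformed columns \eqn{(x_0, x_1)} of [build_transform()],
#'     with no additional intercept. \eqn{\hat\sigma^2 = RSS/(n-2)} and
#'     \eqn{\mathrm{cov}(\hat\theta) = \hat\sigma^2 (X^\top X)^{-1}}. The
#'     point estimates do not depend on \eqn{\sigma}.}
#'   \item{\code{"egger"}}{the classical Egger regression
#'     \eqn{Y_i \sim N(\alpha + \beta s_i, s_i^2)}: weighted least squares
#'     with known variances \eqn{s_i^2}, i.e. the flexible hybrid with
#'     \eqn{\tau^2 = 0} and \eqn{\sigma} fixed at 1.}
#'   \item{\code{"linchu"}}{the Lin–Chu model, joint maximum likelihood of
#'     \eqn{Y_i \sim N(\alpha + \beta\sqrt{\tau^2+s_i^2},\; \tau^2+s_i^2)}
#'     over \eqn{(\alpha, \beta, \tau^2)}; see [fit_lin_chu()].}
#' }
#'
#' The Wald statistic \eqn{\chi^2 = (\hat\beta / se(\hat\beta))^2} is referred
#' to the \eqn{\chi^2_1} distribution. \code{p_star} is the same test with
#' \eqn{\sigma} fixed at 1, i.e. using \eqn{(X^\top X)^{-1}} as the
#' covariance (for \code{"egger"} the two coincide).
#'
#' @param effects numeric vector of effect estimates, or a [meta_dataset()]
#'   (then \code{outcome} selects the column and \code{std_errors} is ignored).
#' @param std_errors numeric vector of positive standard errors.
#' @param model \code{"hybrid"}, \code{"egger"} or \code{"linchu"}.
#' @param tau2_method passed to [estimate_tau2()] for the hybrid model.
#' @param tau2 optional fixed heterogeneity variance for the hybrid model,
#'   bypassing estimation (e.g. \code{tau2 = 0}).
#' @param fix_sigma if \code{TRUE} the hybrid residual scale is fixed at
#'   \eqn{\sigma = 1} instead of estimated; with \code{tau2 = 0} this is
#'   exactly the Egger regression.
#' @param outcome outcome name or index when \code{effects} is a dataset.
#' @return An object of class \code{ssfit} (for \code{"linchu"} additionally
#'   of class \code{linchu_fit}); see Details for the components. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{vcov},
#'   \code{residuals}, \code{fitted}, \code{predict}, \code{plot}.
#' @examples
#' set.seed(1)
#' s <- runif(20, 0.1, 1); y <- 0.2 + 1.5 * s + rnorm(20, sd = s)
#' f <- fit_small_study(y, s)
#' summary(f)
#' coef(f)
#' @seealso [mv_small_study()] for the multivariate global test,
#'   [fit_egger()], [fit_flexible_hybrid()], [fit_lin_chu()].
#' @export
fit_small_study <- function(effects, std_errors = NULL,
                            model = c("hybrid", "egger", "linchu"),
                            tau2_method = c("DL", "REML"),
                            tau2 = NULL, fix_sigma = FALSE,
                            outcome = 1L) {
  model <- match.arg(model)
  tau2_method <- match.arg(tau2_method)
  name <- NULL; ids <- NULL
  if (inherits(effects, "meta_dataset")) {
    v <- outcome_vectors(effects, outcome,
                         min_n = if (model == "egger") 2L else 3L)
    y <- v$y; s <- v$s; ids <- v$ids; name <- v$name
  } else {
    y <- as.numeric(effects); s <- as.numeric(std_errors)
    if (length(y) != length(s))
      stop("'effects' and 'std_errors' lengths differ")
    ids <- paste0("S", seq_along(y))
  }
  if (any(!is.finite(y)) || any(!is.finite(s))) stop("non-finite input")
  if (any(s <= 0)) stop("all standard errors must be > 0")

  fit <- switch(model,
    hybrid = fit_flexible_hybrid(y, s, tau2_method = tau2_method,
                                 tau2 = tau2, fix_sigma = fix_sigma),
    egger  = fit_egger(y, s),
    linchu = fit_lin_chu(y, s))
  fit$outcome <- if (is.null(name)) fit$outcome else name
  fit$study_ids <- ids
  fit
}

# Shared WLS core on the transformed scale. sigma_known = TRUE means variances
# are taken as exact (Egger): covariance is (X'X)^-1 with no sigma estimate.
wls_transformed <- function(y, s, tau2, sigma_known, model_tag, tau2_est = NULL) {
  n <- length(y)
  if (diff(range(s)) == 0)
    stop("collinear design: all standard errors are identical, so the slope ",
         "column is proportional to the intercept column and the model is ",
         "not identifiable")
  tr <- build_transform(y, s, tau2)
  X <- cbind(x0 = tr$x0, x1 = tr$x1)
  qx <- qr(X)
  if (qx$rank < 2L)
    stop("collinear design: transformed columns (x0, x1) are linearly dependent")
  theta <- qr.coef(qx, tr$ystar)
  fitted_star <- drop(X %*% theta)
  res <- tr$ystar - fitted_star
  rss <- sum(res^2)
  xtx_inv <- solve(crossprod(X))
  dimnames(xtx_inv) <- list(c("alpha", "beta"), c("alpha", "beta"))

  degenerate <- FALSE
  if (sigma_known) {
    sigma <- 1
    cov_theta <- xtx_inv
  } else {
    scale2 <- mean(tr$ystar^2)
    degenerate <- rss <= 1e-12 * max(scale2 * n, .Machine$double.xmin)
    sigma <- sqrt(rss / (n - 2))
    if (degenerate) sigma <- 0
    cov_theta <- sigma^2 * xtx_inv
  }

  beta <- theta[2L]; alpha <- theta[1L]
  chi2_star <- beta^2 / xtx_inv[2L, 2L]
  p_star <- chisq_upper_tail(chi2_star, 1L)
  if (sigma_known) {
    chi2 <- chi2_star; p <- p_star
  } else if (degenerate) {
    # zero residual variance: sigma-scaled Wald statistic is undefined, only
    # the sigma = 1 test is reported
    chi2 <- NA_real_; p <- NA_real_
  } else {
    chi2 <- beta^2 / cov_theta[2L, 2L]
    p <- chisq_upper_tail(chi2, 1L)
  }

  structure(list(
    outcome = "Y1",
    model_tag = model_tag,
    n = n,
    effects = y, std_errors = s,
    tau2 = tau2, tau2_estimate = tau2_est,
    alpha = unname(alpha), beta = unname(beta), sigma = sigma,
    cov_theta = cov_theta, cov_theta_unit = xtx_inv,
    chi2 = unname(chi2), df = 1L, p = unname(p),
    chi2_star = unname(chi2_star), p_star = unname(p_star),
    design = list(ystar = tr$ystar, x0 = tr$x0, x1 = tr$x1),
    fitted_star = fitted_star, residuals = res,
    degenerate = degenerate,
    study_ids = paste0("S", seq_len(n))
  ), class = "ssfit")
}

#' Flexible hybrid meta-regression (two-step fit)
#'
#' Vector interface to the default model of [fit_small_study()]; see there
#' for the model. Requires at least 3 studies (two mean parameters plus a
#' residual variance) with non-identical standard errors.
#'
#' @inheritParams estimate_tau2
#' @param tau2_method \code{"DL"} or \code{"REML"}.
#' @param tau2 optional fixed \eqn{\tau^2} (bypasses estimation).
#' @param fix_sigma fix the residual scale at \eqn{\sigma = 1} instead of
#'   estimating it; with \code{tau2 = 0} the fit is then exactly
#'   [fit_egger()].
#' @return an \code{ssfit} object with \code{model_tag = "flexible_hybrid"}.
#' @export
fit_flexible_hybrid <- function(effects, std_errors,
                                tau2_method = c("DL", "REML"),
                                tau2 = NULL, fix_sigma = FALSE) {
  y <- as.numeric(effects); s <- as.numeric(std_errors)
  if (length(y) < 3L)
    stop("flexible hybrid fit requires at least 3 studies, got ", length(y))
  if (is.null(tau2)) {
    t2 <- estimate_tau2(y, s, method = tau2_method)
    tau2 <- t2$value
  } else {
    if (tau2 < 0) stop("'tau2' must be >= 0")
    t2 <- NULL
  }
  wls_transformed(y, s, tau2 = tau2, sigma_known = fix_sigma,
                  model_tag = "flexible_hybrid", tau2_est = t2)
}

#' Egger regression with known variances
#'
#' Weighted least squares of \eqn{Y} on \eqn{(1, s)} with weights
#' \eqn{1/s_i^2} and covariance from the known-variance formula
#' \eqn{(X^\top W X)^{-1}} (no residual scale). Equivalent to the flexible
#' hybrid fit with \eqn{\tau^2 = 0} and \eqn{\sigma} fixed at 1.
#'
#' @inheritParams estimate_tau2
#' @return an \code{ssfit} object with \code{model_tag = "egger"} and
#'   \code{sigma = 1}.
#' @export
fit_egger <- function(effects, std_errors) {
  y <- as.numeric(effects); s <- as.numeric(std_errors)
  if (length(y) < 2L)
    stop("Egger regression requires at least 2 studies, got ", length(y))
  wls_transformed(y, s, tau2 = 0, sigma_known = TRUE, model_tag = "egger")
}

#' @export
coef.ssfit <- function(object, ...) c(alpha = object$alpha, beta = object$beta)

#' @export
vcov.ssfit <- function(object, fix_sigma = FALSE, ...) {
  if (fix_sigma) object$cov_theta_unit else object$cov_theta
}

#' @export
residuals.ssfit <- function(object, ...) object$residuals

#' @export
fitted.ssfit <- function(object, ...) object$fitted_star

#' @export
print.ssfit <- function(x, digits = 4, ...) {
  lab <- switch(x$model_tag, flexible_hybrid = "flexible hybrid",
                egger = "Egger (known variances)",
                lin_chu = "Lin-Chu (ML)", x$model_tag)
  cat(sprintf("Small-study effect regression [%s], outcome %s, n = %d\n",
              lab, x$outcome, x$n))
  cat(sprintf("  tau^2 = %s   sigma = %s\n",
              format(x$tau2, digits = digits), format(x$sigma, digits = digits)))
  cat(sprintf("  alpha = %s (se %s)\n", format(x$alpha, digits = digits),
              format(sqrt(x$cov_theta[1, 1]), digits = digits)))
  cat(sprintf("  beta  = %s (se %s)\n", format(x$beta, digits = digits),
              format(sqrt(x$cov_theta[2, 2]), digits = digits)))
  if (is.na(x$chi2))
    cat(sprintf("  degenerate fit (zero residuals); sigma = 1 test: chi^2 = %s, p* = %s\n",
                format(x$chi2_star, digits = digits),
                format(x$p_star, digits = digits)))
  else
    cat(sprintf("  Wald chi^2(beta = 0) = %s, df = 1, p = %s (p* = %s)\n",
                format(x$chi2, digits = digits), format(x$p, digits = digits),
                format(x$p_star, digits = digits)))
  invisible(x)
}

#' @export
summary.ssfit <- function(object, ...) {
  se <- sqrt(diag(object$cov_theta))
  tab <- data.frame(
    outcome = object$outcome, model = object$model_tag, n = object$n,
    tau2 = object$tau2, alpha = object$alpha, se_alpha = se[1L],
    beta = object$beta, se_beta = se[2L], sigma = object$sigma,
    chi2 = object$chi2, df = object$df, p = object$p,
    p_star = object$p_star, row.names = NULL)
  structure(list(fit = object, table = tab), class = "summary.ssfit")
}

#' @export
print.summary.ssfit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @export
predict.ssfit <- function(object, newdata = NULL, ...) {
  # predictions on the original Y scale at given standard errors
  s <- if (is.null(newdata)) object$std_errors else {
    if (is.list(newdata)) as.numeric(newdata$s) else as.numeric(newdata)
  }
  object$alpha + object$beta * s
}

#' @export
plot.ssfit <- function(x, ...) {
  plot(x$std_errors, x$effects, xlab = "standard error s",
       ylab = "effect estimate Y",
       main = sprintf("Small-study regression (%s): %s", x$model_tag, x$outcome),
       ...)
  ss <- seq(min(x$std_errors), max(x$std_errors), length.out = 50)
  graphics::lines(ss, x$alpha + x$beta * ss, lty = 2)
  invisible(x)
}
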