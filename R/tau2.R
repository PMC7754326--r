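#' Between-study heterogeneity variance from the marginal model
#'
#' Estimates \eqn{\tau^2} from the intercept-only random-effects model
#' \eqn{Y_i \sim N(\alpha, \tau^2 + s_i^2)} — the first step of the two-step
#' flexible hybrid fit. \code{"DL"} is the closed-form DerSimonian–Laird
#' moment estimator, truncated at zero; \code{"REML"} maximises the
#' restricted likelihood of the same model over \eqn{\tau^2 \in [0, \infty)}
#' by bounded quasi-Newton iteration started at the DL value.
#'
#' @param effects numeric vector of effect estimates \eqn{Y_i}.
#' @param std_errors numeric vector of positive standard errors \eqn{s_i}.
#' @param method \code{"DL"} (default) or \code{"REML"}.
#' @return An object of class \code{tau2_estimate}: list with \code{value}
#'   (\eqn{\hat\tau^2 \ge 0}), \code{method}, \code{converged} (always
#'   \code{TRUE} for DL), and \code{truncated} (\code{TRUE} when the
#'   pre-truncation estimate was negative).
#' @examples
#' estimate_tau2(c(0, 1, 2, 3), rep(1, 4))           # DL: 2/3
#' estimate_tau2(c(0, 1, 2, 3), rep(1, 4), "REML")
#' @export
estimate_tau2 <- function(effects, std_errors, method = c("DL", "REML")) {
  method <- match.arg(method)
  y <- as.numeric(effects); s <- as.numeric(std_errors)
  if (length(y) != length(s)) stop("'effects' and 'std_errors' lengths differ")
  if (length(y) < 2L) stop("at least 2 studies are required to estimate tau^2")
  if (any(!is.finite(y)) || any(!is.finite(s))) stop("non-finite input")
  if (any(s <= 0)) stop("all standard errors must be > 0")
  n <- length(y)

  # DL moment estimator: Q-statistic of the fixed-effect fit
  w <- 1 / s^2
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  raw <- if (denom > 0) (Q - (n - 1)) / denom else 0
  dl <- max(0, raw)

  if (method == "DL") {
    return(structure(list(value = dl, method = "DL", converged = TRUE,
                          truncated = raw < 0), class = "tau2_estimate"))
  }

  # REML: restricted log-likelihood of Y ~ N(alpha, tau2 + s^2)
  nll <- function(tau2) {
    v <- tau2 + s^2
    wv <- 1 / v
    mu <- sum(wv * y) / sum(wv)
    0.5 * (sum(log(v)) + log(sum(wv)) + sum((y - mu)^2 * wv))
  }
  upper <- max(10 * stats::var(y), 10 * dl, 1)
  opt <- stats::optim(par = min(dl, upper), fn = nll, method = "L-BFGS-B",
                      lower = 0, upper = upper,
                      control = list(maxit = 200, factr = 1e-10 / .Machine$double.eps))
  structure(list(value = max(0, opt$par), method = "REML",
                 converged = opt$convergence == 0L,
                 truncated = opt$par <= .Machine$double.eps^0.5),
            class = "tau2_estimate")
}

#' @export
print.tau2_estimate <- function(x, ...) {
  cat(sprintf("tau^2 = %.6g (%s%s%s)\n", x$value, x$method,
              if (isTRUE(x$truncated)) ", truncated at 0" else "",
              if (!isTRUE(x$converged)) ", NOT converged" else ""))
  invisible(x)
}

#' Variance-stabilising transformation of the flexible hybrid model
#'
#' Given \eqn{\hat\tau^2}, divides each study by
#' \eqn{\sqrt{\hat\tau^2 + s_i^2}} so that the flexible hybrid model
#' \eqn{Y_i \sim N(\alpha + \beta s_i,\; \sigma^2(\hat\tau^2 + s_i^2))}
#' becomes homoscedastic:
#' \deqn{Y_i^* = Y_i / \sqrt{\hat\tau^2 + s_i^2},\quad
#'       x_{0i} = 1 / \sqrt{\hat\tau^2 + s_i^2},\quad
#'       x_{1i} = s_i / \sqrt{\hat\tau^2 + s_i^2},}
#' after which \eqn{Y_i^* \sim N(x_{0i}\alpha + x_{1i}\beta, \sigma^2)} is an
#' ordinary least-squares problem with no further intercept (the intercept is
#' carried by \eqn{x_0}). Always \eqn{x_{1i}/x_{0i} = s_i}.
#'
#' @param effects,std_errors numeric vectors \eqn{Y_i}, \eqn{s_i > 0}.
#' @param tau2 heterogeneity variance estimate, \eqn{\ge 0}.
#' @return list with numeric vectors \code{ystar}, \code{x0}, \code{x1}.
#' @examples
#' build_transform(1, 1, 3)   # all three equal 0.5
#' @export
build_transform <- function(effects, std_errors, tau2) {
  y <- as.numeric(effects); s <- as.numeric(std_errors)
  if (length(y) != length(s)) stop("'effects' and 'std_errors' lengths differ")
  if (!is.numeric(tau2) || length(tau2) != 1L || is.na(tau2))
    stop("'tau2' must be a single number")
  if (tau2 < 0) stop("'tau2' must be >= 0")
  v <- tau2 + s^2
  if (any(v <= 0)) stop("tau2 + s_i^2 must be > 0 for every study")
  r <- 1 / sqrt(v)
  list(ystar = y * r, x0 = r, x1 = s * r)
}

#' Upper-tail chi-squared probability
#'
#' Reference distribution for every Wald test in the package: the upper tail
#' of the \eqn{\chi^2} distribution.
#'
#' @param x nonnegative statistic value.
#' @param df positive integer degrees of freedom.
#' @return \eqn{P(\chi^2_{df} > x)} in \eqn{[0, 1]}.
#' @examples
#' chisq_upper_tail(7.04, 2)  # 0.030 at 3 decimals
#' @export
chisq_upper_tail <- function(x, df) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stop("'x' must be nonnegative")
  if (any(df < 1) || any(df != as.integer(df)))
    stop("'df' must be a positive integer")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}
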