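#' Threshold divisors of the Shaffer-type sequential procedure
#'
#' For \eqn{J} hypotheses tested after a significant global test, the ordered
#' p-values are compared against \eqn{\alpha / t_j} with
#' \eqn{t = (J-1, J-1, J-2, \dots, 1)}. Once the global null is rejected at
#' most \eqn{J - 1} of the individual nulls can be true, which is what allows
#' the first divisor to drop from Holm's \eqn{J} to \eqn{J - 1}. For
#' \eqn{J = 1} the divisor is \eqn{t = (1)} (a plain level-\eqn{\alpha}
#' test).
#'
#' @param J positive integer number of hypotheses.
#' @return integer vector of length \eqn{J}.
#' @examples
#' shaffer_t_vector(2)  # c(1, 1)
#' shaffer_t_vector(3)  # c(2, 2, 1)
#' @export
shaffer_t_vector <- function(J) {
  if (!is.numeric(J) || length(J) != 1L || is.na(J) || J < 1 || J != as.integer(J))
    stop("'J' must be a positive integer")
  J <- as.integer(J)
  if (J == 1L) return(1L)
  c(J - 1L, (J - 1L):1L)
}

#' Sequentially rejective multiple testing
#'
#' Sorts the p-values ascending (stable: ties keep input order), rejects
#' \eqn{p_{(j)}} as long as \eqn{p_{(j)} \le \alpha / t_j} with the divisors
#' of [shaffer_t_vector()], and stops at the first failure, so the rejection
#' set is always a prefix of the sorted order. Never rejects fewer hypotheses
#' than Holm's procedure at the same level.
#'
#' @param p_values numeric vector of p-values in \eqn{[0, 1]}.
#' @param alpha significance level in \eqn{(0, 1)}.
#' @return An object of class \code{sequential_test}: list with
#'   \code{ordered_p}, \code{order} (permutation into sorted order),
#'   \code{t_vector}, \code{thresholds} (\eqn{\alpha/t_j}, weakly
#'   nondecreasing), \code{rejected} (logical, in input order),
#'   \code{alpha}.
#' @examples
#' sequential_reject(c(0.06, 0.09), alpha = 0.10)  # both rejected
#' @export
sequential_reject <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("all p-values must lie in [0, 1]")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  J <- length(p)
  ord <- order(p)                       # stable: ties keep input order
  t_vec <- shaffer_t_vector(J)
  thr <- alpha / t_vec
  ps <- p[ord]
  ok <- ps <= thr
  n_rej <- if (all(ok)) J else which(!ok)[1L] - 1L
  rejected <- logical(J)
  if (n_rej > 0L) rejected[ord[seq_len(n_rej)]] <- TRUE
  structure(list(ordered_p = ps, order = ord, t_vector = t_vec,
                 thresholds = thr, rejected = rejected, alpha = alpha),
            class = "sequential_test")
}

#' @export
print.sequential_test <- function(x, digits = 4, ...) {
  J <- length(x$ordered_p)
  cat(sprintf("Sequentially rejective test at alpha = %g (J = %d)\n",
              x$alpha, J))
  dec <- x$rejected[x$order]
  for (j in seq_len(J))
    cat(sprintf("  p(%d) = %s  vs  alpha/%d = %s  -> %s\n", j,
                format(x$ordered_p[j], digits = digits), x$t_vector[j],
                format(x$thresholds[j], digits = digits),
                if (dec[j]) "reject" else "retain"))
  invisible(x)
}
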