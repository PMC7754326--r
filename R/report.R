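#' Render the standard analysis report
#'
#' Produces the plain-text table of a multivariate small-study analysis: one
#' row per outcome with \eqn{\hat\tau^2}, \eqn{\hat\alpha} (se),
#' \eqn{\hat\beta} (se), \eqn{\hat\sigma}, the Wald \eqn{\chi^2}, df, P and
#' the \eqn{\sigma = 1} p-value \eqn{p^*}; for two or more outcomes a final
#' "both"/"global" row with the covariance of the slope estimates, the global
#' \eqn{\chi^2}, df and P; and, when present, a multiple-testing block with
#' thresholds and decisions. Estimates are printed at 2 decimals, p-values at
#' 3, per the conventional table layout.
#'
#' @param x an \code{ssmv} object from [mv_small_study()], or a list of
#'   \code{ssfit} objects.
#' @param digits_est,digits_p decimals for estimates and p-values.
#' @return character vector of report lines (also usable via
#'   \code{print.ssmv}).
#' @export
render_report <- function(x, digits_est = 2, digits_p = 3) {
  if (inherits(x, "ssmv")) {
    fits <- x$fits; global <- x$global; mtp <- x$mtp; cov_beta <- x$cov_beta
  } else {
    fits <- x; global <- NULL; mtp <- NULL; cov_beta <- NULL
  }
  fe <- function(v) formatC(v, format = "f", digits = digits_est)
  fp <- function(v) ifelse(is.na(v), "   NA",
                           formatC(v, format = "f", digits = digits_p))

  rows <- lapply(fits, function(f) {
    se <- sqrt(diag(f$cov_theta))
    c(outcome = f$outcome,
      tau2 = fe(f$tau2),
      alpha = sprintf("%s (%s)", fe(f$alpha), fe(se[1L])),
      beta = sprintf("%s (%s)", fe(f$beta), fe(se[2L])),
      sigma = fe(f$sigma),
      chi2 = fe(f$chi2), df = as.character(f$df), P = fp(f$p),
      pstar = fp(f$p_star))
  })
  hdr <- c("outcome", "tau2", "alpha (se)", "beta (se)", "sigma",
           "chi2", "df", "P", "p*")
  m <- rbind(hdr, do.call(rbind, rows))
  if (!is.null(global)) {
    covb <- cov_beta[lower.tri(cov_beta)]
    grow <- c("both",
              sprintf("(covariance of the slopes: %s)",
                      paste(formatC(covb, format = "g", digits = 4),
                            collapse = ", ")),
              "", "", "",
              fe(global$chi2), as.character(global$df), fp(global$p), "")
    m <- rbind(m, grow)
  }
  w <- apply(nchar(m), 2L, max)
  lines <- apply(m, 1L, function(r)
    paste(mapply(formatC, r, width = w, MoreArgs = list(flag = "-")),
          collapse = "  "))
  lines <- trimws(lines, which = "right")
  if (!is.null(global) && !global$psd_ok)
    lines <- c(lines,
               "note: slope covariance was not nonnegative definite; repaired by eigenvalue clipping (df = rank)")
  if (!is.null(mtp)) {
    lines <- c(lines, "",
               sprintf("Sequential multiple testing at alpha = %g:", mtp$alpha))
    dec <- mtp$rejected[mtp$order]
    onames <- vapply(fits, function(f) f$outcome, character(1))
    for (j in seq_along(mtp$ordered_p))
      lines <- c(lines, sprintf("  %s: p = %s <= %s ? %s",
                                onames[mtp$order[j]], fp(mtp$ordered_p[j]),
                                fp(mtp$thresholds[j]),
                                if (dec[j]) "reject" else "retain"))
  }
  unname(lines)
}
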