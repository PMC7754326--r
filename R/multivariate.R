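#' Cross-covariance of two outcomes' regression estimates
#'
#' Working-independence (GEE-type) sandwich estimator of
#' \eqn{C_{12} = \mathrm{cov}(\hat\theta_1, \hat\theta_2)} for two per-outcome
#' fits on the same dataset:
#' \deqn{C_{12} = (x_1^\top x_1)^{-1}
#'   \Big[\sum_{i \in A} x_{1i}^\top
#'   (Y^*_{1i} - \hat Y^*_{1i})(Y^*_{2i} - \hat Y^*_{2i}) x_{2i}\Big]
#'   (x_2^\top x_2)^{-1},}
#' where the bread matrices run over all studies reporting the respective
#' outcome, while the meat sum is restricted to the overlap set \eqn{A} of
#' studies reporting both. Residuals are those of the full per-outcome fits,
#' not refits on \eqn{A}. An empty overlap returns the zero matrix, so the
#' global test then reduces to adding the univariate statistics. An overlap
#' below 3 studies triggers a warning (the estimate is then very unstable)
#' but the computation proceeds.
#'
#' @param fit_j,fit_k \code{ssfit} objects fitted to two outcomes of
#'   \code{dataset} (study ids must identify the rows).
#' @param dataset the common [meta_dataset()].
#' @return An object of class \code{cross_covariance}: list with
#'   \code{outcome_pair}, \code{matrix} (2x2, rows indexing
#'   \eqn{\hat\theta_j}, columns \eqn{\hat\theta_k}), \code{overlap_ids},
#'   \code{overlap_n}.
#' @export
cross_covariance <- function(fit_j, fit_k, dataset) {
  stopifnot(inherits(fit_j, "ssfit"), inherits(fit_k, "ssfit"),
            inherits(dataset, "meta_dataset"))
  if (!all(fit_j$study_ids %in% dataset$study_ids) ||
      !all(fit_k$study_ids %in% dataset$study_ids))
    stop("fit study ids are not all present in the dataset")

  A <- intersect(fit_j$study_ids, fit_k$study_ids)
  X1 <- cbind(fit_j$design$x0, fit_j$design$x1)
  X2 <- cbind(fit_k$design$x0, fit_k$design$x1)

  if (length(A) == 0L) {
    C12 <- matrix(0, 2, 2)
  } else {
    if (length(A) < 3L)
      warning(sprintf("only %d overlapping studies between outcomes %s and %s; the cross-covariance estimate is very unstable",
                      length(A), fit_j$outcome, fit_k$outcome))
    i1 <- match(A, fit_j$study_ids)
    i2 <- match(A, fit_k$study_ids)
    r1 <- fit_j$residuals[i1]
    r2 <- fit_k$residuals[i2]
    # meat = sum_{i in A} x1_i' r1_i r2_i x2_i  (2x2)
    meat <- crossprod(X1[i1, , drop = FALSE] * r1, X2[i2, , drop = FALSE] * r2)
    C12 <- solve(crossprod(X1)) %*% meat %*% solve(crossprod(X2))
  }
  dimnames(C12) <- list(c("alpha", "beta"), c("alpha", "beta"))
  structure(list(outcome_pair = c(fit_j$outcome, fit_k$outcome),
                 matrix = C12, overlap_ids = A, overlap_n = length(A)),
            class = "cross_covariance")
}

#' @export
print.cross_covariance <- function(x, ...) {
  cat(sprintf("cross-covariance of theta(%s) and theta(%s), overlap |A| = %d\n",
              x$outcome_pair[1L], x$outcome_pair[2L], x$overlap_n))
  print(x$matrix)
  invisible(x)
}

#' Assemble the slope vector and its covariance across outcomes
#'
#' Builds the \eqn{2J \times 2J} covariance \eqn{C_\theta} of all stacked
#' per-outcome estimates \eqn{\hat\theta_j = (\hat\alpha_j, \hat\beta_j)},
#' with the per-fit covariances on the diagonal blocks and the sandwich
#' cross-covariances off the diagonal, then extracts the \eqn{J \times J}
#' slope covariance \eqn{C_\beta} and symmetrises it as
#' \eqn{(C_\beta + C_\beta^\top)/2}.
#'
#' @param fits list of \code{ssfit} objects, one per outcome, in outcome
#'   order.
#' @param crosses list of [cross_covariance()] results for every unordered
#'   pair, in the order \code{(1,2), (1,3), ..., (2,3), ...}; may be omitted
#'   or \code{NULL} for a block-diagonal assembly (no overlap anywhere).
#' @return list with \code{beta} (length-J named vector), \code{cov_beta}
#'   (J x J), and \code{cov_theta} (2J x 2J).
#' @export
assemble_beta_covariance <- function(fits, crosses = NULL) {
  J <- length(fits)
  if (J < 2L) stop("at least two outcomes are required")
  if (!all(vapply(fits, inherits, logical(1), "ssfit")))
    stop("'fits' must be a list of ssfit objects")
  npair <- J * (J - 1L) / 2L
  if (!is.null(crosses) && length(crosses) != npair)
    stop(sprintf("expected %d cross-covariance blocks for J = %d, got %d",
                 npair, J, length(crosses)))

  Ctheta <- matrix(0, 2L * J, 2L * J)
  for (j in seq_len(J)) {
    idx <- (2L * j - 1L):(2L * j)
    Ctheta[idx, idx] <- fits[[j]]$cov_theta
  }
  if (!is.null(crosses)) {
    pos <- 0L
    for (j in seq_len(J - 1L)) for (k in (j + 1L):J) {
      pos <- pos + 1L
      Cjk <- crosses[[pos]]$matrix
      if (!all(dim(Cjk) == c(2L, 2L)))
        stop("cross-covariance blocks must be 2x2")
      rj <- (2L * j - 1L):(2L * j); rk <- (2L * k - 1L):(2L * k)
      Ctheta[rj, rk] <- Cjk
      Ctheta[rk, rj] <- t(Cjk)
    }
  }

  bidx <- 2L * seq_len(J)
  cov_beta <- Ctheta[bidx, bidx, drop = FALSE]
  cov_beta <- (cov_beta + t(cov_beta)) / 2
  beta <- vapply(fits, function(f) f$beta, numeric(1))
  names(beta) <- vapply(fits, function(f) f$outcome, character(1))
  dimnames(cov_beta) <- list(names(beta), names(beta))
  list(beta = beta, cov_beta = cov_beta, cov_theta = Ctheta)
}

#' Global Wald test that all small-study slopes are zero
#'
#' Computes \eqn{\chi^2 = \hat\beta^\top C_\beta^{-1} \hat\beta} on \eqn{J}
#' degrees of freedom for \eqn{H_0: \beta_1 = \dots = \beta_J = 0}. The
#' assembled covariance can fail to be nonnegative definite (the sandwich
#' cross blocks are not constrained); in that case the negative eigenvalues
#' are clipped to zero, the Moore–Penrose pseudo-inverse is used, the degrees
#' of freedom drop to the rank, and the result is flagged
#' (\code{psd_ok = FALSE}, \code{repaired = TRUE}).
#'
#' @param beta numeric length-J vector of slope estimates.
#' @param cov_beta symmetric J x J covariance of \code{beta}.
#' @return An object of class \code{ss_global_test}: list with \code{beta},
#'   \code{cov_beta}, \code{chi2}, \code{df}, \code{p}, \code{psd_ok},
#'   \code{repaired}.
#' @examples
#' global_beta_test(c(1, 1), diag(2))   # chi^2 = 2, p = exp(-1)
#' @export
global_beta_test <- function(beta, cov_beta) {
  beta <- as.numeric(beta)
  cov_beta <- as.matrix(cov_beta)
  J <- length(beta)
  if (!all(dim(cov_beta) == c(J, J)))
    stop("'cov_beta' must be J x J with J = length(beta)")
  if (max(abs(cov_beta - t(cov_beta))) > 1e-8 * max(1, max(abs(cov_beta))))
    stop("'cov_beta' must be symmetric")
  cov_beta <- (cov_beta + t(cov_beta)) / 2

  if (all(cov_beta == 0)) {
    if (any(beta != 0))
      stop("degenerate covariance: cov_beta is zero but beta is not")
    return(structure(list(beta = beta, cov_beta = cov_beta, chi2 = 0,
                          df = J, p = 1, psd_ok = TRUE, repaired = FALSE),
                     class = "ss_global_test"))
  }

  ev <- eigen(cov_beta, symmetric = TRUE)
  lmax <- max(abs(ev$values))
  psd_ok <- min(ev$values) >= -1e-10 * lmax
  repaired <- FALSE
  if (psd_ok && min(ev$values) > 1e-12 * lmax) {
    z <- solve(cov_beta, beta)
    chi2 <- drop(crossprod(beta, z))
    df <- J
  } else {
    # clip negative (or numerically zero) eigenvalues, pseudo-invert,
    # reduce df to the retained rank
    repaired <- !psd_ok
    lam <- pmax(ev$values, 0)
    keep <- lam > 1e-12 * lmax
    df <- sum(keep)
    Vk <- ev$vectors[, keep, drop = FALSE]
    pinv <- Vk %*% (t(Vk) / lam[keep])
    chi2 <- drop(crossprod(beta, pinv %*% beta))
  }
  chi2 <- max(0, chi2)
  structure(list(beta = beta, cov_beta = cov_beta, chi2 = chi2, df = df,
                 p = chisq_upper_tail(chi2, df), psd_ok = psd_ok,
                 repaired = repaired),
            class = "ss_global_test")
}

#' @export
print.ss_global_test <- function(x, digits = 4, ...) {
  cat(sprintf("Global test of H0: all small-study slopes = 0\n"))
  cat(sprintf("  chi^2 = %s, df = %d, p = %s\n",
              format(x$chi2, digits = digits), x$df,
              format(x$p, digits = digits)))
  if (!x$psd_ok)
    cat("  WARNING: assembled covariance was not nonnegative definite;",
        "eigenvalues clipped, pseudo-inverse used, df reduced to rank\n")
  invisible(x)
}

#' Multivariate small-study-effect analysis
#'
#' Full pipeline on a multi-outcome dataset: per-outcome fits (see
#' [fit_small_study()]), all pairwise sandwich cross-covariances over the
#' overlap sets, assembly of the slope covariance, the global \eqn{\chi^2}
#' test on \eqn{J} degrees of freedom, and (optionally, when the global test
#' is significant at \code{alpha}) the Shaffer-type sequentially rejective
#' multiple-testing step on the univariate p-values.
#'
#' @param dataset a [meta_dataset()] with \eqn{J \ge 1} outcomes.
#' @param model,tau2_method passed to [fit_small_study()].
#' @param alpha level for the multiple-testing step (and its gate).
#' @param mtp run the sequential multiple-testing step? (default \code{TRUE})
#' @param gate_mtp if \code{TRUE} (default) the multiple-testing step is only
#'   applied when the global p-value is \eqn{\le} \code{alpha}; set
#'   \code{FALSE} to run it unconditionally.
#' @return An object of class \code{ssmv}: list with \code{fits},
#'   \code{crosses}, \code{beta}, \code{cov_beta}, \code{global} (an
#'   \code{ss_global_test}, \code{NULL} when \eqn{J = 1}), \code{mtp} (a
#'   \code{sequential_test}, or \code{NULL}), \code{alpha}. \code{print} and
#'   \code{summary} render the standard report table.
#' @examples
#' cfg <- sim_config(n = 40, overlap = 20, seed = 7)
#' d <- simulate_dataset(cfg)
#' mv_small_study(d)
#' @export
mv_small_study <- function(dataset, model = c("hybrid", "egger", "linchu"),
                           tau2_method = c("DL", "REML"), alpha = 0.10,
                           mtp = TRUE, gate_mtp = TRUE) {
  stopifnot(inherits(dataset, "meta_dataset"))
  model <- match.arg(model); tau2_method <- match.arg(tau2_method)
  J <- length(dataset$outcome_names)
  fits <- lapply(seq_len(J), function(j)
    fit_small_study(dataset, model = model, tau2_method = tau2_method,
                    outcome = j))

  crosses <- NULL; global <- NULL; asm <- NULL
  if (J >= 2L) {
    crosses <- list(); pos <- 0L
    for (j in seq_len(J - 1L)) for (k in (j + 1L):J) {
      pos <- pos + 1L
      crosses[[pos]] <- cross_covariance(fits[[j]], fits[[k]], dataset)
    }
    asm <- assemble_beta_covariance(fits, crosses)
    global <- global_beta_test(asm$beta, asm$cov_beta)
  }

  seq_res <- NULL
  if (mtp) {
    pj <- vapply(fits, function(f) if (is.na(f$p)) f$p_star else f$p,
                 numeric(1))
    gate_pass <- if (is.null(global)) TRUE else global$p <= alpha
    if (!gate_mtp || gate_pass)
      seq_res <- sequential_reject(pj, alpha = alpha)
  }

  structure(list(fits = fits, crosses = crosses,
                 beta = if (is.null(asm)) NULL else asm$beta,
                 cov_beta = if (is.null(asm)) NULL else asm$cov_beta,
                 global = global, mtp = seq_res, alpha = alpha,
                 outcome_names = dataset$outcome_names),
            class = "ssmv")
}

#' @export
print.ssmv <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' @export
summary.ssmv <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$fits, function(f) summary(f)$table))
  structure(list(object = object, table = tab), class = "summary.ssmv")
}

#' @export
print.summary.ssmv <- function(x, ...) {
  print(x$object)
  invisible(x)
}
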