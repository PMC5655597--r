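# MAP estimation of the latent trait vector under a multivariate-normal
# prior with the calibrated latent correlation matrix as covariance, plus
# the posterior information matrix and per-dimension standard errors.

# Gradient of the log-likelihood wrt theta and the expected-information
# likelihood contribution to the Hessian, both at theta, for an
# administered set already normalized by as_administered().
loglik_grad_info <- function(bank, adm, theta) {
  D <- length(theta)
  g <- numeric(D)
  info_diag <- numeric(D)
  for (k in seq_along(adm$item)) {
    i <- adm$item[k]
    d <- bank$domain[i]
    cum <- grm_cumulative(bank$alpha[i], bank$betas[[i]], theta[d])
    w <- cum * (1 - cum)
    p <- pmax(-diff(cum), PROB_FLOOR)
    j <- adm$category[k] + 1L
    # d log P_j / d theta_d = alpha * (w_j - w_{j+1}) / P_j
    g[d] <- g[d] + bank$alpha[i] * (w[j] - w[j + 1L]) / p[j]
    info_diag[d] <- info_diag[d] + bank$alpha[i]^2 * sum(diff(w)^2 / p)
  }
  list(grad = g, info_diag = info_diag)
}

#' MAP estimate of the latent trait
#'
#' Maximizes the log-posterior
#' \eqn{\ell(\theta) + \log \mathrm{MVN}(\theta; 0, \Phi)} by
#' Newton-Raphson with the analytic gradient, the expected-information
#' Hessian approximation and step-halving on non-increase. With no
#' administered items the prior mode \code{rep(0, D)} is returned.
#'
#' @param bank an \code{\link{item_bank}}.
#' @param administered data frame with columns \code{item}, \code{category}
#'   (0-based); may be empty.
#' @param prior_correlation positive-definite prior covariance; defaults to
#'   the bank's latent correlation matrix.
#' @param start optional warm-start vector (CAT loops pass the previous
#'   estimate); defaults to the prior mode.
#' @param tol convergence tolerance on the max-norm of the Newton step.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last iterate and gradient norm in its message.
#' @return numeric vector of length \code{bank$n_dimensions}.
#' @export
map_estimate <- function(bank, administered,
                         prior_correlation = bank$correlation,
                         start = NULL, tol = 1e-6, max_iter = 100L) {
  D <- bank$n_dimensions
  adm <- as_administered(bank, administered)
  prior_prec <- solve_pd(prior_correlation, "prior correlation")
  if (!length(adm$item)) return(numeric(D))
  theta <- if (is.null(start)) numeric(D) else check_theta(start, D)

  log_post <- function(th) {
    ll <- 0
    for (k in seq_along(adm$item)) {
      i <- adm$item[k]
      cum <- grm_cumulative(bank$alpha[i], bank$betas[[i]], th[bank$domain[i]])
      p <- cum[adm$category[k] + 1L] - cum[adm$category[k] + 2L]
      ll <- ll + log(max(p, PROB_FLOOR))
    }
    ll - 0.5 * drop(crossprod(th, prior_prec %*% th))
  }

  lp <- log_post(theta)
  for (iter in seq_len(max_iter)) {
    gi <- loglik_grad_info(bank, adm, theta)
    grad <- gi$grad - drop(prior_prec %*% theta)
    J <- prior_prec
    diag(J) <- diag(J) + gi$info_diag
    step <- solve(J, grad)
    if (max(abs(step)) < tol) return(theta)
    # step-halving: the expected-information step can overshoot far from
    # the mode; halve until the log-posterior does not decrease
    lam <- 1
    repeat {
      cand <- theta + lam * step
      lp_cand <- log_post(cand)
      if (lp_cand >= lp - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    theta <- cand
    lp <- lp_cand
    if (lam * max(abs(step)) < tol) return(theta)
  }
  gi <- loglik_grad_info(bank, adm, theta)
  grad <- gi$grad - drop(prior_prec %*% theta)
  stop(sprintf(
    "MAP estimation did not converge in %d iterations (last theta: %s; gradient norm %.3g)",
    max_iter, paste(sprintf("%.4f", theta), collapse = ", "),
    sqrt(sum(grad^2))))
}

solve_pd <- function(M, what = "matrix") {
  M <- as.matrix(M)
  ch <- tryCatch(chol(M), error = function(e)
    stop(what, " is not positive definite", call. = FALSE))
  chol2inv(ch)
}

#' Posterior information matrix
#'
#' Prior precision plus the sum of the administered items' expected Fisher
#' information matrices, all evaluated at \code{theta_hat}:
#' \eqn{J = \Phi^{-1} + \sum_k s_k a_k a_k^T}. Always symmetric positive
#' definite; with no items it is exactly \eqn{\Phi^{-1}}. The determinant
#' of this matrix drives Segall's D-optimal item selection.
#'
#' @inheritParams map_estimate
#' @param theta_hat latent-trait vector at which to evaluate item
#'   information (normally the MAP estimate).
#' @return a D x D matrix.
#' @export
posterior_information <- function(bank, administered, theta_hat,
                                  prior_correlation = bank$correlation) {
  D <- bank$n_dimensions
  theta_hat <- check_theta(theta_hat, D)
  adm <- as_administered(bank, administered)
  J <- solve_pd(prior_correlation, "prior correlation")
  for (k in seq_along(adm$item)) {
    i <- adm$item[k]
    d <- bank$domain[i]
    s <- grm_scalar_information(bank$alpha[i], bank$betas[[i]], theta_hat[d])
    J[d, d] <- J[d, d] + s * bank$alpha[i]^2
  }
  J
}

#' Per-dimension standard errors from a posterior information matrix
#'
#' Square roots of the diagonal of the inverse information matrix; the
#' CAT termination rule compares these to the SE threshold (0.316,
#' i.e. reliability 0.9) per dimension.
#'
#' @param posterior_info symmetric positive-definite matrix.
#' @return numeric vector of positive standard errors.
#' @export
standard_errors <- function(posterior_info) {
  V <- solve_pd(posterior_info, "posterior information")
  sqrt(diag(V))
}

#' Build the posterior state after a set of responses
#'
#' Convenience wrapper running \code{\link{map_estimate}},
#' \code{\link{posterior_information}} and \code{\link{standard_errors}}
#' and applying the per-dimension termination rule.
#'
#' @inheritParams map_estimate
#' @param se_threshold termination threshold on the per-dimension SE.
#' @param start warm start passed to \code{map_estimate}.
#' @return an object of class \code{posterior_state} with fields
#'   \code{administered} (normalized item/category vectors),
#'   \code{theta_hat}, \code{posterior_info}, \code{se} and
#'   \code{terminated_dims} (integer indices with \code{se < se_threshold}).
#' @export
posterior_state <- function(bank, administered,
                            prior_correlation = bank$correlation,
                            se_threshold = 0.316, start = NULL) {
  adm <- as_administered(bank, administered)
  theta_hat <- map_estimate(bank, administered, prior_correlation,
                            start = start)
  J <- posterior_information(bank, administered, theta_hat,
                             prior_correlation)
  se <- standard_errors(J)
  structure(
    list(administered = adm, theta_hat = theta_hat, posterior_info = J,
         se = se, terminated_dims = which(se < se_threshold),
         se_threshold = se_threshold),
    class = "posterior_state")
}

#' @export
print.posterior_state <- function(x, ...) {
  cat(sprintf("<posterior_state> %d items administered\n",
              length(x$administered$item)))
  cat("  theta_hat:", paste(sprintf("%.3f", x$theta_hat), collapse = " "), "\n")
  cat("  se       :", paste(sprintf("%.3f", x$se), collapse = " "), "\n")
  cat("  terminated dims:",
      if (length(x$terminated_dims)) paste(x$terminated_dims, collapse = " ")
      else "none", "\n")
  invisible(x)
}
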