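# Adaptive test loop: one random starting item per domain, Segall
# determinant-based (D-optimal / "Bayesian Volume Decrease") item
# selection restricted to unterminated dimensions, response simulation,
# MAP re-estimation after every item, per-dimension SE termination.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' CAT configuration
#'
#' @param se_threshold per-dimension standard-error termination threshold.
#'   The default 0.316 is the reliability-0.9 convention
#'   (\eqn{\sqrt{1 - 0.9}}).
#' @param n_initial_per_domain number of random starting items per domain.
#' @param max_length safety cap on test length; default \code{NULL} means
#'   the bank size (a non-converged CAT is recorded, not discarded).
#' @param seed optional integer seed applied at the start of
#'   \code{\link{run_cat}}; \code{NULL} uses the current RNG state.
#' @return object of class \code{cat_config}.
#' @export
cat_config <- function(se_threshold = 0.316, n_initial_per_domain = 1L,
                       max_length = NULL, seed = NULL) {
  stopifnot(is.numeric(se_threshold), length(se_threshold) == 1L,
            se_threshold > 0)
  n_initial_per_domain <- as.integer(n_initial_per_domain)
  stopifnot(n_initial_per_domain >= 1L)
  if (!is.null(max_length)) {
    max_length <- as.integer(max_length)
    stopifnot(max_length >= 1L)
  }
  structure(list(se_threshold = se_threshold,
                 n_initial_per_domain = n_initial_per_domain,
                 max_length = max_length, seed = seed),
            class = "cat_config")
}

# draw a response for bank item i at theta using the current RNG stream
simulate_response_idx <- function(bank, i, theta) {
  cum <- grm_cumulative(bank$alpha[i], bank$betas[[i]], theta[bank$domain[i]])
  p <- -diff(cum)
  sum(stats::runif(1) > cumsum(p))
}

# D-optimal selection criterion for every candidate item index, given the
# inverse posterior information. The rank-1 determinant identity
# det(J + s a a') = det(J) (1 + s a' J^{-1} a) with a = alpha e_d reduces
# the criterion to s * alpha^2 * (J^{-1})_{dd}, so selection costs one
# D x D inverse plus O(candidates).
selection_criterion <- function(bank, candidates, theta, Jinv) {
  s <- vapply(candidates, function(i)
    grm_scalar_information(bank$alpha[i], bank$betas[[i]],
                           theta[bank$domain[i]]), 0)
  s * bank$alpha[candidates]^2 * diag(Jinv)[bank$domain[candidates]]
}

#' Select the next item by the posterior-information determinant
#'
#' Among items not yet administered whose domain has not terminated,
#' returns the one maximizing \eqn{\det(J + I_k(\hat\theta))}, evaluated
#' through the rank-1 determinant identity. Exact ties are broken
#' uniformly at random from the current RNG stream. The determinant is
#' taken over the full D x D matrix even when some dimensions have
#' terminated: termination restricts eligibility, not the objective.
#'
#' @param state a \code{\link{posterior_state}}.
#' @param bank an \code{\link{item_bank}}.
#' @return the selected item id (character).
#' @export
select_next_item <- function(state, bank) {
  administered <- state$administered$item
  eligible <- setdiff(which(!(bank$domain %in% state$terminated_dims)),
                      administered)
  if (!length(eligible))
    stop(structure(class = c("bank_exhausted", "error", "condition"),
                   list(message = "no eligible item remains",
                        call = sys.call())))
  Jinv <- solve_pd(state$posterior_info, "posterior information")
  crit <- selection_criterion(bank, eligible, state$theta_hat, Jinv)
  best <- which(crit >= max(crit) * (1 - 1e-12))
  pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
  bank$item_id[eligible[pick]]
}

#' Record a response and refresh the posterior state
#'
#' Appends \code{(item_id, category)} to the administered set, re-runs MAP
#' estimation (warm-started at the previous estimate), and recomputes the
#' posterior information matrix, standard errors and terminated dimensions.
#'
#' @param state a \code{\link{posterior_state}}.
#' @param bank an \code{\link{item_bank}}.
#' @param item_id item to administer (id or index); administering an item
#'   twice is an error.
#' @param category observed 0-based response category.
#' @return the updated \code{posterior_state}.
#' @export
administer_and_update <- function(state, bank, item_id, category) {
  idx <- resolve_item_index(bank, item_id)
  if (idx %in% state$administered$item)
    stop("item '", bank$item_id[idx], "' was already administered")
  adm <- data.frame(
    item = c(state$administered$item, idx),
    category = c(state$administered$category, as.integer(category)))
  posterior_state(bank, adm, se_threshold = state$se_threshold,
                  start = state$theta_hat)
}

new_cat_result <- function(respondent_id, true_theta, item_idx, categories,
                           theta_final, se_final, converged, bank,
                           n_initial, grid_value = NA_real_) {
  structure(
    list(respondent_id = respondent_id,
         true_theta = true_theta,
         items = bank$item_id[item_idx],
         item_idx = item_idx,
         categories = categories,
         theta_final = theta_final,
         se_final = se_final,
         test_length = length(item_idx),
         n_initial = n_initial,
         converged = converged,
         grid_value = grid_value),
    class = "cat_result")
}

#' @export
print.cat_result <- function(x, ...) {
  cat(sprintf("<cat_result %s> %d items, %s\n", x$respondent_id,
              x$test_length,
              if (x$converged) "converged" else "not converged"))
  cat("  theta_final:", paste(sprintf("%.3f", x$theta_final), collapse = " "),
      "\n  se_final   :", paste(sprintf("%.3f", x$se_final), collapse = " "),
      "\n")
  invisible(x)
}

#' Run one simulated adaptive test
#'
#' Administers one uniformly random item from each domain (in domain
#' order), then iterates: MAP re-estimation, per-dimension termination
#' check, determinant-based selection among eligible items, response
#' simulation at \code{true_theta}. Stops when every dimension's SE is
#' below the threshold, when no eligible item remains, or at
#' \code{max_length}. Initial items count toward test length and usage.
#'
#' @param bank an \code{\link{item_bank}}.
#' @param true_theta generating latent-trait vector.
#' @param config a \code{\link{cat_config}}.
#' @param respondent_id label carried into the result.
#' @return object of class \code{cat_result}: administered item sequence
#'   with responses, final estimate and SEs, test length, convergence flag.
#' @examples
#' bank <- generate_item_bank(bank_recipe(domain_sizes = c(8, 8),
#'   correlation = matrix(c(1, .7, .7, 1), 2), seed = 1))
#' run_cat(bank, true_theta = c(0, 0), cat_config(seed = 42))
#' @export
run_cat <- function(bank, true_theta, config = cat_config(),
                    respondent_id = "sim") {
  if (!is.null(config$seed)) set.seed(config$seed)
  D <- bank$n_dimensions
  true_theta <- check_theta(true_theta, D)
  n_items <- length(bank$items)
  max_len <- config$max_length %||% n_items
  prior_prec <- solve_pd(bank$correlation, "prior correlation")

  administered <- logical(n_items)
  item_seq <- integer(0)
  cat_seq <- integer(0)

  # initial block: n_initial_per_domain random items from each domain
  for (d in seq_len(D)) {
    pool <- which(bank$domain == d)
    take <- min(config$n_initial_per_domain, length(pool))
    if (!take) next
    picked <- if (length(pool) == 1L) pool else
      pool[sample.int(length(pool), take)]
    for (i in picked) {
      item_seq <- c(item_seq, i)
      cat_seq <- c(cat_seq, simulate_response_idx(bank, i, true_theta))
      administered[i] <- TRUE
    }
  }
  n_initial <- length(item_seq)

  theta <- numeric(D)
  repeat {
    theta <- map_estimate(bank,
                          data.frame(item = item_seq, category = cat_seq),
                          start = theta)
    J <- prior_prec
    for (i in item_seq) {
      d <- bank$domain[i]
      J[d, d] <- J[d, d] +
        grm_scalar_information(bank$alpha[i], bank$betas[[i]], theta[d]) *
        bank$alpha[i]^2
    }
    Jinv <- chol2inv(chol(J))
    se <- sqrt(diag(Jinv))
    terminated <- se < config$se_threshold
    if (all(terminated) || length(item_seq) >= max_len) break
    eligible <- which(!administered & !terminated[bank$domain])
    if (!length(eligible)) break
    crit <- selection_criterion(bank, eligible, theta, Jinv)
    best <- which(crit >= max(crit) * (1 - 1e-12))
    pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
    i <- eligible[pick]
    item_seq <- c(item_seq, i)
    cat_seq <- c(cat_seq, simulate_response_idx(bank, i, true_theta))
    administered[i] <- TRUE
  }

  new_cat_result(respondent_id, true_theta, item_seq, cat_seq,
                 theta_final = theta, se_final = se,
                 converged = all(terminated), bank = bank,
                 n_initial = n_initial)
}
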