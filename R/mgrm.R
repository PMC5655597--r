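# Between-item multidimensional graded response model (MGRM):
# category probabilities, response simulation, log-likelihood and Fisher
# information for polytomous items that each load on a single latent
# dimension, with multidimensionality carried by the latent correlation.

#' Probability floor applied before logarithms and divisions
#'
#' Thresholds in realistic health banks span roughly -7.6 to 7.7, so at
#' extreme latent values the probability of an off-target category can
#' underflow; every probability is floored at this constant before it is
#' used in a logarithm or a denominator.
#' @keywords internal
PROB_FLOOR <- 1e-10

#' Construct the parameters of a single graded-response item
#'
#' An item in a between-item multidimensional graded response model loads
#' on exactly one latent dimension: it has a single positive discrimination
#' \code{alpha} on its own dimension (all other loadings are structurally
#' zero) and \code{m = n_categories - 1} strictly increasing thresholds
#' \code{betas} on the \code{alpha * theta - beta} metric.
#'
#' @param item_id character scalar identifying the item.
#' @param domain integer index (1-based) of the latent dimension the item
#'   measures.
#' @param alpha positive discrimination parameter.
#' @param betas numeric vector of strictly increasing thresholds; its length
#'   fixes the number of response categories (\code{length(betas) + 1},
#'   between 2 and 5).
#' @return An object of class \code{item_parameters}.
#' @examples
#' item_parameters("PF1", domain = 2, alpha = 2.1, betas = c(-1.5, 0, 1.2))
#' @export
item_parameters <- function(item_id, domain, alpha, betas) {
  stopifnot(is.character(item_id), length(item_id) == 1L)
  domain <- as.integer(domain)
  if (length(domain) != 1L || is.na(domain) || domain < 1L)
    stop("'domain' must be a positive integer index")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("'alpha' must be a single positive finite number (item '",
         item_id, "')")
  betas <- as.numeric(betas)
  m <- length(betas)
  if (m < 1L || m > 4L)
    stop("items must have 2..5 categories, got ", m + 1L,
         " (item '", item_id, "')")
  if (any(!is.finite(betas)))
    stop("non-finite threshold for item '", item_id, "'")
  if (m > 1L && any(diff(betas) <= 0))
    stop("thresholds must be strictly increasing for item '", item_id, "'")
  structure(
    list(item_id = item_id, domain = domain, alpha = alpha,
         betas = betas, n_categories = m + 1L),
    class = "item_parameters")
}

#' @export
print.item_parameters <- function(x, ...) {
  cat(sprintf("<item %s> domain %d, alpha %.3f, betas (%s)\n",
              x$item_id, x$domain, x$alpha,
              paste(sprintf("%.3f", x$betas), collapse = ", ")))
  invisible(x)
}

#' Assemble a multidimensional item bank
#'
#' Bundles a set of \code{\link{item_parameters}} with the latent-trait
#' correlation matrix. The correlation matrix doubles as the prior
#' covariance in MAP estimation (latent variances are fixed at 1).
#' Flat copies of the parameters (\code{alpha}, \code{domain},
#' \code{betas} list) are precomputed for the simulation engine.
#'
#' @param items list of \code{item_parameters}.
#' @param correlation symmetric positive-definite matrix with unit diagonal;
#'   its order fixes the number of latent dimensions.
#' @param domain_labels optional character vector of dimension names.
#' @return An object of class \code{item_bank}.
#' @export
item_bank <- function(items, correlation, domain_labels = NULL) {
  if (!length(items) || !all(vapply(items, inherits, TRUE, "item_parameters")))
    stop("'items' must be a non-empty list of item_parameters")
  correlation <- as.matrix(correlation)
  D <- nrow(correlation)
  if (ncol(correlation) != D)
    stop("'correlation' must be square")
  if (any(abs(diag(correlation) - 1) > 1e-8))
    stop("'correlation' must have unit diagonal")
  if (any(abs(correlation - t(correlation)) > 1e-8))
    stop("'correlation' must be symmetric")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("'correlation' must be positive definite (min eigenvalue ",
         format(min(ev)), ")")
  domains <- vapply(items, `[[`, 1L, "domain")
  if (any(domains > D))
    stop("item domain index exceeds the number of dimensions (", D, ")")
  ids <- vapply(items, `[[`, "", "item_id")
  if (anyDuplicated(ids))
    stop("duplicate item ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(domain_labels))
    domain_labels <- paste0("dim", seq_len(D))
  if (length(domain_labels) != D)
    stop("'domain_labels' must have one entry per dimension")
  structure(
    list(items = items,
         n_dimensions = D,
         correlation = correlation,
         domain_labels = as.character(domain_labels),
         item_id = ids,
         domain = domains,
         alpha = vapply(items, `[[`, 0, "alpha"),
         betas = lapply(items, `[[`, "betas"),
         n_categories = vapply(items, `[[`, 0L, "n_categories")),
    class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %d items, %d dimensions (%s)\n",
              length(x$items), x$n_dimensions,
              paste(x$domain_labels, collapse = ", ")))
  tab <- table(factor(x$domain, levels = seq_len(x$n_dimensions)))
  cat("  items per domain:", paste(tab, collapse = "/"), "\n")
  invisible(x)
}

#' Number of items in a bank
#' @param x an \code{item_bank}.
#' @param ... ignored.
#' @export
length.item_bank <- function(x) length(x$items)

check_theta <- function(theta, D) {
  theta <- as.numeric(theta)
  if (length(theta) != D || any(!is.finite(theta)))
    stop("'theta' must be a finite numeric vector of length ", D)
  theta
}

# Cumulative curves C_j = plogis(alpha*theta_d - beta_j), padded with the
# boundary conventions C_0 = 1, C_{m+1} = 0 so that P_j = C_j - C_{j+1}.
grm_cumulative <- function(alpha, betas, theta_d) {
  c(1, stats::plogis(alpha * theta_d - betas), 0)
}

#' Category probabilities of a graded-response item
#'
#' Evaluates the three-branch graded response model at a latent-trait
#' vector: with cumulative curves
#' \eqn{\Psi_j = \Psi(\alpha \theta_d - \beta_j)} (logistic \eqn{\Psi},
#' \eqn{d} the item's own dimension), category \eqn{j} has probability
#' \eqn{\Psi_j - \Psi_{j+1}} under the conventions \eqn{\Psi_0 = 1},
#' \eqn{\Psi_{m+1} = 0}.
#'
#' @param item an \code{\link{item_parameters}} object.
#' @param theta numeric latent-trait vector; its length must be at least
#'   the item's domain index (pass the full D-vector).
#' @return numeric vector of length \code{item$n_categories}, positive and
#'   summing to 1.
#' @examples
#' it <- item_parameters("x", 1, alpha = 1, betas = c(-1, 0, 1))
#' category_probabilities(it, theta = 0)
#' @export
category_probabilities <- function(item, theta) {
  theta <- as.numeric(theta)
  if (item$domain > length(theta) || any(!is.finite(theta)))
    stop("'theta' too short for item on dimension ", item$domain)
  cum <- grm_cumulative(item$alpha, item$betas, theta[item$domain])
  -diff(cum)
}

#' Simulate one graded response
#'
#' Draws a category index from the categorical distribution given by
#' \code{\link{category_probabilities}}, using R's current random number
#' stream (seed with \code{set.seed} for reproducibility).
#'
#' @inheritParams category_probabilities
#' @return integer category index in \code{0..(n_categories - 1)}.
#' @export
simulate_response <- function(item, theta) {
  p <- category_probabilities(item, theta)
  # inverse-CDF draw keeps one uniform per response, cheap and reproducible
  sum(stats::runif(1) > cumsum(p))
}

resolve_item_index <- function(bank, item) {
  if (is.character(item)) {
    idx <- match(item, bank$item_id)
    if (anyNA(idx)) stop("unknown item id: ",
                         paste(item[is.na(idx)], collapse = ", "))
    idx
  } else {
    idx <- as.integer(item)
    if (any(idx < 1L | idx > length(bank$items)))
      stop("item index out of range")
    idx
  }
}

# Normalize the administered argument to list(item = int vector,
# category = int vector). Accepts a two-column data.frame/matrix with
# columns item (id or index) and category, or NULL/empty.
as_administered <- function(bank, administered) {
  if (is.null(administered) || NROW(administered) == 0L)
    return(list(item = integer(0), category = integer(0)))
  if (is.matrix(administered)) administered <- as.data.frame(administered)
  if (!all(c("item", "category") %in% names(administered)))
    stop("'administered' needs columns 'item' and 'category'")
  idx <- resolve_item_index(bank, administered$item)
  cat <- as.integer(administered$category)
  bad <- which(cat < 0L | cat >= bank$n_categories[idx])
  if (length(bad))
    stop("invalid category ", cat[bad[1]], " for item '",
         bank$item_id[idx[bad[1]]], "'")
  list(item = idx, category = cat)
}

#' Log-likelihood of a response pattern
#'
#' Sum of log category probabilities of the observed responses under the
#' graded response model, with each probability floored at
#' \code{PROB_FLOOR} so the result is always finite.
#'
#' @param bank an \code{\link{item_bank}}.
#' @param administered data frame with columns \code{item} (id or index
#'   into the bank) and \code{category} (0-based); may be empty.
#' @param theta numeric latent-trait vector of length
#'   \code{bank$n_dimensions}.
#' @return scalar log-likelihood (0 for an empty pattern).
#' @export
response_log_likelihood <- function(bank, administered, theta) {
  adm <- as_administered(bank, administered)
  theta <- check_theta(theta, bank$n_dimensions)
  if (!length(adm$item)) return(0)
  ll <- 0
  for (k in seq_along(adm$item)) {
    i <- adm$item[k]
    cum <- grm_cumulative(bank$alpha[i], bank$betas[[i]], theta[bank$domain[i]])
    p <- cum[adm$category[k] + 1L] - cum[adm$category[k] + 2L]
    ll <- ll + log(max(p, PROB_FLOOR))
  }
  ll
}

# Scalar Fisher information of the linear predictor z = alpha*theta_d - beta
# for one item at one theta: s = sum_j (w_j - w_{j+1})^2 / P_j with
# w_j = C_j (1 - C_j) and boundary w_0 = w_{m+1} = 0. The D x D item
# information is s * alpha^2 on the (d, d) entry.
grm_scalar_information <- function(alpha, betas, theta_d) {
  cum <- grm_cumulative(alpha, betas, theta_d)
  w <- cum * (1 - cum)          # zero at both boundaries by construction
  p <- pmax(-diff(cum), PROB_FLOOR)
  sum(diff(w)^2 / p)
}

# Scalar informations of every item in the bank at theta (vector over items).
bank_scalar_information <- function(bank, theta) {
  s <- numeric(length(bank$items))
  for (i in seq_along(s))
    s[i] <- grm_scalar_information(bank$alpha[i], bank$betas[[i]],
                                   theta[bank$domain[i]])
  s
}

#' Fisher information matrix of one item
#'
#' For a between-item multidimensional model the item's loading vector is
#' \eqn{a = \alpha e_d}, so its expected information at \eqn{\theta} is the
#' rank-1 positive semi-definite matrix \eqn{s(\theta)\, a a^T}: a single
#' nonzero entry \eqn{s \alpha^2} at \code{(domain, domain)}, where \eqn{s}
#' is the unidimensional graded-response information of the linear
#' predictor.
#'
#' @inheritParams category_probabilities
#' @return a \code{length(theta)} square matrix.
#' @export
item_information <- function(item, theta) {
  theta <- as.numeric(theta)
  D <- length(theta)
  if (item$domain > D || any(!is.finite(theta)))
    stop("'theta' too short for item on dimension ", item$domain)
  s <- grm_scalar_information(item$alpha, item$betas, theta[item$domain])
  M <- matrix(0, D, D)
  M[item$domain, item$domain] <- s * item$alpha^2
  M
}
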