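# Synthetic item banks and respondent populations with the statistical
# structure of a calibrated four-domain health-related quality-of-life
# bank, plus the sparse-category collapsing rule used in data preparation.

#' Latent correlation among the four HRQL domains
#'
#' The calibrated correlation matrix among fatigue, physical function,
#' participation in social roles, and the COPD-specific domain, used both
#' as the generating correlation of synthetic populations and as the MAP
#' prior covariance (variances fixed at 1).
#'
#' @return a 4 x 4 correlation matrix with named dimensions.
#' @export
copd_hrql_correlation <- function() {
  labels <- c("Fatigue", "PhysicalFunction", "SocialRoles", "COPD-SIB")
  matrix(c(1.00, 0.77, 0.87, 0.77,
           0.77, 1.00, 0.84, 0.76,
           0.87, 0.84, 1.00, 0.77,
           0.77, 0.76, 0.77, 1.00),
         4, 4, dimnames = list(labels, labels))
}

#' Recipe for a synthetic item bank
#'
#' Defaults emulate a 194-item bank: domain sizes 50 (fatigue), 63
#' (physical function), 35 (social roles), 46 (disease-specific),
#' discriminations in 0.82-5.40, thresholds within -7.57..7.67, and a
#' category profile of 139 five-category, 51 four-category and 4
#' three-category items (the residue of sparse-category merging).
#'
#' @param domain_sizes integer vector of items per domain.
#' @param alpha_range truncation range of the log-uniform discrimination.
#' @param beta_range clipping range for thresholds.
#' @param category_profile named counts (names = number of categories).
#'   When the counts sum to the bank size they are assigned exactly;
#'   otherwise they act as sampling weights.
#' @param correlation latent correlation matrix; defaults to
#'   \code{\link{copd_hrql_correlation}} for four domains, an exchangeable
#'   0.75 matrix otherwise.
#' @param domain_labels dimension names.
#' @param seed integer seed used by \code{\link{generate_item_bank}}.
#' @return object of class \code{bank_recipe}.
#' @export
bank_recipe <- function(domain_sizes = c(50L, 63L, 35L, 46L),
                        alpha_range = c(0.82, 5.40),
                        beta_range = c(-7.57, 7.67),
                        category_profile = c(`3` = 4, `4` = 51, `5` = 139),
                        correlation = NULL,
                        domain_labels = NULL,
                        seed = NULL) {
  domain_sizes <- as.integer(domain_sizes)
  stopifnot(length(domain_sizes) >= 1L, all(domain_sizes > 0L),
            length(alpha_range) == 2L, alpha_range[1] > 0,
            alpha_range[2] >= alpha_range[1],
            length(beta_range) == 2L, beta_range[2] > beta_range[1])
  D <- length(domain_sizes)
  if (is.null(correlation)) {
    correlation <- if (D == 4L) copd_hrql_correlation() else {
      M <- matrix(0.75, D, D); diag(M) <- 1; M
    }
  }
  if (is.null(domain_labels)) {
    domain_labels <- if (!is.null(dimnames(correlation)[[1]]))
      dimnames(correlation)[[1]] else paste0("dim", seq_len(D))
  }
  if (is.null(names(category_profile)))
    stop("'category_profile' must be named by number of categories")
  ncat <- as.integer(names(category_profile))
  stopifnot(all(ncat >= 2L & ncat <= 5L), all(category_profile >= 0))
  structure(list(domain_sizes = domain_sizes, alpha_range = alpha_range,
                 beta_range = beta_range,
                 category_profile = category_profile,
                 correlation = as.matrix(correlation),
                 domain_labels = domain_labels, seed = seed),
            class = "bank_recipe")
}

# spacing constant: adjacent thresholds are kept at least this far apart
MIN_BETA_GAP <- 0.2

#' Generate a synthetic item bank from a recipe
#'
#' Discriminations are drawn log-uniformly over \code{alpha_range}
#' (heavier mass at moderate values, as in calibrated clinical banks).
#' Threshold \emph{locations} are drawn on the latent scale — normal
#' draws around an item-specific center (\code{N(0, 1.2)} centers,
#' within-item sd 0.7) — and multiplied by the item's discrimination to
#' land on the \eqn{\alpha\theta - \beta} metric, which is what makes the
#' \eqn{\beta} range of highly discriminating banks so much wider than
#' the trait range itself. Thresholds are then sorted, clipped to
#' \code{beta_range} and pushed apart to a minimum gap of 0.2.
#'
#' @param recipe a \code{\link{bank_recipe}}.
#' @return an \code{\link{item_bank}}.
#' @examples
#' bank <- generate_item_bank(bank_recipe(seed = 7))
#' length(bank)
#' @export
generate_item_bank <- function(recipe) {
  stopifnot(inherits(recipe, "bank_recipe"))
  if (!is.null(recipe$seed)) set.seed(recipe$seed)
  n <- sum(recipe$domain_sizes)
  D <- length(recipe$domain_sizes)
  domain <- rep(seq_len(D), times = recipe$domain_sizes)
  lo <- recipe$beta_range[1]; hi <- recipe$beta_range[2]

  alpha <- exp(stats::runif(n, log(recipe$alpha_range[1]),
                            log(recipe$alpha_range[2])))
  ncat_levels <- as.integer(names(recipe$category_profile))
  n_cats <- if (sum(recipe$category_profile) == n) {
    sample(rep(ncat_levels, times = recipe$category_profile))
  } else {
    sample(ncat_levels, n, replace = TRUE,
           prob = recipe$category_profile / sum(recipe$category_profile))
  }

  items <- vector("list", n)
  dom_counter <- integer(D)
  for (i in seq_len(n)) {
    m <- n_cats[i] - 1L
    center <- stats::rnorm(1, 0, 1.2)
    b <- alpha[i] * sort(stats::rnorm(m, center, 0.7))
    b <- pmin(pmax(b, lo), hi)
    if (m > 1L) for (j in 2:m) b[j] <- max(b[j], b[j - 1] + MIN_BETA_GAP)
    if (b[m] > hi) b <- b - (b[m] - hi)
    if (b[1] < lo)
      stop("infeasible threshold gap constraints: ", m,
           " thresholds with gap ", MIN_BETA_GAP,
           " do not fit the beta range")
    d <- domain[i]
    dom_counter[d] <- dom_counter[d] + 1L
    items[[i]] <- item_parameters(
      sprintf("%s_%03d", recipe$domain_labels[d], dom_counter[d]),
      domain = d, alpha = alpha[i], betas = b)
  }
  item_bank(items, recipe$correlation, recipe$domain_labels)
}

#' Draw a correlated respondent population
#'
#' Samples \code{n} latent-trait vectors from a multivariate normal with
#' mean zero, unit variances and the given correlation.
#'
#' @param correlation positive-definite correlation matrix.
#' @param n number of respondents.
#' @return an \code{n x D} matrix, one trait vector per row.
#' @export
generate_population <- function(correlation, n) {
  correlation <- as.matrix(correlation)
  R <- tryCatch(chol(correlation), error = function(e)
    stop("'correlation' must be positive definite", call. = FALSE))
  D <- nrow(correlation)
  matrix(stats::rnorm(n * D), n, D) %*% R
}

#' Merge sparsely endorsed response categories
#'
#' Applies the data-preparation rule: per item, while any category has
#' fewer than \code{min_count} responses and more than two categories
#' remain, the sparsest under-threshold category is merged with an
#' adjacent one — extreme categories merge inward, interior categories
#' merge into the smaller-count neighbor (ties toward the lower index).
#' Categories are renumbered consecutively from 0. The procedure is
#' idempotent.
#'
#' @param response_matrix respondents x items matrix of 0-based category
#'   indices (categories consecutive integers from 0).
#' @param min_count endorsement threshold below which a category is merged.
#' @return list with \code{responses} (recoded matrix) and
#'   \code{merge_map} (per item, the old-to-new category mapping as an
#'   integer vector indexed by old category + 1).
#' @export
collapse_sparse_categories <- function(response_matrix, min_count = 10L) {
  response_matrix <- as.matrix(response_matrix)
  if (!is.numeric(response_matrix) || any(response_matrix < 0) ||
      any(response_matrix != floor(response_matrix)))
    stop("'response_matrix' must contain non-negative integer categories")
  n_items <- ncol(response_matrix)
  out <- response_matrix
  merge_map <- vector("list", n_items)
  names(merge_map) <- colnames(response_matrix)
  for (j in seq_len(n_items)) {
    x <- response_matrix[, j]
    K0 <- max(x) + 1L
    if (K0 < 2L)
      stop("item ", j, " has fewer than 2 categories")
    lab <- seq_len(K0) - 1L                   # old category -> current label
    K <- K0
    repeat {
      counts <- tabulate(lab[x + 1L] + 1L, nbins = K)
      under <- which(counts < min_count)
      if (!length(under) || K <= 2L) break
      target <- under[which.min(counts[under])] - 1L   # 0-based
      nb <- if (target == 0L) 1L
            else if (target == K - 1L) K - 2L
            else if (counts[target] <= counts[target + 2L]) target - 1L
            else target + 1L
      # target and nb are adjacent labels: collapsing keep and keep+1 and
      # shifting the upper tail down renumbers consecutively in one pass
      keep <- min(target, nb)
      lab <- ifelse(lab > keep, lab - 1L, lab)
      K <- K - 1L
    }
    merge_map[[j]] <- lab
    out[, j] <- lab[x + 1L]
  }
  if (length(merge_map) && is.null(names(merge_map)))
    names(merge_map) <- paste0("item", seq_len(n_items))
  list(responses = out, merge_map = merge_map)
}
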