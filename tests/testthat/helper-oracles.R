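# Independent oracles: deliberately written from the model definitions,
# not by calling package internals, so they can sit on the other side of
# every dual-route check.

# Three-branch graded-response probabilities, written branch by branch.
oracle_category_probs <- function(alpha, betas, theta_d) {
  z <- alpha * theta_d
  m <- length(betas)
  p <- numeric(m + 1)
  p[1] <- 1 - plogis(z - betas[1])
  if (m > 1)
    for (j in seq_len(m - 1))
      p[j + 1] <- plogis(z - betas[j]) - plogis(z - betas[j + 1])
  p[m + 1] <- plogis(z - betas[m])
  p
}

# Expected negative second derivative of the log-likelihood wrt theta_d,
# by central finite differences on each category's log-probability and
# averaging over categories with the model probabilities.
oracle_item_info_numeric <- function(alpha, betas, theta_d, h = 1e-4) {
  p <- oracle_category_probs(alpha, betas, theta_d)
  info <- 0
  for (j in seq_along(p)) {
    lp <- function(t) log(oracle_category_probs(alpha, betas, t)[j])
    d2 <- (lp(theta_d + h) - 2 * lp(theta_d) + lp(theta_d - h)) / h^2
    info <- info + p[j] * (-d2)
  }
  info
}

# Dense grid-search MAP oracle for a one-dimensional bank.
oracle_map_grid <- function(bank, administered, step = 1e-3,
                            lim = c(-6, 6)) {
  grid <- seq(lim[1], lim[2], by = step)
  lp <- vapply(grid, function(t)
    response_log_likelihood(bank, administered, t) - 0.5 * t^2, 0)
  grid[which.max(lp)]
}

# Brute-force D-optimal selection: dense determinants over all eligible
# items, no rank-1 shortcut.
oracle_select_dense <- function(bank, administered_idx, terminated_dims,
                                theta_hat) {
  J <- posterior_information(
    bank, data.frame(item = administered_idx,
                     category = rep(0L, length(administered_idx))),
    theta_hat)
  # the category does not enter the information matrix, only theta does
  eligible <- setdiff(which(!(bank$domain %in% terminated_dims)),
                      administered_idx)
  dets <- vapply(eligible, function(i) {
    it <- bank$items[[i]]
    det(J + item_information(it, theta_hat))
  }, 0)
  eligible[dets >= max(dets) * (1 - 1e-10)]
}

# A random polytomous item with reproducible parameters.
random_item <- function(id, domain = 1L, m = sample(1:4, 1)) {
  item_parameters(id, domain,
                  alpha = runif(1, 0.82, 5.4),
                  betas = sort(runif(m, -3, 3) + 0.25 * seq_len(m)))
}
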