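# Small deterministic fixtures built in code.

corr2 <- function(rho = 0.6) matrix(c(1, rho, rho, 1), 2, 2)

# Fixed 4-item, 2-dimension bank with hand-picked parameters.
toy_bank <- function() {
  item_bank(list(
    item_parameters("A1", 1, alpha = 1.8, betas = c(-1.0, 0.2, 1.1)),
    item_parameters("A2", 1, alpha = 0.9, betas = c(-0.5, 1.5)),
    item_parameters("B1", 2, alpha = 2.5, betas = c(-2.0, -0.4, 0.6, 1.9)),
    item_parameters("B2", 2, alpha = 1.2, betas = 0.3)),
    corr2(), c("left", "right"))
}

# Random bank of n items spread over D dimensions (seed set by caller).
random_bank <- function(n = 20, D = 2, rho = 0.6) {
  M <- matrix(rho, D, D); diag(M) <- 1
  items <- lapply(seq_len(n), function(i)
    random_item(sprintf("it%02d", i), domain = 1L + (i - 1L) %% D))
  item_bank(items, M)
}

# One-dimensional bank wrapper (correlation is the 1x1 identity).
bank_1d <- function(items) item_bank(items, matrix(1, 1, 1), "only")

# Minimal stand-in for a cat_result, for usage accounting tests.
fake_result <- function(items, grid_value, true_theta = 0,
                        theta_final = true_theta) {
  structure(list(respondent_id = "fake", true_theta = true_theta,
                 items = items, categories = rep(0L, length(items)),
                 theta_final = theta_final, se_final = NA_real_,
                 test_length = length(items), n_initial = 0L,
                 converged = TRUE, grid_value = grid_value),
            class = "cat_result")
}
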