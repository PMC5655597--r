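test_that("category probabilities follow the three-branch logistic form", {
  bin <- item_parameters("b", 1, alpha = 1.3, betas = 0.65)
  expect_equal(category_probabilities(bin, 0.5), c(0.5, 0.5))

  sym <- item_parameters("s", 1, alpha = 1, betas = c(-1, 0, 1))
  p <- category_probabilities(sym, 0)
  expect_equal(p[1], p[4])
  expect_equal(p[2], p[3])
  expect_equal(sum(p), 1)
  # frozen: 1 - plogis(1) and plogis(1) - plogis(0)
  expect_equal(p[1], 0.268941421369995, tolerance = 1e-12)
  expect_equal(p[2], 0.231058578630005, tolerance = 1e-12)

  set.seed(11)
  for (k in 1:20) {
    it <- random_item(paste0("r", k), domain = 2L)
    th <- c(rnorm(1), rnorm(1))
    expect_equal(category_probabilities(it, th),
                 oracle_category_probs(it$alpha, it$betas, th[2]),
                 tolerance = 1e-12)
  }
})

test_that("probabilities are a proper simplex for random items and thetas", {
  set.seed(42)
  for (k in 1:1000) {
    it <- random_item("x")
    p <- category_probabilities(it, rnorm(1, 0, 2))
    expect_true(all(p > 0))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("item construction enforces the parameter invariants", {
  expect_error(item_parameters("x", 1, alpha = -1, betas = 0), "positive")
  expect_error(item_parameters("x", 1, alpha = 1, betas = c(0.5, 0.5)),
               "strictly increasing")
  expect_error(item_parameters("x", 1, alpha = 1, betas = numeric(0)),
               "categories")
  expect_error(item_parameters("x", 1, alpha = 1, betas = 1:5), "categories")
})

test_that("simulated responses reproduce the category distribution", {
  it <- item_parameters("s", 1, alpha = 2.1, betas = c(-1.2, 0.1, 0.9))
  p <- category_probabilities(it, 0.4)
  n <- 1e5
  set.seed(99)
  draws <- replicate(n, simulate_response(it, 0.4))
  freq <- tabulate(draws + 1L, nbins = 4) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < 3 * se))

  # degenerate distribution at extreme theta
  set.seed(1)
  expect_true(all(replicate(50, simulate_response(it, -30)) == 0L))

  set.seed(7); a <- replicate(20, simulate_response(it, 0.4))
  set.seed(7); b <- replicate(20, simulate_response(it, 0.4))
  expect_identical(a, b)
})

test_that("response log-likelihood matches the brute-force product", {
  bank <- toy_bank()
  one <- data.frame(item = "B2", category = 1L)
  expect_equal(response_log_likelihood(bank, one, c(0, 0.25)), log(0.5))
  expect_equal(response_log_likelihood(bank, NULL, c(0, 0)), 0)

  set.seed(5)
  for (k in 1:20) {
    nk <- sample(1:4, 1)
    idx <- sample(4, nk)
    cats <- vapply(idx, function(i)
      sample.int(bank$n_categories[i], 1) - 1L, 0L)
    adm <- data.frame(item = bank$item_id[idx], category = cats)
    th <- rnorm(2)
    brute <- sum(log(vapply(seq_len(nk), function(j)
      oracle_category_probs(bank$alpha[idx[j]], bank$betas[[idx[j]]],
                            th[bank$domain[idx[j]]])[cats[j] + 1L], 0)))
    expect_equal(response_log_likelihood(bank, adm, th), brute,
                 tolerance = 1e-10)
    # additivity over items
    parts <- vapply(seq_len(nk), function(j)
      response_log_likelihood(bank, adm[j, ], th), 0)
    expect_equal(sum(parts), response_log_likelihood(bank, adm, th))
  }
})

test_that("item information equals the expected negative Hessian", {
  set.seed(21)
  thetas <- seq(-2.5, 2.5, length.out = 10)
  for (k in 1:5) {
    it <- random_item(paste0("i", k), domain = 2L)
    for (t in thetas) {
      M <- item_information(it, c(0.3, t))
      expect_equal(M[2, 2], oracle_item_info_numeric(it$alpha, it$betas, t),
                   tolerance = 1e-4)
      expect_true(all(M[-2, ] == 0) && all(M[, -2] == 0))
      expect_gte(min(eigen(M, symmetric = TRUE)$values), -1e-10)
    }
  }
})

test_that("binary items reduce to the 2PL information", {
  set.seed(3)
  for (k in 1:10) {
    a <- runif(1, 0.8, 4); b <- rnorm(1); t <- rnorm(1)
    it <- item_parameters("b", 1, a, b)
    P <- plogis(a * t - b)
    expect_equal(item_information(it, t)[1, 1], a^2 * P * (1 - P),
                 tolerance = 1e-10)
  }
})
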