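test_that("determinant selection prefers the more informative item", {
  # same domain, same thresholds, strictly larger discrimination
  weak <- item_parameters("weak", 1, alpha = 1.0, betas = c(-0.5, 0.5))
  strong <- item_parameters("strong", 1, alpha = 2.5, betas = c(-0.5, 0.5))
  other <- item_parameters("other", 2, alpha = 0.9, betas = 0)
  bank <- item_bank(list(weak, strong, other), corr2())
  st <- posterior_state(bank, NULL)
  expect_identical(select_next_item(st, bank), "strong")
})

test_that("selection agrees with dense determinants on random states", {
  set.seed(61)
  bank <- random_bank(n = 20, D = 2)
  for (k in 1:50) {
    n_adm <- sample(0:6, 1)
    adm_idx <- if (n_adm) sample(20, n_adm) else integer(0)
    cats <- vapply(adm_idx, function(i)
      sample.int(bank$n_categories[i], 1) - 1L, integer(1))
    adm <- if (n_adm) data.frame(item = adm_idx, category = cats) else NULL
    st <- posterior_state(bank, adm)
    if (length(st$terminated_dims) == bank$n_dimensions) {
      expect_error(select_next_item(st, bank), class = "bank_exhausted")
      next
    }
    chosen <- select_next_item(st, bank)
    allowed <- oracle_select_dense(bank, adm_idx, st$terminated_dims,
                                   st$theta_hat)
    expect_true(match(chosen, bank$item_id) %in% allowed)
  }
})

test_that("items from terminated dimensions are never selected", {
  strong1 <- item_parameters("s1", 1, alpha = 5.0,
                             betas = c(-1.5, -0.5, 0.5, 1.5))
  strong2 <- item_parameters("s2", 1, alpha = 4.5,
                             betas = c(-1.2, 0, 1.2))
  weak2 <- item_parameters("w2", 2, alpha = 1.0, betas = 0.2)
  bank <- item_bank(list(strong1, strong2, weak2), corr2(0.3))
  st <- posterior_state(bank, data.frame(item = "s1", category = 2L),
                        se_threshold = 0.9)
  expect_true(1 %in% st$terminated_dims)   # dimension 1 already precise
  expect_identical(select_next_item(st, bank), "w2")
  # exhausting eligibility signals the caller
  st2 <- posterior_state(bank,
                         data.frame(item = c("s1", "w2"),
                                    category = c(2L, 0L)),
                         se_threshold = 0.9)
  expect_error(select_next_item(st2, bank), class = "bank_exhausted")
})

test_that("administering updates the state and forbids duplicates", {
  bank <- toy_bank()
  st0 <- posterior_state(bank, NULL)
  st1 <- administer_and_update(st0, bank, "A1", 2L)
  expect_length(st1$administered$item, 1)
  expect_error(administer_and_update(st1, bank, "A1", 1L),
               "already administered")
  st2 <- administer_and_update(st1, bank, "B1", 0L)
  # incremental updates equal the batch posterior
  batch <- posterior_state(bank, data.frame(item = c("A1", "B1"),
                                            category = c(2L, 0L)))
  # warm vs cold starts stop within the 1e-6 Newton tolerance of each other
  expect_equal(st2$theta_hat, batch$theta_hat, tolerance = 1e-5)
  expect_equal(st2$posterior_info, batch$posterior_info, tolerance = 1e-5)
  expect_equal(st2$se, batch$se, tolerance = 1e-5)
  # terminated set is definitional in the current SEs
  expect_identical(st2$terminated_dims, which(st2$se < st2$se_threshold))
})

test_that("run_cat respects length bounds, uniqueness and reproducibility", {
  set.seed(71)
  bank <- random_bank(n = 24, D = 2)
  cfg <- cat_config(se_threshold = 0.4, seed = 5)
  r1 <- run_cat(bank, c(0.5, -0.5), cfg)
  r2 <- run_cat(bank, c(0.5, -0.5), cfg)
  expect_identical(r1, r2)
  expect_false(anyDuplicated(r1$items) > 0)
  expect_gte(r1$test_length, 2)
  expect_lte(r1$test_length, 24)
  expect_identical(r1$test_length, length(r1$items))
  expect_identical(r1$converged, all(r1$se_final < 0.4))

  # every adaptive item's domain was unterminated when it was chosen
  for (k in 3:r1$test_length) {
    st <- posterior_state(bank, data.frame(item = r1$items[seq_len(k - 1)],
                                           category = r1$categories[seq_len(k - 1)]),
                          se_threshold = 0.4)
    d_k <- bank$domain[match(r1$items[k], bank$item_id)]
    expect_false(d_k %in% st$terminated_dims)
  }
})

test_that("an impossible threshold exhausts the bank", {
  set.seed(81)
  bank <- random_bank(n = 10, D = 2)
  r <- run_cat(bank, c(0, 0), cat_config(se_threshold = 1e-4, seed = 2))
  expect_identical(r$test_length, 10L)
  expect_setequal(r$items, bank$item_id)
  expect_false(r$converged)
})

test_that("a sufficiently informative start terminates at D items", {
  items <- list(
    item_parameters("p1", 1, alpha = 5.4, betas = c(-2, -0.7, 0.7, 2)),
    item_parameters("p2", 2, alpha = 5.4, betas = c(-2, -0.7, 0.7, 2)))
  bank <- item_bank(items, corr2())
  r <- run_cat(bank, c(0, 0), cat_config(se_threshold = 0.9, seed = 1))
  expect_identical(r$test_length, 2L)
  expect_true(r$converged)
})

test_that("max_length caps the test", {
  set.seed(91)
  bank <- random_bank(n = 12, D = 2)
  r <- run_cat(bank, c(0, 0),
               cat_config(se_threshold = 1e-4, max_length = 5L, seed = 3))
  expect_identical(r$test_length, 5L)
})
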