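# Four-item reference bank for the hand-enumerated usage examples.
usage_bank <- function() {
  item_bank(list(
    item_parameters("i1", 1, 1.5, c(-1, 0, 1)),
    item_parameters("i2", 1, 1.0, 0.5),
    item_parameters("i3", 2, 2.0, c(-0.5, 0.5)),
    item_parameters("i4", 2, 0.9, 0)),
    corr2(), c("gA", "gB"))
}

test_that("usage counting matches hand enumeration", {
  bank <- usage_bank()
  res <- list(fake_result(c("i1", "i2"), 0),
              fake_result(c("i1", "i3"), 0),
              fake_result(c("i1", "i2"), 0))
  tab <- compute_usage_rates(res, bank)
  expect_equal(as.numeric(tab$usage_rate), c(1, 2 / 3, 1 / 3, 0))
  expect_equal(tab$mean_test_length, 2)
  expect_equal(sum(tab$usage_rate[, 1]), tab$mean_test_length[1])

  tab <- classify_and_summarize(tab, bank)
  expect_equal(tab$expected_usage, 0.5)
  expect_identical(rownames(tab$counts)[tab$overused[, 1]], c("i1", "i2"))
  expect_identical(sum(tab$active[, 1]), 3L)
  tot <- subset(tab$summary, group == "Total")
  expect_equal(tot$active_pct, 75)
  expect_equal(tot$overused_pct, 50)
  expect_equal(tot$overlap_pct, 100 * 2 / 3)
  expect_equal(round_half_up(tot$overlap_pct), 67)
  # per-domain rows use the domain size as denominator
  gA <- subset(tab$summary, group == "gA")
  expect_equal(gA$active_pct, 100)   # both gA items used
  expect_equal(gA$overused_pct, 100)
})

test_that("degenerate usage tables behave", {
  bank <- usage_bank()
  empty <- compute_usage_rates(list(), bank)
  expect_identical(ncol(empty$counts), 0L)

  # every CAT administers the whole bank: nothing exceeds expectation
  res <- replicate(3, fake_result(bank$item_id, 1), simplify = FALSE)
  tab <- classify_and_summarize(compute_usage_rates(res, bank), bank)
  expect_equal(tab$expected_usage, 1)
  expect_identical(sum(tab$overused), 0L)
  tot <- subset(tab$summary, group == "Total")
  expect_equal(tot$active_pct, 100)
  expect_true(tab$summary$n_overused[1] <= tab$summary$n_active[1])

  expect_error(compute_usage_rates(list(fake_result("nope", 0)), bank),
               "not in bank")
  expect_error(accuracy_metrics(list()), "no results")
})

test_that("overused items are always a subset of active items", {
  set.seed(23)
  bank <- random_bank(n = 16, D = 2)
  study <- run_study(bank, study_design(-1, 1, 1, 6, seed = 2),
                     cat_config(se_threshold = 0.45))
  tab <- classify_and_summarize(compute_usage_rates(study, bank), bank)
  expect_true(all(tab$active[tab$overused]))
  for (gi in seq_along(tab$grid_values))
    expect_equal(sum(tab$usage_rate[, gi]), tab$mean_test_length[gi])
})

test_that("accuracy metrics recover trivial error structures", {
  res <- list(fake_result("i1", 0, true_theta = c(1, -1),
                          theta_final = c(1, -1)),
              fake_result("i1", 0, true_theta = c(0.5, 0),
                          theta_final = c(0.5, 0)))
  acc <- accuracy_metrics(res)
  expect_true(all(acc$bias == 0) && all(acc$rmse == 0))

  res2 <- lapply(res, function(r) {
    r$theta_final <- r$true_theta + c(0.1, 0); r
  })
  acc2 <- accuracy_metrics(res2)
  expect_equal(acc2$bias[acc2$dimension == 1], rep(0.1, 2))
  expect_equal(acc2$rmse[acc2$dimension == 1], rep(0.1, 2))
  expect_equal(acc2$bias[acc2$dimension == 2], rep(0, 2))
})

test_that("per-step parameter records are complete and deterministic", {
  bank <- usage_bank()
  res <- list(fake_result(c("i1", "i3"), 0))
  tab <- classify_and_summarize(compute_usage_rates(res, bank), bank)
  rep1 <- usage_vs_parameters_report(tab, bank)
  expect_identical(nrow(rep1), sum(bank$n_categories - 1L))
  expect_identical(rep1, usage_vs_parameters_report(tab, bank))
  expect_equal(unique(rep1$max_usage_rate[rep1$item_id == "i1"]), 1)
})

test_that("high-discrimination items dominate usage within a domain", {
  set.seed(29)
  items <- lapply(1:6, function(i)
    item_parameters(paste0("u", i), 1, alpha = c(0.9, 1.2, 1.6, 2.2, 3, 4)[i],
                    betas = c(-1, 0, 1)))
  bank <- item_bank(items, matrix(1, 1, 1), "one")
  study <- run_study(bank, study_design(0, 0, 0.2, 60, seed = 6),
                     cat_config(se_threshold = 0.45))
  tab <- classify_and_summarize(compute_usage_rates(study, bank), bank)
  rates <- tab$usage_rate[, 1]
  expect_gte(rates[["u6"]], 0.9 * max(rates))
})

test_that("random selection equalizes usage where adaptive selection does not", {
  set.seed(37)
  bank <- random_bank(n = 12, D = 2)
  n_sims <- 150
  fixed_len <- 5
  rand_counts <- integer(12)
  for (k in seq_len(n_sims)) {
    pick <- sample(12, fixed_len)
    rand_counts[pick] <- rand_counts[pick] + 1L
  }
  p_rand <- stats::chisq.test(rand_counts,
                              p = rep(1 / 12, 12))$p.value
  expect_gt(p_rand, 1e-3)

  study <- run_study(bank, study_design(0, 0, 0.2, 40, seed = 3),
                     cat_config(se_threshold = 0.45))
  adaptive <- rowSums(compute_usage_rates(study, bank)$counts)
  p_adapt <- suppressWarnings(
    stats::chisq.test(adaptive, p = rep(1 / 12, 12))$p.value)
  expect_lt(p_adapt, 1e-3)
})

test_that("tightening the SE threshold never shrinks the active bank", {
  set.seed(41)
  bank <- generate_item_bank(
    bank_recipe(domain_sizes = c(12, 12), correlation = corr2(0.7),
                category_profile = c(`5` = 24), seed = 8))
  design <- study_design(0, 0, 0.2, 25, seed = 11)
  act <- vapply(c(0.45, 0.316), function(thr) {
    study <- run_study(bank, design, cat_config(se_threshold = thr))
    tab <- classify_and_summarize(compute_usage_rates(study, bank), bank)
    sum(tab$active[, 1])
  }, 0L)
  expect_gte(act[2], act[1])
})
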