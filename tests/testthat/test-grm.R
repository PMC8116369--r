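test_that("category probabilities are a proper distribution at every node", {
  for (p in the_params) {
    pr <- grm_probability(the_grid$nodes, p)
    expect_true(all(pr >= 0))
    expect_lt(max(abs(rowSums(pr) - 1)), 1e-12)
  }
})

test_that("symmetric thresholds give symmetric extreme categories at theta = 0", {
  it <- item_parameters("sym", a = 2, b = c(-1.5, -0.5, 0.5, 1.5))
  pr <- grm_probability(0, it)
  expect_equal(unname(pr[, 1]), unname(pr[, 5]))
})

test_that("category probability matches direct formula evaluation", {
  it <- item_parameters("x", a = 1.5, b = c(-2, -1, 0, 1))
  # independent hand evaluation of the two logistic terms at theta = 0.5, k = 3:
  # 1/(1+exp(-1.5*(0.5 - (-1)))) - 1/(1+exp(-1.5*(0.5 - 0))) = 0.22547184
  expect_equal(unname(grm_probability(0.5, it, k = 3)), 0.22547184,
               tolerance = 1e-7)
  expect_error(grm_probability(0.5, it, k = 6), "category")
  expect_error(grm_probability(0.5, it, k = 0), "category")
})

test_that("the T metric is the affine map 50 + 10 theta", {
  expect_equal(to_tscore(0), 50)
  expect_equal(to_tscore(-0.53), 44.7)
  expect_equal(to_tscore(1), 60)
})

test_that("an all-missing pattern returns the prior, flagged", {
  pars <- the_params[gmh_items]
  res <- eap_score(rep(NA_integer_, 4), pars, the_grid)
  expect_lt(abs(res$theta_hat), 1e-3)
  expect_lt(abs(res$se_theta - 1), 1e-3)
  expect_equal(res$t_score, 50, tolerance = 1e-2)
  expect_equal(res$n_items_used, 0L)
  expect_true(res$all_missing)
})

test_that("pattern EAP agrees with a dense integration oracle, complete and incomplete", {
  pars <- the_params[gph_items]
  patterns <- list(c(3L, 4L, 2L, 3L), c(1L, 1L, 1L, 1L), c(5L, 5L, 5L, 5L),
                   c(5L, NA, 2L, NA), c(NA, NA, NA, 4L))
  for (pat in patterns) {
    got <- eap_score(pat, pars, the_grid)
    want <- dense_eap_oracle(pat, pars)
    expect_equal(got$theta_hat, want$theta, tolerance = 1e-6)
    expect_equal(got$se_theta, want$se, tolerance = 1e-6)
  }
})

test_that("better responses never give a lower trait estimate", {
  pars <- the_params[gmh_items]
  lo <- eap_score(c(1L, 1L, 1L, 1L), pars, the_grid)
  hi <- eap_score(c(5L, 5L, 5L, 5L), pars, the_grid)
  expect_gt(hi$theta_hat, lo$theta_hat)
})

test_that("estimates shrink: bounded trait and SE never above the prior SD", {
  pars <- the_params[gph_items]
  res <- score_responses(all_patterns_4x5, pars, the_grid)
  expect_true(all(abs(res$theta_hat) < max(abs(the_grid$nodes))))
  expect_true(all(res$se_theta <= 1 + 1e-3))
})

test_that("mismatched or out-of-range inputs are rejected", {
  pars <- the_params[gph_items]
  expect_error(eap_score(c(1L, 2L), pars, the_grid), "match")
  expect_error(eap_score(c(1L, 2L, 6L, 1L), pars, the_grid), "1..5")
})

test_that("summed-score table: base case equals the item's own curves", {
  p <- the_params["Global03"]
  tab <- summed_score_table(p, the_grid)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$sum_score, 1:5)
  L <- attr(tab, "likelihood")
  expect_equal(unname(L), unname(t(grm_probability(the_grid$nodes, p[[1]]))),
               tolerance = 1e-14)
})

test_that("summed-score T is non-decreasing and summed likelihoods stay normalized", {
  for (set in list(the_params[gmh_items], the_params[gph_items],
                   the_params[c("Global03", "Global06")])) {
    tab <- summed_score_table(set, the_grid)
    expect_equal(nrow(tab), length(set) * 4L + 1L)
    expect_true(all(diff(tab$t_score) >= 0))
    # sum over attainable sums of L_s(theta) is 1 at every node
    expect_lt(max(abs(colSums(attr(tab, "likelihood")) - 1)), 1e-12)
  }
  expect_error(summed_score_table(list()), "at least one")
})

test_that("pattern and sum-table scoring agree closely on realistic populations", {
  pop <- generate_population(synthetic_config(n = 1500, seed = 11))
  pat <- score_population(pop$records, the_params, the_instrument,
                          subscales = c("GMH", "GPH"), method = "pattern")
  sct <- score_population(pop$records, the_params, the_instrument,
                          subscales = c("GMH", "GPH"), method = "sum-table")
  d <- abs(pat$t_score - sct$t_score)
  expect_gt(stats::cor(pat$t_score, sct$t_score), 0.99)
  expect_gt(mean(d < 3), 0.95)
  expect_lt(stats::median(d), 1.5)
})

test_that("sum-table scoring refuses incomplete responses", {
  rec <- make_record(responses = c(2L, 3L, NA, 5L, 1L, 2L, 7L, 2L, 3L, 4L))
  expect_error(score_population(rec, the_params, the_instrument,
                                subscales = "GPH", method = "sum-table"),
               "complete")
})

test_that("conversion-table export round-trips through CSV", {
  tab <- summed_score_table(the_params[c("Global03", "Global06")], the_grid, "GPH-2a")
  f <- tempfile(fileext = ".csv")
  write_conversion_table(tab, f)
  back <- read.csv(f)
  expect_equal(back$raw_sum, tab$sum_score)
  expect_equal(back$t_score, round_half_up(tab$t_score, 1))
})
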