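test_that("generation is deterministic in the seed and leaves the RNG state alone", {
  cfg <- synthetic_config(n = 300, seed = 42)
  p1 <- generate_population(cfg)
  set.seed(777); before <- runif(1)
  set.seed(777)
  p2 <- generate_population(cfg)
  after <- runif(1)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$truth, p2$truth)
  expect_equal(before, after)  # caller's RNG stream not consumed
  p3 <- generate_population(synthetic_config(n = 300, seed = 43))
  expect_false(identical(p1$records, p3$records))
})

test_that("config validation catches broken settings", {
  st <- default_strata()
  st$proportion[1] <- st$proportion[1] + 0.1
  expect_error(synthetic_config(strata = st), "sum to 1")
  expect_error(synthetic_config(rho = 1), "rho")
  expect_error(synthetic_config(missing_rate = 1), "missing_rate")
  expect_error(synthetic_config(anchor_weight = 1.2), "anchor_weight")
  pars <- default_item_parameters()
  attr(pars, "trait") <- NULL
  expect_error(synthetic_config(params = pars), "trait")
})

test_that("records are valid instrument input and round-trip through CSV", {
  pop <- generate_population(synthetic_config(n = 150, seed = 9,
                                              missing_rate = 0.15))
  expect_silent(validate_responses(pop$records, the_instrument))
  expect_gt(mean(is.na(as.matrix(pop$records[, paste0("global", sprintf("%02d", 1:10))]))),
            0.05)
  f <- tempfile(fileext = ".csv")
  write_responses(pop$records, f)
  back <- read_responses(f, the_instrument)
  expect_equal(back, pop$records)
})

test_that("a centred population scores at the metric centre", {
  st <- default_strata()
  st$mu_gmh <- 0; st$mu_gph <- 0
  pop <- generate_population(synthetic_config(n = 5000, seed = 31, strata = st))
  sc <- score_population(pop$records, the_params, the_instrument,
                         subscales = c("GMH", "GPH"))
  means <- tapply(sc$t_score, sc$subscale, mean)
  expect_true(all(abs(means - 50) < 0.5))
})

test_that("empirical stratum proportions converge to the configured ones", {
  cfg <- synthetic_config(n = 5000, seed = 12)
  pop <- generate_population(cfg)
  emp <- table(factor(pop$truth$stratum,
                      levels = paste(cfg$strata$gender, cfg$strata$age_band)))
  gap <- 100 * abs(as.numeric(emp) / 5000 - cfg$strata$proportion)
  expect_lt(max(gap), 2)
})

test_that("implied category frequencies match simulation and collapse to point probabilities", {
  pars <- the_params[gph_items]
  impl <- implied_category_frequencies(pars, mean = -0.5, sd = 1)
  expect_equal(unname(rowSums(impl)), rep(100, 4), tolerance = 1e-9)
  # degenerate trait: frequencies approach the category probabilities at the mean
  impl0 <- implied_category_frequencies(pars, mean = 0.3, sd = 1e-6)
  point <- t(vapply(pars, function(p) grm_probability(0.3, p)[1, ], numeric(5)))
  expect_equal(unname(impl0 / 100), unname(point), tolerance = 1e-3)
  # Monte Carlo agreement within one percentage point
  set.seed(2024)
  theta <- stats::rnorm(50000, -0.5, 1)
  for (p in pars[1:2]) {
    pr <- grm_probability(theta, p)
    u <- stats::runif(length(theta))
    k <- rowSums(u > t(apply(pr, 1, cumsum))) + 1
    sim <- 100 * tabulate(k, p$K) / length(theta)
    expect_lt(max(abs(sim - impl[p$item_id, ])), 1)
  }
})

test_that("default strata mirror the published subgroup structure", {
  st <- default_strata()
  expect_equal(nrow(st), 12L)
  expect_equal(sum(st$proportion), 1, tolerance = 1e-12)
  expect_equal(sum(st$proportion[st$gender == "Male"]), 2069 / 4370,
               tolerance = 1e-9)
  # additive decomposition recovers the published total when aggregated
  tot_gmh <- 50 + 10 * sum(st$proportion * st$mu_gmh)
  expect_equal(tot_gmh, 44.7, tolerance = 0.15)
  w <- default_age_weights()
  expect_setequal(names(w), c("18-34", "35-44", "45-54", "55-64", "65-74", "75+"))
  for (b in names(w)) expect_equal(sum(w[[b]]$weight), 1)
  # calibrated split: implied coarse 18-39 share matches the published margin
  share_18_39 <- sum(st$proportion[st$age_band == "18-34"]) +
    sum(st$proportion[st$age_band == "35-44"]) *
      sum(w[["35-44"]]$weight[w[["35-44"]]$age < 40])
  expect_equal(100 * share_18_39, 33, tolerance = 0.2)
})

test_that("anchor item tracks the composite trait and fills all five groups", {
  pop <- generate_population(synthetic_config(n = 4370, seed = 1))
  anchor <- recode_responses(pop$records, the_instrument)[, "Global01"]
  expect_true(all(1:5 %in% anchor))
  expect_gt(stats::cor(anchor, pop$truth$theta_composite, method = "spearman"), 0.5)
})
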