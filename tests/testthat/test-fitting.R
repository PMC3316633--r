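test_that("negative log-likelihood matches the scalar oracle", {
  trials <- tiny_trials()
  for (par in list(c(0.02, 0, 0.5), c(0.05, 0.03, 0.2), c(0.1, -0.05, 1))) {
    p <- discount_params(par[1], par[2], par[3])
    expect_equal(negative_log_likelihood(p, trials, "priming"),
                 oracle_nll(par[1], par[2], par[3], trials), tolerance = 1e-10)
    expect_equal(negative_log_likelihood(p, trials, "baseline"),
                 oracle_nll(par[1], 0, par[3], trials), tolerance = 1e-10)
  }
  # coin-flip likelihood at the indifference point
  flat <- data.frame(trial_type = "TD", prime = "cup", amount = 106.40,
                     delay = 180, choice = rep(c("now", "later"), 108))
  expect_equal(negative_log_likelihood(discount_params(0.024, 0, 1e-3), flat),
               216 * log(2), tolerance = 1e-3)
  expect_error(negative_log_likelihood(default_params(),
                                       data.frame(trial_type = "PC", prime = "control",
                                                  amount = NA, delay = NA, choice = NA)),
               "no usable TD trials")
})

test_that("maximum-likelihood fits recover generating parameters", {
  n_rep <- 40
  k_hat <- a_hat <- w_hat <- numeric(n_rep)
  sch <- build_design()
  for (i in seq_len(n_rep)) {
    d <- simulate_choices(discount_params(0.024, 0.06, 0.3), sch, seed = 1000 + i)
    f <- fit_priming(d)
    expect_true(f$converged)
    k_hat[i] <- f$params$k; a_hat[i] <- f$params$a; w_hat[i] <- f$params$omega
  }
  expect_lt(abs(mean(k_hat) - 0.024), 0.1 * 0.024)
  expect_lt(abs(mean(a_hat) - 0.06), 0.025)
  expect_lt(abs(mean(w_hat) - 0.3), 0.06)
})

test_that("fit output satisfies the information-criterion identities", {
  d <- quick_dataset(3)
  for (f in list(fit_baseline(d), fit_priming(d))) {
    expect_equal(f$aic, 2 * f$n_params - 2 * f$log_lik)
    expect_equal(f$bic, f$n_params * log(f$n_trials) - 2 * f$log_lik)
    expect_lte(f$log_lik, 0)
    expect_true(all(is.finite(f$std_errors)))
  }
})

test_that("the priming model nests the baseline on every dataset", {
  for (s in 1:10) {
    d <- quick_dataset(s, a = if (s %% 2) 0 else 0.06)
    fb <- fit_baseline(d); fp <- fit_priming(d)
    expect_gte(fp$log_lik, fb$log_lik - 1e-8)
  }
})

test_that("estimates are invariant to trial order and run relabelling", {
  d <- quick_dataset(11)
  f1 <- fit_priming(d)
  d2 <- d[rev(seq_len(nrow(d))), ]
  f2 <- fit_priming(d2)
  d3 <- d; d3$run <- 7 - d3$run
  f3 <- fit_priming(d3)
  expect_equal(f1$params$a, f2$params$a, tolerance = 1e-8)
  expect_equal(f1$params$a, f3$params$a, tolerance = 1e-8)
  expect_equal(f1$log_lik, f2$log_lik, tolerance = 1e-8)
})

test_that("degenerate choice records raise a non-identifiability error", {
  d <- quick_dataset(5)
  d$choice[d$trial_type == "TD"] <- "later"
  expect_error(fit_baseline(d), "NonIdentifiable")
  d$choice[d$trial_type == "TD"] <- "now"
  expect_error(fit_priming(d), "NonIdentifiable")
  # missing one prime condition
  d2 <- quick_dataset(6)
  d2 <- d2[!(d2$trial_type == "TD" & d2$prime == "apple"), ]
  expect_error(fit_priming(d2), "both prime conditions")
})

test_that("model comparison computes the chi-square LR test", {
  d <- quick_dataset(2)
  fb <- fit_baseline(d); fp <- fit_priming(d)
  cmp <- compare_models(fb, fp)
  expect_equal(cmp$lr_statistic, 2 * (fp$log_lik - fb$log_lik))
  expect_equal(cmp$df, 1)
  expect_equal(cmp$p_value, pchisq(cmp$lr_statistic, 1, lower.tail = FALSE))
  expect_equal(cmp$delta_aic, fp$aic - fb$aic)
  # identical fits give LR 0, p 1
  cmp0 <- compare_models(fb, structure(c(fb[names(fb) != "n_params"],
                                         list(n_params = 3L)), class = "td_fit"))
  expect_equal(cmp0$lr_statistic, 0)
  expect_equal(cmp0$p_value, 1)
  # LR = 3.84 sits at the 5% point of chi-square(1)
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05, tolerance = 1e-6)
})

test_that("predicted choices break ties toward the immediate option", {
  d <- quick_dataset(4)
  f <- fit_priming(d)
  pred <- predict_choices(f, d)
  td <- pred$trial_type == "TD"
  expect_true(all(pred$predicted[td] == ifelse(pred$p_later[td] > 0.5, "later", "now")))
  # accuracy strictly between chance and perfection at moderate noise
  acc <- mean(pred$correct[td])
  expect_gt(acc, 0.5); expect_lt(acc, 1)
  # noise-free choices are predicted perfectly by the generating model
  sch <- build_design()
  dn <- simulate_choices(discount_params(0.024, 0.05, 9.99), sch, seed = 12)
  fn <- list(params = discount_params(0.024, 0.05, 9.99), model = "priming")
  class(fn) <- "td_fit"
  predn <- predict_choices(fn, dn)
  expect_gt(mean(predn$correct[predn$trial_type == "TD"]), 0.99)
})

test_that("group premium inference detects a positive population premium", {
  set.seed(21)
  datasets <- lapply(1:13, function(j) {
    k <- max(0.004, rnorm(1, 0.024, 0.018))
    a <- rnorm(1, 0.06, 0.05)
    while (k + a <= 0) a <- rnorm(1, 0.06, 0.05)
    w <- max(0.08, rnorm(1, 0.3, 0.1))
    sch <- build_design(design_config(seed = 300 + j), k_pretest = k)
    simulate_choices(discount_params(k, a, w), sch, seed = 400 + j)
  })
  g <- group_premium_test(datasets)
  expect_length(g$a_hat, 13)
  expect_lt(g$pooled$p_value, 0.001)
  expect_gt(g$pooled$a, 0)
  expect_lt(g$t_test$p.value, 0.05)
  expect_error(group_premium_test(datasets[1:2]), "at least 3")
})

test_that("pooled premium recovers a common generating value", {
  set.seed(31)
  datasets <- lapply(1:8, function(j) {
    sch <- build_design(design_config(seed = 500 + j))
    simulate_choices(discount_params(0.024, 0.06, 0.3), sch, seed = 600 + j)
  })
  g <- group_premium_test(datasets)
  expect_lt(abs(g$pooled$a - 0.06), 0.02)
})
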