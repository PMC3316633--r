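test_that("subjective value follows the hyperbolic form", {
  expect_equal(subjective_value(50, 0, 0.024), 50)     # zero delay
  expect_equal(subjective_value(50, 10, 0), 50)        # zero discounting
  expect_equal(subjective_value(106.40, 180, 0.024), 20)
  # homogeneous of degree 1 in amount
  for (c_scale in c(0.5, 2, 7.3)) {
    expect_equal(subjective_value(c_scale * 80, 90, 0.05),
                 c_scale * subjective_value(80, 90, 0.05))
  }
  # monotone non-increasing in delay and k
  d <- subjective_value(100, c(0, 1, 10, 100), 0.1)
  expect_true(all(diff(d) < 0))
  expect_error(subjective_value(-5, 1, 0.1), "positive")
  expect_error(subjective_value(5, -1, 0.1), "non-negative")
})

test_that("primed subjective value applies the premium only on apple trials", {
  expect_equal(primed_subjective_value(106.40, 180, 0.024, 0.06, FALSE), 20)
  expect_equal(primed_subjective_value(106.40, 180, 0.024, 0, TRUE), 20)
  expect_equal(primed_subjective_value(106.40, 180, 0.024, 0.06, TRUE),
               106.40 / (1 + 0.084 * 180))
  expect_error(primed_subjective_value(50, 10, 0.01, -0.05, TRUE), "non-negative")
})

test_that("choice probability is the logistic of the value difference", {
  expect_equal(choice_probability(20, 0.7), 0.5)
  expect_equal(choice_probability(25, 0.2), 1 / (1 + exp(-1)))
  expect_gt(choice_probability(25, 100), 1 - 1e-10)    # deterministic limit
  expect_true(all(diff(choice_probability(c(10, 19, 20, 30), 0.3)) > 0))
  expect_error(choice_probability(25, -1), "positive")
})

test_that("indifference amount inverts the value function at P = 0.5", {
  expect_equal(indifference_amount(0, 0.5), 20)
  expect_equal(indifference_amount(180, 0.024), 106.40)
  expect_equal(indifference_amount(1, 0), 20)
  for (i in 1:20) {
    D <- 200 * i / 20; k <- 0.002 * i; w <- 0.05 * i
    sv <- subjective_value(indifference_amount(D, k), D, k)
    expect_equal(choice_probability(sv, w), 0.5)
  }
})

test_that("difficulty index is bounded, even, maximal at zero distance", {
  expect_equal(difficulty_index(0, 0.3), 1)
  expect_lt(difficulty_index(1000, 0.3), 1e-10)
  # P = 0.75 corresponds to gamma = 0.5
  delta_75 <- stats::qlogis(0.75) / 0.3
  expect_equal(difficulty_index(delta_75, 0.3), 0.5)
  dl <- seq(0.5, 30, length.out = 15)
  expect_equal(difficulty_index(dl, 0.4), difficulty_index(-dl, 0.4))
  expect_true(all(diff(difficulty_index(dl, 0.4)) < 0))
})

test_that("median split labels hard strictly above the median", {
  expect_equal(label_difficulty(c(0.1, 0.5, 0.9)), c(FALSE, FALSE, TRUE))
  expect_false(any(label_difficulty(rep(0.4, 6))))     # ties are easy
  expect_error(label_difficulty(0.5), "at least 2")
  # near 50/50 split on continuous values
  g <- stats::runif(216)
  expect_equal(sum(label_difficulty(g)), 108)
})

test_that("per-trial derived quantities match the formula transcription", {
  p <- default_params()
  trials <- tiny_trials()
  der <- derive_trial_values(trials, p)
  for (i in seq_len(nrow(trials))) {
    apple <- trials$prime[i] == "apple"
    sv <- oracle_sv(trials$amount[i], trials$delay[i], p$k)
    svs <- oracle_sv_star(trials$amount[i], trials$delay[i], p$k, p$a, apple)
    expect_equal(der$sv[i], sv, tolerance = 1e-12)
    expect_equal(der$sv_star[i], svs, tolerance = 1e-12)
    expect_equal(der$pi[i], svs - sv, tolerance = 1e-12)
    expect_equal(der$sigma[i], p$a * svs, tolerance = 1e-12)
    expect_equal(der$gamma[i], oracle_gamma(sv - 20, p$omega), tolerance = 1e-12)
  }
  # premium is exactly zero on cup trials, negative on apple (a > 0, D > 0)
  expect_true(all(der$pi[der$prime == "cup"] == 0))
  expect_true(all(der$pi[der$prime == "apple"] < 0))
  # sigma_on_cup switch zeroes the interaction on cup trials
  der0 <- derive_trial_values(trials, p, sigma_on_cup = FALSE)
  expect_true(all(der0$sigma[der0$prime == "cup"] == 0))
  expect_equal(der0$sigma[der0$prime == "apple"], der$sigma[der$prime == "apple"])
})

test_that("all scalar operations agree with the oracle at random points", {
  set.seed(91)
  for (i in 1:1000) {
    R <- stats::runif(1, 20.1, 400); D <- stats::runif(1, 0, 200)
    k <- stats::runif(1, 0, 0.5); a <- stats::runif(1, -k, 0.5)
    w <- stats::runif(1, 0.01, 5)
    expect_equal(subjective_value(R, D, k), oracle_sv(R, D, k), tolerance = 1e-12)
    expect_equal(primed_subjective_value(R, D, k, a, TRUE),
                 oracle_sv_star(R, D, k, a, TRUE), tolerance = 1e-12)
    sv <- oracle_sv(R, D, k)
    expect_equal(choice_probability(sv, w), oracle_p_later(sv, w), tolerance = 1e-12)
    expect_equal(difficulty_index(sv - 20, w), oracle_gamma(sv - 20, w),
                 tolerance = 1e-12)
  }
})

test_that("a positive premium always shifts choice toward the immediate option", {
  set.seed(17)
  for (i in 1:200) {
    R <- stats::runif(1, 21, 300); D <- stats::runif(1, 0.5, 180)
    k <- stats::runif(1, 0.001, 0.3); a <- stats::runif(1, 0.001, 0.3)
    w <- stats::runif(1, 0.05, 2)
    sv <- subjective_value(R, D, k)
    svs <- primed_subjective_value(R, D, k, a, TRUE)
    expect_lt(svs, sv)
    # strictly lower choice probability wherever the logistic is not
    # saturated at double precision
    p_star <- choice_probability(svs, w); p0 <- choice_probability(sv, w)
    expect_lte(p_star, p0)
    if (p0 < 1 - 1e-12 && p_star > 1e-12) expect_lt(p_star, p0)
  }
})
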