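test_that("haemodynamic kernel peaks at 6 s with unit height", {
  h <- hrf_kernel(100)
  t <- seq(0, 32, by = 0.1)
  expect_equal(t[which.max(h)], 6, tolerance = 0.11)
  expect_equal(max(h), 1)
  expect_gt(sum(h), 0)
  expect_identical(hrf_kernel(500), hrf_kernel(500))
  expect_error(hrf_kernel(-1), "positive")
})

make_subject <- function(seed, regions = list(), a = 0.06, noise_sd = 1) {
  p <- discount_params(0.024, a, 0.3)
  sch <- build_design(design_config(seed = seed))
  d <- simulate_choices(p, sch, seed = seed + 1000)
  spec <- tiny_bold_spec(regions = regions, noise_sd = noise_sd)
  list(bold = simulate_bold(d, p, spec, seed = seed + 2000), data = d,
       params = p, spec = spec)
}

test_that("interaction design orthogonalizes the modulators serially", {
  s <- make_subject(41)
  des <- build_interaction_design(s$data, s$params, s$spec)
  expect_setequal(colnames(des$runs[[1]])[1:5],
                  c("apple", "cup", "control", "sv", "sigma"))
  for (X in des$runs) {
    expect_lt(abs(sum(X[, "sigma"] * X[, "sv"])), 1e-8)
    expect_lt(abs(sum(X[, "sigma"] * X[, "apple"])), 1e-8)
    expect_lt(abs(sum(X[, "sv"] * X[, "cup"])), 1e-8)
    expect_false(any(apply(X, 2, function(cl) all(cl == 0))))
  }
  # reversed order attributes shared variance to sigma instead
  desr <- build_interaction_design(s$data, s$params, s$spec, reverse_order = TRUE)
  Xr <- desr$runs[[1]]
  expect_lt(abs(sum(Xr[, "sv"] * Xr[, "sigma"])), 1e-8)
  # a = 0 degenerates the interaction modulator, which is dropped
  expect_warning(d0 <- build_interaction_design(
    s$data, discount_params(0.024, 0, 0.3), s$spec), "identically zero")
  expect_false("sigma" %in% d0$columns)
})

test_that("premium design carries the premium on apple trials only", {
  s <- make_subject(43)
  des <- build_premium_design(s$data, s$params, s$spec)
  expect_true(all(c("sv", "pi") %in% des$columns))
  # cup trials contribute zero: rebuilding with cup premiums zeroed changes nothing
  der <- derive_trial_values(s$data, s$params)
  expect_true(all(der$pi[der$prime == "cup"] == 0))
  # restriction to correctly predicted trials with a near-noise-free fit
  fit <- fit_priming(s$data)
  desr <- build_premium_design(s$data, s$params, s$spec, correct_only = TRUE,
                               fit = fit)
  expect_true(all(c("sv", "pi") %in% desr$columns))
  expect_error(build_premium_design(s$data, s$params, s$spec, correct_only = TRUE),
               "requires a fitted model")
})

test_that("OLS recovers planted parametric amplitudes without noise", {
  s <- make_subject(45, regions = list(val = region_box(3:6, 3:6, 3:5, "sv_parametric")),
                    noise_sd = 0)
  s$bold$spec$drift_amplitude <- 0
  des <- build_interaction_design(s$data, s$params, s$spec)
  fit <- fit_glm(s$bold, des)
  sv_map <- contrast_map(fit, c(sv = 1))
  idx <- s$bold$truth$val$index
  # planted region carries the parametric scale, elsewhere ~0
  expect_gt(min(sv_map[idx]), 0.5 * s$spec$parametric_scale)
  expect_lt(max(abs(sv_map[-idx])), 0.2 * s$spec$parametric_scale)
  expect_error(contrast_map(fit, c(nonexistent = 1)), "unknown design columns")
})

test_that("premium contrast recovers a planted premium region", {
  s <- make_subject(46, regions = list(prem = region_box(3:6, 3:6, 3:5,
                                                         "premium_parametric")),
                    noise_sd = 0)
  des <- build_premium_design(s$data, s$params, s$spec)
  fit <- fit_glm(s$bold, des)
  pi_map <- contrast_map(fit, c(pi = 1))
  idx <- s$bold$truth$prem$index
  expect_gt(mean(pi_map[idx]), 5 * mean(abs(pi_map[-idx])))
})

test_that("duplicated design columns raise a rank error naming them", {
  s <- make_subject(47)
  des <- build_interaction_design(s$data, s$params, s$spec)
  des$runs <- lapply(des$runs, function(X) {
    X2 <- cbind(X, dup = X[, "sv"]); X2
  })
  des$columns <- c(des$columns, "dup")
  expect_error(fit_glm(s$bold, des), "rank-deficient")
})

test_that("pure-noise data yield calibrated t statistics", {
  s <- make_subject(49)
  s$bold$spec$td_amplitude <- 0
  des <- build_interaction_design(s$data, s$params, s$spec)
  b <- simulate_bold(s$data, s$params, tiny_bold_spec(td_amplitude = 0,
                                                      pc_amplitude = 0),
                     seed = 50)
  fit <- fit_glm(b, des)
  m <- contrast_map(fit, c(sv = 1))
  expect_lt(abs(mean(m)), 0.01)
})

test_that("cluster labelling agrees with a brute-force flood fill", {
  oracle_label <- function(supra) {
    dims <- dim(supra); labels <- array(0L, dims); cur <- 0L
    idx_all <- which(supra)
    for (start in idx_all) {
      if (labels[start] > 0) next
      cur <- cur + 1L; queue <- start
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (labels[v] > 0) next
        labels[v] <- cur
        co <- arrayInd(v, dims)
        for (dd in 1:3) for (s in c(-1L, 1L)) {
          nb <- co; nb[dd] <- nb[dd] + s
          if (all(nb >= 1) && all(nb <= dims)) {
            w <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
            if (supra[w] && labels[w] == 0) queue <- c(queue, w)
          }
        }
      }
    }
    labels
  }
  set.seed(61)
  for (i in 1:5) {
    supra <- array(stats::runif(6 * 5 * 4) < 0.35, c(6, 5, 4))
    got <- array(tdprime:::label_clusters(supra), dim(supra))
    want <- oracle_label(supra)
    # same partition (label ids may differ)
    expect_equal(got > 0, want > 0)
    expect_equal(length(unique(got[got > 0])), length(unique(want[want > 0])))
    tab_got <- sort(table(got[got > 0]))
    tab_want <- sort(table(want[want > 0]))
    expect_equal(as.integer(tab_got), as.integer(tab_want))
    expect_equal(tdprime:::max_cluster_size(supra),
                 if (any(want > 0)) max(table(want[want > 0])) else 0)
  }
})

test_that("sign-flip cluster inference controls the family-wise error", {
  set.seed(71)
  n_exp <- 30
  fp <- 0
  for (e in seq_len(n_exp)) {
    maps <- lapply(1:6, function(i) {
      gaussian_smooth(array(stats::rnorm(12 * 12 * 8), c(12, 12, 8)), 8, 4)
    })
    res <- group_cluster_fwe(maps, n_perm = 199, seed = e)
    fp <- fp + (nrow(res$significant) > 0)
  }
  expect_lte(fp / n_exp, 0.2)   # nominal 5%, wide Monte-Carlo band
  # a strong planted effect is detected at the planted location
  maps2 <- lapply(1:6, function(i) {
    m <- array(stats::rnorm(12 * 12 * 8), c(12, 12, 8))
    m[4:7, 4:7, 3:5] <- m[4:7, 4:7, 3:5] + 3
    gaussian_smooth(m, 8, 4)
  })
  res2 <- group_cluster_fwe(maps2, n_perm = 199, seed = 99)
  expect_gt(nrow(res2$significant), 0)
  pk <- res2$significant[1, ]
  expect_true(pk$peak_x %in% 3:8 && pk$peak_y %in% 3:8)
  # threshold above the global max gives no clusters
  res3 <- group_cluster_fwe(maps2, z_thresh = 1e6, n_perm = 199, seed = 1)
  expect_equal(nrow(res3$clusters), 0)
  expect_error(group_cluster_fwe(maps2, n_perm = 50), "at least 100")
  expect_error(group_cluster_fwe(maps2[1:3]), "at least 5")
})

test_that("gaussian smoothing preserves constants and reduces variance", {
  a <- array(stats::rnorm(10 * 10 * 6), c(10, 10, 6))
  sm <- gaussian_smooth(a, 8, 4)
  expect_lt(sd(sm), sd(a))
  expect_equal(gaussian_smooth(array(2, c(4, 4, 4)), 8, 4), array(2, c(4, 4, 4)))
  expect_identical(gaussian_smooth(a, 0, 4), a)
})
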