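test_that("sphere offsets enumerate the lattice ball", {
  # independent enumeration oracle over a bounding cube
  oracle_count <- function(r) {
    n <- 0L
    for (x in -r:r) for (y in -r:r) for (z in -r:r)
      if (x^2 + y^2 + z^2 <= r^2) n <- n + 1L
    n
  }
  for (r in 1:4) expect_equal(nrow(sphere_offsets(r)), oracle_count(r))
  expect_equal(nrow(sphere_offsets(1)), 7)
  expect_equal(nrow(sphere_offsets(2)), 33)
  expect_equal(nrow(sphere_offsets(3)), 123)
  expect_true(any(apply(sphere_offsets(2) == 0, 1, all)))  # centre included
  expect_error(sphere_offsets(0), "at least 1")
})

test_that("compiled SVM agrees with the libsvm reference", {
  skip_if_not_installed("e1071")
  set.seed(81)
  for (i in 1:60) {
    d <- sample(3:30, 1)
    X <- matrix(stats::rnorm(10 * d), 10, d)
    y <- rep(c(1L, -1L), 5)
    X[y == 1, 1] <- X[y == 1, 1] + stats::runif(1, 0, 2)
    Xt <- matrix(stats::rnorm(8 * d), 8, d)
    ours <- tdprime:::.svm_smo_decision(X, y, Xt, 1.0)
    m <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
    pr <- predict(m, Xt, decision.values = TRUE)
    ref <- attr(pr, "decision.values")[, 1]
    if (colnames(attr(pr, "decision.values")) == "-1/1") ref <- -ref
    expect_equal(sign(ours), unname(sign(ref)))
    expect_gt(stats::cor(ours, ref), 0.999)
  }
})

fir_subject <- function(seed, regions = list(), labels = NULL) {
  p <- default_params()
  sch <- build_design(design_config(seed = seed))
  d <- simulate_choices(p, sch, seed = seed + 1)
  b <- simulate_bold(d, p, tiny_bold_spec(regions = regions), seed = seed + 2)
  if (is.null(labels)) labels <- ifelse(d$trial_type == "TD", d$prime, NA)
  list(fir = fit_fir(b, d, labels), bold = b, data = d, params = p)
}

test_that("FIR bookkeeping matches the decoding design", {
  s <- fir_subject(201)
  expect_equal(dim(s$fir$estimates)[2:3], c(2, 6))   # 2 classes x 6 bins
  expect_equal(prod(dim(s$fir$estimates)[2:3]), 12)  # condition regressors/run
  expect_equal(s$fir$runs_used, 1:6)
  expect_equal(s$fir$classes, c("apple", "cup"))
})

test_that("noiseless FIR recovers planted stick amplitudes", {
  p <- default_params()
  sch <- build_design(design_config(seed = 203))
  d <- simulate_choices(p, sch, seed = 204)
  spec <- tiny_bold_spec(noise_sd = 0, drift_amplitude = 0, td_amplitude = 0,
                         pc_amplitude = 0,
                         regions = list(roi = region_box(3:5, 3:5, 3:4, "prime_pattern")))
  b <- simulate_bold(d, p, spec, seed = 205)
  fir <- fit_fir(b, d, ifelse(d$trial_type == "TD", d$prime, NA))
  idx <- b$truth$roi$index
  pat <- b$truth$roi$pattern
  # at late bins, class difference across region voxels is proportional to
  # the planted pattern difference
  diff_est <- fir$estimates[idx, 1, 5, 3] - fir$estimates[idx, 2, 5, 3]
  expect_gt(abs(stats::cor(diff_est, pat[, 1] - pat[, 2])), 0.999)
  # voxels outside any region carry no class difference
  out <- setdiff(seq_len(prod(spec$grid)), idx)[1:50]
  expect_lt(max(abs(fir$estimates[out, 1, 5, 3] - fir$estimates[out, 2, 5, 3])),
            1e-8)
})

test_that("unbalanced runs trigger the exclusion rules", {
  p <- default_params()
  sch <- build_design(design_config(seed = 206))
  d <- simulate_choices(p, sch, seed = 207)
  b <- simulate_bold(d, p, tiny_bold_spec(), seed = 208)
  labels <- ifelse(d$trial_type == "TD", d$prime, NA)
  # starve one run below the per-class minimum: run is dropped
  lab2 <- labels
  lab2[d$run == 3 & d$prime == "apple"] <- NA
  fir <- fit_fir(b, d, lab2)
  expect_equal(fir$runs_used, c(1, 2, 4, 5, 6))
  # starve four runs: subject excluded
  lab3 <- labels
  lab3[d$run %in% 1:4 & d$prime == "apple"] <- NA
  expect_error(fit_fir(b, d, lab3), class = "td_subject_excluded")
  expect_error(fit_fir(b, d, rep("apple", nrow(d))), "exactly two classes")
})

test_that("searchlight accuracy is bounded, symmetric under label swap", {
  s <- fir_subject(209, regions = list(roi = region_box(3:6, 3:6, 3:5, "prime_pattern")))
  am <- searchlight_decode(s$fir, radius = 2)
  acc <- am$accuracy
  expect_true(all(acc >= 0 & acc <= 1, na.rm = TRUE))
  expect_equal(am$chance, 0.5)
  expect_equal(am$n_folds, 6)
  # swapping the class order leaves accuracies unchanged
  fir_sw <- s$fir
  fir_sw$estimates <- fir_sw$estimates[, 2:1, , , drop = FALSE]
  fir_sw$classes <- rev(fir_sw$classes)
  am_sw <- searchlight_decode(fir_sw, radius = 2)
  expect_equal(am_sw$accuracy, acc)
  # planted region decodes above chance; map respects the mask
  idx <- s$bold$truth$roi$index
  expect_gt(mean(acc[idx]), 0.8)
  mask <- array(TRUE, dim(acc)); mask[1, 1, 1] <- FALSE
  am_m <- searchlight_decode(s$fir, radius = 2, mask = mask)
  expect_true(is.na(am_m$accuracy[1, 1, 1]))
})

test_that("radius-2 replication also recovers the planted region", {
  s <- fir_subject(212, regions = list(roi = region_box(4:7, 4:7, 3:5, "prime_pattern")))
  for (r in c(2, 3)) {
    am <- searchlight_decode(s$fir, radius = r)
    expect_gt(mean(am$accuracy[s$bold$truth$roi$index]), 0.75)
  }
  # concatenating bins is an accepted variant
  amc <- searchlight_decode(s$fir, combine = "concatenate")
  expect_gt(mean(amc$accuracy[s$bold$truth$roi$index]), 0.75)
})

test_that("early time bins carry no decision-related information", {
  s <- fir_subject(215, regions = list(roi = region_box(4:7, 4:7, 3:5, "prime_pattern")))
  idx <- s$bold$truth$roi$index
  late <- searchlight_decode(s$fir, bins = c(5, 6))
  early <- searchlight_decode(s$fir, bins = c(1, 2))
  expect_gt(mean(late$accuracy[idx]), 0.75)
  expect_lt(mean(early$accuracy[idx]), 0.65)
})

test_that("group accuracy inference flags planted above-chance decoding", {
  maps <- lapply(1:6, function(i) {
    s <- fir_subject(300 + 10 * i,
                     regions = list(roi = region_box(3:6, 3:6, 3:5, "prime_pattern")))
    searchlight_decode(s$fir, radius = 2)
  })
  res <- group_accuracy_inference(maps, n_perm = 199, seed = 5)
  expect_gt(nrow(res$significant), 0)
  pk <- res$significant[1, ]
  expect_true(pk$peak_x %in% 2:7 && pk$peak_y %in% 2:7)
})

test_that("within-condition difficulty decoding recovers a shared region", {
  p <- default_params()
  sch <- build_design(design_config(seed = 221))
  d <- simulate_choices(p, sch, seed = 222)
  spec <- tiny_bold_spec(regions = list(roi = region_box(3:6, 3:6, 3:5,
                                                         "difficulty_pattern")))
  b <- simulate_bold(d, p, spec, seed = 223)
  res <- within_condition_difficulty_decode(b, d, p, radius = 2, min_trials = 2)
  idx <- b$truth$roi$index
  expect_gt(mean(res$apple$accuracy[idx]), 0.6)
  expect_gt(mean(res$cup$accuracy[idx]), 0.6)
})
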