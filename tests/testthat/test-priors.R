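# Attribution machinery: expected gradients, the exact-Shapley oracle,
# class-prior assembly, scaling and resampling.

test_that("expected gradients recover the closed form for linear scorers", {
  set.seed(1)
  w <- rnorm(12)
  grad_fn <- function(z) w
  x <- runif(12)
  # single zero background: attribution is exactly w * x for any draw count
  eg <- expected_gradients(grad_fn, x, list(rep(0, 12)), n_draws = 3, seed = 5)
  expect_equal(eg, w * x, tolerance = 1e-12)
  # input equal to its only background: zero attribution
  eg0 <- expected_gradients(grad_fn, x, list(x), n_draws = 3, seed = 5)
  expect_equal(eg0, rep(0, 12), tolerance = 1e-12)
})

test_that("exact Shapley values satisfy the additivity, symmetry and efficiency axioms", {
  groups <- lapply(1:5, function(g) g)
  # additive score: each group's value is its own term
  coefs <- c(2, -1, 0.5, 3, -0.25)
  score <- function(z) sum(coefs * z)
  x <- c(1, 2, 3, 4, 5); base <- rep(0, 5)
  phi <- exact_shapley(score, x, base, groups)
  expect_equal(phi, coefs * x, tolerance = 1e-12)
  # symmetry: interchangeable groups with equal values get equal attributions
  score_sym <- function(z) (z[1] + z[2])^2 + z[3]
  phi_sym <- exact_shapley(score_sym, c(2, 2, 1), rep(0, 3),
                           lapply(1:3, function(g) g))
  expect_equal(phi_sym[1], phi_sym[2], tolerance = 1e-12)
  # efficiency on random nonlinear scorers with grouped features
  for (rep in 1:10) {
    sc <- make_toy_scorer(10, seed = rep)
    x <- withr::with_seed(100 + rep, runif(10))
    b <- withr::with_seed(200 + rep, runif(10) * 0.2)
    grp <- split(1:10, rep(1:5, each = 2))
    phi <- exact_shapley(sc$score, x, b, grp)
    expect_equal(sum(phi), sc$score(x) - sc$score(b), tolerance = 1e-9)
  }
  expect_error(exact_shapley(function(z) sum(z), 1:20, rep(0, 20),
                             as.list(1:20)), "limit")
})

test_that("expected gradients agree with exact Shapley on an 8-voxel multilinear scorer", {
  sc <- make_multilinear_scorer(8, seed = 3)
  x <- withr::with_seed(11, runif(8))
  b <- rep(0, 8)
  phi <- exact_shapley(sc$score, x, b, as.list(1:8))
  eg <- expected_gradients(sc$grad, x, list(b), n_draws = 4000, seed = 17)
  expect_equal(eg, phi, tolerance = 0.01)
  # Monte-Carlo error of the efficiency identity shrinks with the draw count
  target <- sc$score(x) - sc$score(b)
  rmse <- vapply(c(25L, 400L, 6400L), function(nd) {
    errs <- vapply(1:5, function(s)
      sum(expected_gradients(sc$grad, x, list(b), nd, seed = s)) - target,
      numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[3], 0.01)
})

test_that("model attribution is seeded per subject and zero on self-background", {
  m <- tiny_model(shape = c(8, 8, 8), ds = 2, seed = 6)
  vol <- random_volume(seed = 20)
  cfg <- attribution_config(n_draws = 4, seed = 9)
  bg <- list(random_volume(seed = 21))
  a1 <- attribute(m, vol, 2L, bg, cfg)
  a2 <- attribute(m, vol, 2L, bg, cfg)
  expect_identical(a1, a2)
  expect_equal(dim(a1), c(8L, 8L, 8L))
  self <- attribute(m, vol, 1L, list(vol), cfg)
  expect_equal(self, array(0, dim = c(8, 8, 8)), tolerance = 1e-12)
  expect_error(attribute(m, vol, 5L, bg, cfg), "range")
})

test_that("class priors average attributions over correct predictions only", {
  coh <- separable_cohort(n = 6)
  tc <- train_config(lambda = 0, epochs = 30, micro_batch = 6, lr = 0.01, seed = 5)
  mc <- model_config(c(16, 16, 16), encoder_channels = 6,
                     downsample_factor = 2, seed = 8)
  fit <- cached("prior_fit", train_stage1(coh$samples, coh$samples, mc, tc))
  ev <- evaluate_model(fit$model, coh$samples)
  expect_equal(ev$accuracy, 1)
  cfg <- attribution_config(n_background = 3, n_draws = 4, seed = 77)
  priors <- build_class_priors(fit$model, coh$samples, cfg)
  expect_length(priors, 3)
  expect_equal(vapply(priors, function(p) p$n_samples_averaged, integer(1)),
               rep(6L, 3))
  # oracle: recompute the class-2 average externally with the same background
  labels <- cohort_labels(coh)
  nc_idx <- which(labels == 0)
  bg_idx <- sort(withr::with_seed(77, sample(nc_idx, 3)))
  bgs <- lapply(coh$samples[bg_idx], function(s) s$volume)
  idx2 <- which(labels == 2)
  manual <- Reduce(`+`, lapply(coh$samples[idx2], function(s)
    attribute(fit$model, s, 2L, bgs, cfg))) / length(idx2)
  expect_equal(priors[[3]]$grid, manual, tolerance = 1e-12)
  # permutation invariance of the averages
  perm <- withr::with_seed(5, sample(length(coh$samples)))
  priors_p <- build_class_priors(fit$model, coh$samples[perm], cfg)
  for (k in 1:3) expect_equal(priors_p[[k]]$grid, priors[[k]]$grid,
                              tolerance = 1e-12)
})

test_that("classes without correct predictions yield absent-prior markers", {
  coh <- separable_cohort(n = 4)
  m <- tiny_model(shape = c(16, 16, 16), channels = 6, ds = 2, seed = 1)
  # this untrained model predicts a single class, so the others get no
  # correct predictions
  pred <- apply(predict_classes(m, lapply(coh$samples, function(s) s$volume)),
                1, which.max) - 1L
  expect_lt(length(unique(pred)), 3)
  cfg <- attribution_config(n_background = 2, n_draws = 2, seed = 3)
  priors <- build_class_priors(m, coh$samples, cfg)
  absent <- vapply(priors, function(p) p$absent, logical(1))
  expect_true(any(absent))
  expect_true(all(vapply(priors[absent], function(p) is.null(p$grid), logical(1))))
  expect_error(train_stage2(coh$samples, coh$samples, priors,
                            model_config(c(16, 16, 16), encoder_channels = 6,
                                         downsample_factor = 2, seed = 2),
                            train_config(lambda = 1e-3, epochs = 1)),
               "absent")
})

test_that("unit scaling preserves sign, zeros and rank order of magnitudes", {
  grid <- array(c(-4, 0, 2, 1, -0.5, 3, 0, -2), dim = c(2, 2, 2))
  pr <- structure(list(class_id = 2L, grid = grid, n_samples_averaged = 5L,
                       scale = "raw", absent = FALSE), class = "dg_prior")
  u <- scale_to_unit(pr)
  expect_equal(max(abs(u$grid)), 1)
  expect_equal(u$grid, grid / 4, tolerance = 1e-12)
  expect_identical(sign(u$grid), sign(grid))
  expect_equal(rank(abs(as.vector(u$grid))), rank(abs(as.vector(grid))))
  # antisymmetric grid stays antisymmetric
  anti <- array(c(-3, 3, 1, -1, 2, -2, 0, 0), dim = c(2, 2, 2))
  pa <- pr; pa$grid <- anti
  expect_equal(scale_to_unit(pa)$grid, anti / 3, tolerance = 1e-12)
  z <- pr; z$grid <- array(0, dim = c(2, 2, 2))
  expect_warning(zz <- scale_to_unit(z), "all-zero")
  expect_equal(zz$grid, z$grid)
})

test_that("prior resampling preserves constants and identity shapes", {
  pr <- structure(list(class_id = 0L, grid = array(0.4, dim = c(6, 6, 6)),
                       n_samples_averaged = 2L, scale = "raw", absent = FALSE),
                  class = "dg_prior")
  expect_equal(resample_prior(pr, c(3, 4, 5))$grid,
               array(0.4, dim = c(3, 4, 5)), tolerance = 1e-12)
  expect_equal(resample_prior(pr, c(6, 6, 6))$grid, pr$grid, tolerance = 1e-12)
})
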