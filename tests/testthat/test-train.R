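# Losses, augmentation, Mixup, and the two-stage training loop.

test_that("class weights are inverse counts and fail on missing classes", {
  expect_equal(class_weights(rep(0:2, each = 10)), rep(0.1, 3))
  w <- class_weights(rep(0:2, times = c(30, 15, 5)))
  expect_equal(w / w[1], c(1, 2, 6))
  expect_error(class_weights(c(0, 0, 2), n_classes = 3), "class 1")
})

test_that("weighted cross-entropy matches closed forms and a per-sample loop", {
  onehot <- diag(3)
  expect_equal(wce_loss(onehot, 0:2, rep(1, 3)), 0, tolerance = 1e-10)
  unif <- matrix(1 / 3, 4, 3)
  expect_equal(wce_loss(unif, c(0, 1, 2, 0), rep(1, 3)), log(3), tolerance = 1e-12)
  set.seed(4)
  P <- t(apply(matrix(runif(15), 5, 3), 1, function(r) r / sum(r)))
  y <- c(0, 2, 1, 1, 0)
  w <- c(0.5, 1.5, 2)
  loop <- mean(vapply(1:5, function(i) -w[y[i] + 1] * log(P[i, y[i] + 1]),
                      numeric(1)))
  expect_equal(wce_loss(P, y, w), loop, tolerance = 1e-12)
  # zero probability at the true class is clamped, not infinite
  Pz <- rbind(c(0, 1, 0))
  expect_true(is.finite(wce_loss(Pz, 0L, rep(1, 3))))
})

test_that("similarity loss is the summed per-class L2 norm, zero iff aligned", {
  dims <- c(4, 4, 4)
  set.seed(2)
  M <- array(runif(3 * 64), dim = c(3, dims))
  priors <- lapply(0:2, function(k) array(runif(64), dim = dims))
  # voxel-loop oracle
  oracle <- 0
  for (k in 1:3) {
    ss <- 0
    for (v in 1:64) ss <- ss + (as.vector(M[k, , , ])[v] - as.vector(priors[[k]])[v])^2
    oracle <- oracle + sqrt(ss)
  }
  expect_equal(sim_loss(M, priors), oracle, tolerance = 1e-12)
  # identity alignment
  Ms <- M
  for (k in 1:3) Ms[k, , , ] <- priors[[k]]
  expect_equal(sim_loss(Ms, priors), 0, tolerance = 1e-12)
  expect_gt(sim_loss(M, priors), 0)
  # single-voxel example: unit distance
  M1 <- array(c(1, 0, 0), dim = c(3, 1, 1, 1))
  p0 <- lapply(1:3, function(k) array(0, dim = c(1, 1, 1)))
  expect_equal(sim_loss(M1, p0), 1, tolerance = 1e-12)
  # batch mean reduction
  expect_equal(sim_loss(list(M, Ms), priors), oracle / 2, tolerance = 1e-12)
})

test_that("total loss combines components linearly", {
  expect_equal(total_loss(1.3, 99, 0), 1.3)
  expect_equal(total_loss(1, 2, 0.5), 2)
})

test_that("augmentation contracts: identity when off, bounded and shape-preserving when on", {
  v <- random_volume(c(8, 8, 8), seed = 3)
  v <- (v - min(v)) / (max(v) - min(v))   # spans [0, 1] exactly
  expect_equal(augment_volume(v, seed = 5), v, tolerance = 1e-12)
  a <- augment_volume(v, contrast = TRUE, bias_field = TRUE, crop = TRUE, seed = 5)
  expect_equal(dim(a), dim(v))
  expect_true(all(a >= 0 & a <= 1))
  expect_false(identical(a, v))
  expect_identical(a, augment_volume(v, contrast = TRUE, bias_field = TRUE,
                                     crop = TRUE, seed = 5))
  expect_false(identical(a, augment_volume(v, contrast = TRUE, bias_field = TRUE,
                                           crop = TRUE, seed = 6)))
})

test_that("mixup forms convex combinations with Beta-distributed coefficients", {
  xa <- array(0, c(2, 2, 2)); xb <- array(1, c(2, 2, 2))
  ya <- c(1, 0, 0); yb <- c(0, 0, 1)
  end <- mixup_batch(xa, ya, xb, yb, lam = 1)
  expect_equal(end$x, xa); expect_equal(end$y, ya)
  half <- mixup_batch(xa, ya, xb, yb, lam = 0.5)
  expect_equal(unique(as.vector(half$x)), 0.5)
  expect_equal(half$y, c(0.5, 0, 0.5))
  lams <- vapply(1:50, function(s) mixup_batch(xa, ya, xb, yb, alpha = 0.2,
                                               seed = s)$lam, numeric(1))
  expect_true(all(lams >= 0 & lams <= 1))
  expect_error(mixup_batch(xa, ya, xb, yb, alpha = 0), "alpha")
})

test_that("gradient accumulation reproduces the full-batch update", {
  m <- tiny_model(shape = c(8, 8, 8), ds = 2, seed = 31)
  set.seed(12)
  vols <- lapply(1:16, function(i) random_volume(c(8, 8, 8), seed = 100 + i))
  y <- rep(0:2, length.out = 16)
  Q <- matrix(0, 16, 3); Q[cbind(1:16, y + 1)] <- 1
  w <- class_weights(y, 3)
  full <- loss_gradients(m, vols, Q, w)$grads
  acc <- NULL
  for (a in 1:8) {
    sel <- ((a - 1) * 2 + 1):(a * 2)
    g <- loss_gradients(m, vols[sel], Q[sel, , drop = FALSE], w)$grads
    acc <- if (is.null(acc)) g else acc + g
  }
  acc <- acc / 8
  expect_equal(acc, full, tolerance = 1e-12)
  theta <- unlist(m$params)
  up_full <- adam_step(theta, full, adam_init(length(theta)), lr = 3e-3)$theta
  up_acc <- adam_step(theta, acc, adam_init(length(theta)), lr = 3e-3)$theta
  expect_equal(up_acc, up_full, tolerance = 1e-5)
})

test_that("lambda = 0 stage-2 training reproduces stage-1 step for step", {
  coh <- tiny_cohort(n_per_class = c(6, 6, 6), seed = 19)
  sp <- split_head(coh, 4)
  tr <- sp$train; va <- sp$val
  mc <- model_config(c(16, 16, 16), encoder_channels = 6,
                     downsample_factor = 2, seed = 44)
  tc <- train_config(lambda = 0, epochs = 3, micro_batch = 4, lr = 5e-3, seed = 9)
  fit1 <- train_stage1(tr, va, mc, tc)
  dummy_priors <- lapply(0:2, function(k)
    structure(list(class_id = k,
                   grid = array(stats::runif(16^3), dim = c(16, 16, 16)),
                   n_samples_averaged = 1L, scale = "raw", absent = FALSE),
              class = "dg_prior"))
  fit2 <- train_stage2(tr, va, dummy_priors, mc, tc)
  expect_equal(fit2$steps[, "wce"], fit1$steps[, "wce"], tolerance = 1e-9)
  expect_equal(fit2$steps[, "total"] - fit1$steps[, "total"], rep(0, nrow(fit1$steps)),
               tolerance = 1e-9)
  expect_equal(unlist(fit2$final_model$params), unlist(fit1$final_model$params),
               tolerance = 1e-12)
})

test_that("recorded total loss decomposes as wce + lambda * sim at every step", {
  coh <- tiny_cohort(n_per_class = c(6, 6, 6), seed = 23)
  sp <- split_head(coh, 4)
  tr <- sp$train; va <- sp$val
  mc <- model_config(c(16, 16, 16), encoder_channels = 6,
                     downsample_factor = 2, seed = 2)
  tc <- train_config(lambda = 3e-3, epochs = 3, micro_batch = 4, lr = 5e-3, seed = 3)
  priors <- lapply(0:2, function(k)
    structure(list(class_id = k,
                   grid = array(stats::runif(16^3, 0, 0.2), dim = c(16, 16, 16)),
                   n_samples_averaged = 1L, scale = "raw", absent = FALSE),
              class = "dg_prior"))
  fit <- train_stage2(tr, va, priors, mc, tc)
  expect_equal(fit$steps[, "total"],
               fit$steps[, "wce"] + 3e-3 * fit$steps[, "sim"], tolerance = 1e-9)
  expect_true(all(is.finite(fit$steps)))
})

test_that("training history has one row per epoch and is seed-reproducible", {
  coh <- tiny_cohort(n_per_class = c(5, 5, 5), seed = 29)
  sp <- split_head(coh, 3)
  tr <- sp$train; va <- sp$val
  mc <- model_config(c(16, 16, 16), encoder_channels = 6,
                     downsample_factor = 2, seed = 1)
  tc <- train_config(lambda = 0, epochs = 4, micro_batch = 3, lr = 5e-3, seed = 6)
  f1 <- train_stage1(tr, va, mc, tc)
  f2 <- train_stage1(tr, va, mc, tc)
  expect_equal(nrow(f1$history), 4)
  expect_identical(f1$history, f2$history)
  expect_identical(unlist(f1$model$params), unlist(f2$model$params))
})

test_that("stage-1 fits a linearly separable toy cohort to high accuracy", {
  coh <- separable_cohort(n = 6)
  tc <- train_config(lambda = 0, epochs = 30, micro_batch = 6, lr = 0.01, seed = 5)
  mc <- model_config(c(16, 16, 16), encoder_channels = 6,
                     downsample_factor = 2, seed = 8)
  fit <- cached("prior_fit", train_stage1(coh$samples, coh$samples, mc, tc))
  expect_gte(evaluate_model(fit$model, coh$samples)$accuracy, 0.95)
})
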