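# Shared fixtures, built in code. Small cohorts / models for unit tests; the
# heavier trained objects used by several acceptance checks are cached per
# session in `.fixture_cache`.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_parcellation <- function(shape = c(16L, 16L, 16L), n_regions = 8L, seed = 1L) {
  make_parcellation(shape, n_regions, seed = seed)
}

tiny_cohort <- function(n_per_class = c(8L, 8L, 8L), shape = c(16L, 16L, 16L),
                        effect_size = 0.25, noise_sd = 0.02, seed = 7L,
                        grade_distributions = NULL) {
  parc <- tiny_parcellation(shape)
  args <- list(n_per_class = n_per_class, shape = shape, n_regions = 8L,
               disease_regions = c(1L, 2L), effect_size = effect_size,
               noise_sd = noise_sd, seed = seed)
  if (!is.null(grade_distributions)) args$grade_distributions <- grade_distributions
  spec <- do.call(cohort_spec, args)
  generate_cohort(spec, parc)
}

# deterministic cohort with fully class-determined grades (linearly separable)
separable_cohort <- function(n = 10L, shape = c(16L, 16L, 16L), seed = 3L) {
  gd <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  tiny_cohort(n_per_class = rep(n, 3), shape = shape, effect_size = 0.25,
              noise_sd = 0, seed = seed, grade_distributions = gd)
}

# stratified head/tail split of a cohort (samples are stored class-ordered)
split_head <- function(cohort, n_train_per_class) {
  labels <- cohort_labels(cohort)
  tr <- unlist(lapply(0:2, function(cl) which(labels == cl)[seq_len(n_train_per_class)]))
  va <- setdiff(seq_along(labels), tr)
  list(train = cohort$samples[tr], val = cohort$samples[va])
}

tiny_model <- function(shape = c(8L, 8L, 8L), channels = 5L, ds = 2L, seed = 4L) {
  init_model(model_config(shape, n_classes = 3L, encoder_channels = channels,
                          downsample_factor = ds, seed = seed))
}

random_volume <- function(shape = c(8L, 8L, 8L), seed = 1L) {
  set.seed(seed)
  array(runif(prod(shape)), dim = shape)
}

# The desk-scale study used by the training-benefit and prior-recovery
# checks: 60 subjects/class, 32^3 volumes, 27 regions with 3 disease
# regions, strong planted effect and low noise.
study_conditions <- function() {
  list(shape = c(32L, 32L, 32L), n_regions = 27L,
       disease_regions = c(3L, 7L, 12L),
       effect_size = 0.25, noise_sd = 0.02)
}

study_cohort <- function() {
  cached("study_cohort", {
    sc <- study_conditions()
    parc <- make_parcellation(sc$shape, sc$n_regions, seed = 1L)
    spec <- cohort_spec(c(60L, 60L, 60L), sc$shape, sc$n_regions,
                        sc$disease_regions, effect_size = sc$effect_size,
                        noise_sd = sc$noise_sd, seed = 11L)
    generate_cohort(spec, parc)
  })
}

study_model_config <- function(seed) {
  model_config(study_conditions()$shape, encoder_channels = 8L,
               downsample_factor = 4L, seed = seed)
}

study_train_config <- function(lambda, seed) {
  train_config(lambda = lambda, epochs = 30L, steps_per_epoch = 27L,
               micro_batch = 4L, lr = 0.01, prior_scale = "unit", seed = seed)
}

study_split <- function() {
  cached("study_split", {
    coh <- study_cohort()
    plan <- stratified_kfold(cohort_labels(coh), k = 5L, seed = 2L)
    fold <- plan$folds[[1]]
    list(train = coh$samples[fold$train], val = coh$samples[fold$val],
         test = coh$samples[fold$test])
  })
}

study_stage1 <- function() {
  cached("study_stage1", {
    sp <- study_split()
    train_stage1(sp$train, sp$val, study_model_config(101L),
                 study_train_config(0, 11L))
  })
}

study_priors <- function() {
  cached("study_priors", {
    sp <- study_split()
    build_class_priors(study_stage1()$model, sp$train,
                       attribution_config(n_background = 6L, n_draws = 8L,
                                          seed = 301L))
  })
}

# simple two-layer scorer on a small input, with analytic gradient
make_toy_scorer <- function(n_in, n_hidden = 4L, seed = 1L) {
  set.seed(seed)
  W1 <- matrix(rnorm(n_in * n_hidden, sd = 0.8), n_in, n_hidden)
  b1 <- rnorm(n_hidden, sd = 0.3)
  w2 <- rnorm(n_hidden)
  list(
    score = function(x) sum(w2 * tanh(drop(crossprod(W1, x)) + b1)),
    grad = function(x) {
      h <- drop(crossprod(W1, x)) + b1
      drop(W1 %*% (w2 * (1 - tanh(h)^2)))
    })
}

# multilinear scorer (linear + pairwise + one triple term). For multilinear
# games the straight-path integrated gradient equals the Shapley value, so
# expected gradients with a single baseline must agree with exact_shapley up
# to Monte-Carlo error only.
make_multilinear_scorer <- function(n_in, seed = 1L) {
  set.seed(seed)
  a <- rnorm(n_in)
  B <- matrix(rnorm(n_in^2, sd = 0.5), n_in, n_in)
  B[lower.tri(B, diag = TRUE)] <- 0
  c3 <- rnorm(1, sd = 0.3)
  list(
    score = function(z) sum(a * z) + sum(B * outer(z, z)) + c3 * z[1] * z[2] * z[3],
    grad = function(z) {
      g <- a + drop(B %*% z) + drop(t(B) %*% z) - 2 * diag(B) * z
      g[1] <- g[1] + c3 * z[2] * z[3]
      g[2] <- g[2] + c3 * z[1] * z[3]
      g[3] <- g[3] + c3 * z[1] * z[2]
      g
    })
}
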