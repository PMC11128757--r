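# Shapley-style voxel attributions and class-wise saliency priors. The
# scalable estimator is expected gradients (a Shapley-value formulation of
# integrated gradients with a reference distribution); an exact
# subset-enumeration Shapley implementation is provided as the small-instance
# oracle. Priors are per-class averages of attributions over the samples a
# baseline model predicts correctly.

#' Attribution configuration
#'
#' @param method `"expected_gradients"` (scalable estimator) or
#'   `"exact_shapley"` (enumeration; only for tiny grouped problems).
#' @param n_background number of reference (background) volumes drawn from
#'   the normal-cognition class of the training set.
#' @param n_draws Monte-Carlo draws per sample for expected gradients.
#' @param seed integer seed; per-sample streams are derived from it and the
#'   subject id so results do not depend on dataset ordering.
#' @return object of class `dg_attr_config`.
#' @export
attribution_config <- function(method = c("expected_gradients", "exact_shapley"),
                               n_background = 5L, n_draws = 16L, seed = 1L) {
  method <- match.arg(method)
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  structure(list(method = method, n_background = as.integer(n_background),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "dg_attr_config")
}

#' Expected-gradients attribution for an arbitrary differentiable scorer
#'
#' Averages, over `n_draws` joint draws of a reference example `b` and an
#' interpolation coefficient `alpha ~ U(0, 1)`, the quantity
#' `grad f(b + alpha (x - b)) * (x - b)`. For a linear scorer this equals
#' `w * (x - baseline)` exactly; in expectation the attributions sum to
#' `f(x) - mean f(background)` (the SHAP efficiency property).
#'
#' @param grad_fn function(z) returning the gradient of the score at `z`
#'   (same shape as `z`).
#' @param x input (numeric vector or array).
#' @param backgrounds list of reference inputs with the same shape as `x`.
#' @param n_draws number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return attribution with the same shape as `x`.
#' @export
expected_gradients <- function(grad_fn, x, backgrounds, n_draws = 16L, seed = 1L) {
  if (length(backgrounds) == 0L) stop("background set is empty", call. = FALSE)
  with_seed(seed, {
    acc <- x * 0
    for (d in seq_len(n_draws)) {
      b <- backgrounds[[sample.int(length(backgrounds), 1L)]]
      alpha <- stats::runif(1)
      z <- b + alpha * (x - b)
      acc <- acc + grad_fn(z) * (x - b)
    }
    acc / n_draws
  })
}

#' Voxel attribution of a model prediction
#'
#' Expected-gradients attribution of the target class's pre-softmax logit
#' with respect to the input volume.
#'
#' @param model a trained `dg_model`.
#' @param sample a `dg_sample` (or a bare 3D volume).
#' @param target_class class id in `0..K-1`.
#' @param backgrounds list of reference volumes (e.g. NC training volumes).
#' @param config an [attribution_config()].
#' @return 3D attribution grid with the volume's shape.
#' @export
attribute <- function(model, sample, target_class, backgrounds, config) {
  stopifnot(inherits(model, "dg_model"), inherits(config, "dg_attr_config"))
  vol <- if (inherits(sample, "dg_sample")) sample$volume else sample
  check_volume(model, vol)
  for (p in model$params$enc) {
    if (!all(is.finite(p$W))) stop("model parameters are not finite", call. = FALSE)
  }
  k <- as.integer(target_class)
  K <- model$config$n_classes
  if (k < 0L || k >= K) stop("target_class out of range", call. = FALSE)
  tag <- if (inherits(sample, "dg_sample")) sample$subject_id else "volume"
  seed_i <- derive_seed(config$seed, tag)
  onehot <- numeric(K); onehot[k + 1L] <- 1
  grad_fn <- function(z) {
    fw <- forward_pass(model, z)
    backward_pass(model, fw, onehot, input_grad = TRUE)$dinput
  }
  expected_gradients(grad_fn, vol, backgrounds, config$n_draws, seed_i)
}

#' Exact Shapley values by subset enumeration
#'
#' Computes exact Shapley attributions for feature groups by evaluating
#' `score_fn` on all 2^G coalitions (absent groups take their baseline
#' values). Satisfies the efficiency axiom:
#' `sum(phi) == score_fn(x) - score_fn(baseline)` up to floating point.
#'
#' @param score_fn function(z) -> scalar score.
#' @param x input vector.
#' @param baseline reference vector of the same length.
#' @param groups list of integer index vectors (disjoint feature groups);
#'   at most 16 groups.
#' @return numeric vector of per-group Shapley values.
#' @export
exact_shapley <- function(score_fn, x, baseline, groups) {
  G <- length(groups)
  if (G < 1L) stop("need at least one group", call. = FALSE)
  if (G > 16L) {
    stop(sprintf("exact_shapley enumerates 2^G coalitions; G = %d exceeds the limit of 16", G),
         call. = FALSE)
  }
  nS <- bitwShiftL(1L, G)
  subsets <- 0:(nS - 1L)
  vals <- numeric(nS)
  for (s in subsets) {
    z <- baseline
    for (g in seq_len(G)) {
      if (bitwAnd(s, bitwShiftL(1L, g - 1L)) != 0L) z[groups[[g]]] <- x[groups[[g]]]
    }
    vals[s + 1L] <- score_fn(z)
  }
  popcount <- integer(nS)
  for (g in seq_len(G)) {
    popcount <- popcount + (bitwAnd(subsets, bitwShiftL(1L, g - 1L)) != 0L)
  }
  lfact <- lgamma(seq_len(G + 1L))          # lfact[m+1] = log(m!)
  wt <- exp(lfact[0:(G - 1L) + 1L] + lfact[G - (0:(G - 1L)) - 1L + 1L] - lfact[G + 1L])
  phi <- numeric(G)
  for (g in seq_len(G)) {
    bit <- bitwShiftL(1L, g - 1L)
    without <- which(bitwAnd(subsets, bit) == 0L)   # 1-based positions
    k <- popcount[without]
    phi[g] <- sum(wt[k + 1L] * (vals[without + bit] - vals[without]))
  }
  phi
}

#' Build class-wise saliency priors over correct predictions
#'
#' For each class k, attributions toward class k are averaged over exactly
#' the samples whose predicted class (argmax of the probabilities, ties
#' broken toward the lowest class index) equals their true label k. The
#' reference set is a seeded subset of the cohort's NC volumes.
#'
#' @param model a trained `dg_model` (the stage-1 baseline).
#' @param samples list of `dg_sample`s (typically the training split).
#' @param config an [attribution_config()].
#' @return list of K objects of class `dg_prior`, each with `class_id`,
#'   `grid` (3D array, `NULL` when absent), `n_samples_averaged`, `scale`
#'   (`"raw"`), and `absent` flag. Errors if no class has any correct
#'   prediction.
#' @export
build_class_priors <- function(model, samples, config) {
  stopifnot(inherits(config, "dg_attr_config"))
  K <- model$config$n_classes
  labels <- vapply(samples, function(s) s$label, integer(1))
  probs <- predict_classes(model, lapply(samples, function(s) s$volume))
  pred <- apply(probs, 1L, function(p) which(p == max(p))[1] - 1L)
  nc_idx <- which(labels == 0L)
  if (length(nc_idx) == 0L) stop("no NC samples available as attribution background", call. = FALSE)
  bg_idx <- with_seed(config$seed,
                      sample(nc_idx, min(config$n_background, length(nc_idx))))
  bg_idx <- sort(bg_idx)  # order-independent background set
  backgrounds <- lapply(samples[bg_idx], function(s) s$volume)
  priors <- vector("list", K)
  any_present <- FALSE
  for (k in 0:(K - 1L)) {
    correct <- which(labels == k & pred == k)
    if (length(correct) == 0L) {
      priors[[k + 1L]] <- structure(
        list(class_id = k, grid = NULL, n_samples_averaged = 0L,
             scale = "raw", absent = TRUE), class = "dg_prior")
      next
    }
    any_present <- TRUE
    acc <- array(0, dim = model$config$input_shape)
    for (i in correct) {
      acc <- acc + attribute(model, samples[[i]], k, backgrounds, config)
    }
    priors[[k + 1L]] <- structure(
      list(class_id = k, grid = acc / length(correct),
           n_samples_averaged = length(correct), scale = "raw",
           absent = FALSE), class = "dg_prior")
  }
  if (!any_present) {
    tab <- paste(sprintf("class %d: %d/%d correct", 0:(K - 1L),
                         vapply(0:(K - 1L), function(k) sum(labels == k & pred == k), integer(1)),
                         vapply(0:(K - 1L), function(k) sum(labels == k), integer(1))),
                 collapse = "; ")
    stop("no correct predictions for any class; cannot build priors (", tab, ")",
         call. = FALSE)
  }
  priors
}

#' Scale a prior to the range [-1, 1]
#'
#' Divides by the maximum absolute attribution, preserving signs and zeros.
#' Intended for visualization; the training loss applies its own scaling
#' through the `prior_scale` switch of [train_config()].
#'
#' @param prior a `dg_prior`.
#' @return the prior with `scale = "unit"`; an all-zero grid is returned
#'   unchanged with a warning flag (`attr(, "degenerate")`).
#' @export
scale_to_unit <- function(prior) {
  stopifnot(inherits(prior, "dg_prior"))
  if (isTRUE(prior$absent)) stop("cannot scale an absent prior", call. = FALSE)
  m <- max(abs(prior$grid))
  if (m == 0) {
    warning("all-zero prior grid; returned unchanged")
    attr(prior, "degenerate") <- TRUE
    return(prior)
  }
  prior$grid <- prior$grid / m
  prior$scale <- "unit"
  prior
}

#' Resample a prior to a new grid shape
#'
#' Trilinear resampling (see [resample_trilinear()]); bridges input-space
#' priors to the attention module's feature resolution.
#'
#' @param prior a `dg_prior`.
#' @param target_shape integer length-3 shape.
#' @return the prior with `grid` at `target_shape`.
#' @export
resample_prior <- function(prior, target_shape) {
  stopifnot(inherits(prior, "dg_prior"))
  if (isTRUE(prior$absent)) stop("cannot resample an absent prior", call. = FALSE)
  prior$grid <- resample_trilinear(prior$grid, target_shape)
  prior
}
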