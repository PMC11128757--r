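# Two-stage training. Stage 1 optimizes inverse-frequency weighted
# cross-entropy (WCE) and provides the baseline whose attributions become the
# class priors. Stage 2 trains a fresh, independently initialized model on
# the combined loss  L = L_WCE + lambda * L_sim,  where L_sim is, per sample,
# the sum over classes of the L2 norm between each attention channel and its
# class prior (resampled to attention resolution). Optimization is Adam with
# gradient accumulation; both losses are mean-reduced over the batch so
# lambda keeps its meaning across batch sizes.

#' Inverse-count class weights
#'
#' @param labels integer class labels in `0..K-1`.
#' @param n_classes K; defaults to `max(labels) + 1`.
#' @return numeric vector `w` with `w_k = 1 / count_k`.
#' @export
class_weights <- function(labels, n_classes = NULL) {
  labels <- as.integer(labels)
  K <- as.integer(n_classes %||% (max(labels) + 1L))
  counts <- tabulate(labels + 1L, nbins = K)
  if (any(counts == 0L)) {
    stop(sprintf("class %s has no samples; cannot compute inverse-count weights",
                 paste(which(counts == 0L) - 1L, collapse = ", ")), call. = FALSE)
  }
  1 / counts
}

#' Weighted cross-entropy loss
#'
#' Mean over the batch of `-w[y_i] * log(p_i[y_i])`; predicted probabilities
#' are clamped at 1e-12.
#'
#' @param probs N x K matrix (or length-K vector) of probabilities.
#' @param labels integer labels in `0..K-1`.
#' @param weights per-class weights (length K).
#' @return non-negative scalar.
#' @export
wce_loss <- function(probs, labels, weights) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1L)
  labels <- as.integer(labels)
  p_true <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  mean(-weights[labels + 1L] * log(pmax(p_true, 1e-12)))
}

prior_matrix <- function(priors, dims, prior_scale = "unit") {
  K <- length(priors)
  S <- matrix(0, prod(dims), K)
  for (k in seq_len(K)) {
    pr <- priors[[k]]
    if (!inherits(pr, "dg_prior")) {
      grid <- pr
    } else {
      if (isTRUE(pr$absent)) {
        stop(sprintf("prior for class %d is absent; stage-2 training cannot start",
                     pr$class_id), call. = FALSE)
      }
      if (prior_scale == "unit" && pr$scale != "unit" && max(abs(pr$grid)) > 0) {
        pr <- scale_to_unit(pr)
      }
      grid <- pr$grid
    }
    if (!identical(as.integer(dim(grid)), as.integer(dims))) {
      grid <- resample_trilinear(grid, dims)
    }
    S[, k] <- as.vector(grid)
  }
  S
}

#' Similarity loss between attention maps and class priors
#'
#' Per sample, `sum_k || M_k - SHAP_k ||_2` (L2 norm over voxels of each
#' class channel), mean-reduced over the batch. Zero iff every attention
#' channel equals its prior.
#'
#' @param attention a K x d x h x w array (or `dg_attention`), or a list of
#'   them for a batch.
#' @param priors list of K `dg_prior`s (or bare 3D arrays) at the attention
#'   resolution (resampled automatically if shapes differ).
#' @param normalize_by_voxels if `TRUE` use the root-mean-square distance
#'   instead of the raw L2 norm.
#' @param prior_scale `"raw"` to use the priors as-is.
#' @return non-negative scalar.
#' @export
sim_loss <- function(attention, priors, normalize_by_voxels = FALSE,
                     prior_scale = "raw") {
  batch <- if (is.list(attention) && !inherits(attention, "dg_attention"))
    attention else list(attention)
  to_mat <- function(a) {
    if (inherits(a, "dg_features")) return(list(mat = a$mat, dims = a$dims))
    stopifnot(length(dim(a)) == 4L)
    list(mat = matrix(aperm(a, c(2, 3, 4, 1)), ncol = dim(a)[1]),
         dims = dim(a)[-1])
  }
  first <- to_mat(batch[[1]])
  S <- prior_matrix(priors, first$dims, prior_scale)
  if (ncol(S) != ncol(first$mat)) {
    stop("number of priors does not match number of attention channels", call. = FALSE)
  }
  vals <- vapply(batch, function(a) {
    M <- to_mat(a)$mat
    d <- sqrt(colSums((M - S)^2))
    if (normalize_by_voxels) d <- d / sqrt(nrow(M))
    sum(d)
  }, numeric(1))
  mean(vals)
}

#' Combined loss
#'
#' @param wce weighted cross-entropy component.
#' @param sim similarity component.
#' @param lambda trade-off hyper-parameter (>= 0); the reference value from
#'   full-scale training is 5e-5, but it is resolution-dependent (see the
#'   methods vignette).
#' @return `wce + lambda * sim`.
#' @export
total_loss <- function(wce, sim, lambda) {
  stopifnot(is.finite(wce), is.finite(sim), lambda >= 0)
  wce + lambda * sim
}

#' Training configuration
#'
#' @param lambda similarity-loss weight (default 5e-5, the full-scale
#'   reference value; desk-scale experiments in this package use 0.01).
#' @param epochs number of epochs.
#' @param steps_per_epoch weight updates per epoch; default covers the
#'   training set once.
#' @param micro_batch samples per forward/backward pass.
#' @param accumulation_steps micro-batches accumulated per weight update
#'   (effective batch = `micro_batch * accumulation_steps`).
#' @param lr Adam step size.
#' @param mixup_alpha Beta(alpha, alpha) parameter for the Mixup comparator.
#' @param mixup enable Mixup augmentation of each micro-batch.
#' @param augment enable the stochastic intensity/spatial augmentations.
#' @param sim_scope `"all_classes"` aligns every attention channel with its
#'   class prior for every sample (the loss as formulated);
#'   `"true_class_only"` aligns only the ground-truth channel.
#' @param prior_scale `"unit"` (default) rescales priors to `[-1, 1]` before
#'   the loss; `"raw"` uses raw attribution scale.
#' @param normalize_by_voxels use RMS instead of raw L2 in the similarity
#'   loss.
#' @param seed seed for data ordering and stochastic augmentation.
#' @return object of class `dg_train_config`.
#' @export
train_config <- function(lambda = 5e-5, epochs = 10L, steps_per_epoch = NULL,
                         micro_batch = 4L, accumulation_steps = 1L,
                         lr = 3e-3, mixup_alpha = 0.2, mixup = FALSE,
                         augment = FALSE,
                         sim_scope = c("all_classes", "true_class_only"),
                         prior_scale = c("unit", "raw"),
                         normalize_by_voxels = FALSE, seed = 1L) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (accumulation_steps < 1L) stop("accumulation_steps must be >= 1", call. = FALSE)
  structure(list(lambda = lambda, epochs = as.integer(epochs),
                 steps_per_epoch = if (!is.null(steps_per_epoch)) as.integer(steps_per_epoch),
                 micro_batch = as.integer(micro_batch),
                 accumulation_steps = as.integer(accumulation_steps),
                 lr = lr, mixup_alpha = mixup_alpha, mixup = isTRUE(mixup),
                 augment = isTRUE(augment),
                 sim_scope = match.arg(sim_scope),
                 prior_scale = match.arg(prior_scale),
                 normalize_by_voxels = isTRUE(normalize_by_voxels),
                 seed = as.integer(seed)),
            class = "dg_train_config")
}

#' Stochastic augmentation of a volume
#'
#' Applies (per flags) random contrast adjustment (gamma), a random smooth
#' multiplicative bias field, random spatial cropping followed by trilinear
#' upsampling back to the input shape, and always finishes with min-max
#' intensity scaling to `[0, 1]`. Deterministic given `seed`.
#'
#' @param volume 3D array with values in `[0, 1]`.
#' @param contrast,bias_field,crop logical flags.
#' @param seed integer seed.
#' @return augmented volume, same shape, values in `[0, 1]`.
#' @export
augment_volume <- function(volume, contrast = FALSE, bias_field = FALSE,
                           crop = FALSE, seed = 1L) {
  dims <- dim(volume)
  with_seed(seed, {
    v <- volume
    if (contrast) {
      gamma <- exp(stats::runif(1, -0.3, 0.3))
      v <- pmax(v, 0)^gamma
    }
    if (bias_field) {
      ax <- lapply(dims, function(n) seq(-1, 1, length.out = n))
      X <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
      Y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
      Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
      a <- stats::rnorm(9, sd = 0.08)
      v <- v * exp(a[1] * X + a[2] * Y + a[3] * Z + a[4] * X * Y +
                     a[5] * X * Z + a[6] * Y * Z + a[7] * X^2 + a[8] * Y^2 +
                     a[9] * Z^2)
    }
    if (crop) {
      size <- pmax(vapply(dims, function(n) round(stats::runif(1, 0.85, 1) * n), numeric(1)), 4)
      off <- vapply(seq_len(3), function(a) sample.int(dims[a] - size[a] + 1L, 1L), integer(1))
      v <- v[off[1]:(off[1] + size[1] - 1L),
             off[2]:(off[2] + size[2] - 1L),
             off[3]:(off[3] + size[3] - 1L), drop = FALSE]
      v <- resample_trilinear(v, dims)
    }
    rng <- range(v)
    if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
    v
  })
}

#' Mixup of two examples (or batches)
#'
#' Draws `lam ~ Beta(alpha, alpha)` and forms the convex combinations
#' `lam * x_a + (1 - lam) * x_b` of inputs and of one-hot labels.
#'
#' @param x_a,x_b numeric arrays of identical shape.
#' @param y_a,y_b one-hot label vectors (or matrices) of identical shape.
#' @param alpha Beta concentration (> 0); reference value 0.2.
#' @param seed integer seed.
#' @param lam optional forced mixing coefficient (bypasses the draw).
#' @return list with `x`, `y`, `lam`.
#' @export
mixup_batch <- function(x_a, y_a, x_b, y_b, alpha = 0.2, seed = 1L, lam = NULL) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (is.null(lam)) lam <- with_seed(seed, stats::rbeta(1, alpha, alpha))
  list(x = lam * x_a + (1 - lam) * x_b,
       y = lam * y_a + (1 - lam) * y_b,
       lam = lam)
}

# ---- internal training machinery ------------------------------------------

flatten_params <- function(params) unlist(params, use.names = FALSE)

flatten_grads <- function(grads, params) {
  grads$dinput <- NULL
  unlist(grads[names(params)], use.names = FALSE)
}

# Gradients of total_loss over one micro-batch. `targets` is a B x K matrix
# of (possibly soft) target distributions; `S` the prior matrix (voxels x K)
# or NULL. Mean reduction over the micro-batch.
#' Loss and gradients over a micro-batch
#'
#' Computes the mean-reduced combined loss and its gradient with respect to
#' all model parameters over one micro-batch. Exposed as a building block so
#' that gradient-accumulation schemes can be composed and verified.
#'
#' @param model a `dg_model`.
#' @param volumes list of input volumes.
#' @param targets B x K matrix of target distributions (one-hot rows for
#'   ordinary training).
#' @param weights per-class weights.
#' @param S prior matrix (n_feature_voxels x K) or `NULL` for WCE only.
#' @param lambda similarity-loss weight.
#' @param sim_scope,normalize_by_voxels see [train_config()].
#' @return list with `grads` (flat numeric vector), `wce`, `sim`, `probs`.
#' @export
loss_gradients <- function(model, volumes, targets, weights, S = NULL,
                           lambda = 0, sim_scope = "all_classes",
                           normalize_by_voxels = FALSE) {
  B <- length(volumes)
  K <- model$config$n_classes
  gacc <- NULL
  wce_acc <- 0; sim_acc <- 0
  probs <- matrix(0, B, K)
  for (i in seq_len(B)) {
    fw <- forward_pass(model, volumes[[i]])
    probs[i, ] <- fw$probs
    t_i <- targets[i, ] * weights
    wce_acc <- wce_acc + sum(-t_i * log(pmax(fw$probs, 1e-12)))
    dlogits <- (sum(t_i) * fw$probs - t_i) / B
    dM_extra <- NULL
    if (!is.null(S) && lambda > 0) {
      Dm <- fw$M - S
      nrm <- sqrt(colSums(Dm^2))
      scalef <- if (normalize_by_voxels) sqrt(nrow(Dm)) else 1
      ks <- if (sim_scope == "true_class_only") which.max(targets[i, ]) else seq_len(K)
      sim_i <- sum(nrm[ks]) / scalef
      sim_acc <- sim_acc + sim_i
      dM_extra <- matrix(0, nrow(Dm), K)
      for (k in ks) {
        if (nrm[k] > 0) dM_extra[, k] <- (lambda / (B * scalef)) * Dm[, k] / nrm[k]
      }
    } else if (!is.null(S)) {
      Dm <- fw$M - S
      nrm <- sqrt(colSums(Dm^2))
      scalef <- if (normalize_by_voxels) sqrt(nrow(Dm)) else 1
      ks <- if (sim_scope == "true_class_only") which.max(targets[i, ]) else seq_len(K)
      sim_acc <- sim_acc + sum(nrm[ks]) / scalef
    }
    g <- backward_pass(model, fw, dlogits, dM_extra)
    gvec <- flatten_grads(g, model$params)
    gacc <- if (is.null(gacc)) gvec else gacc + gvec
  }
  list(grads = gacc, wce = wce_acc / B, sim = sim_acc / B, probs = probs)
}

#' One Adam update
#'
#' @param theta flat parameter vector.
#' @param grad flat gradient vector.
#' @param state list with `m`, `v`, `t` (use `adam_init(length(theta))`).
#' @param lr step size; `beta1`, `beta2`, `eps` standard Adam constants.
#' @return list with updated `theta` and `state`.
#' @export
adam_step <- function(theta, grad, state, lr = 3e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = state)
}

#' @rdname adam_step
#' @param n parameter count.
#' @export
adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

one_hot <- function(labels, K) {
  Q <- matrix(0, length(labels), K)
  Q[cbind(seq_along(labels), labels + 1L)] <- 1
  Q
}

train_loop <- function(train, val, model_cfg, train_cfg, priors = NULL) {
  model <- init_model(model_cfg)
  K <- model_cfg$n_classes
  labels <- vapply(train, function(s) s$label, integer(1))
  weights <- class_weights(labels, K)
  S <- if (!is.null(priors))
    prior_matrix(priors, model$geom$fdims, train_cfg$prior_scale)
  lambda <- if (is.null(priors)) 0 else train_cfg$lambda
  skel <- model$params
  theta <- flatten_params(skel)
  st <- adam_init(length(theta))
  n <- length(train)
  steps <- train_cfg$steps_per_epoch %||%
    max(1L, ceiling(n / (train_cfg$micro_batch * train_cfg$accumulation_steps)))
  history <- vector("list", train_cfg$epochs)
  best <- list(theta = theta, val_f1 = -Inf, epoch = 0L)
  step_log <- list()
  with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      ptr <- 0L
      e_wce <- 0; e_sim <- 0
      for (step in seq_len(steps)) {
        gsum <- NULL; s_wce <- 0; s_sim <- 0
        for (a in seq_len(train_cfg$accumulation_steps)) {
          take <- integer(0)
          while (length(take) < train_cfg$micro_batch) {
            if (ptr >= n) { ord <- sample.int(n); ptr <- 0L }
            ptr <- ptr + 1L
            take <- c(take, ord[ptr])
          }
          vols <- lapply(train[take], function(s) s$volume)
          Q <- one_hot(labels[take], K)
          if (train_cfg$augment) {
            vols <- lapply(vols, function(v)
              augment_volume(v, contrast = TRUE, bias_field = TRUE,
                             crop = TRUE,
                             seed = sample.int(.Machine$integer.max, 1L)))
          }
          if (train_cfg$mixup) {
            perm <- sample(length(take))
            lam <- stats::rbeta(1, train_cfg$mixup_alpha, train_cfg$mixup_alpha)
            vols <- lapply(seq_along(vols), function(i)
              lam * vols[[i]] + (1 - lam) * vols[[perm[i]]])
            Q <- lam * Q + (1 - lam) * Q[perm, , drop = FALSE]
          }
          lg <- loss_gradients(model, vols, Q, weights, S, lambda,
                               train_cfg$sim_scope, train_cfg$normalize_by_voxels)
          gsum <- if (is.null(gsum)) lg$grads else gsum + lg$grads
          s_wce <- s_wce + lg$wce; s_sim <- s_sim + lg$sim
        }
        gvec <- gsum / train_cfg$accumulation_steps
        s_wce <- s_wce / train_cfg$accumulation_steps
        s_sim <- s_sim / train_cfg$accumulation_steps
        s_total <- total_loss(s_wce, s_sim, lambda)
        if (!is.finite(s_total)) {
          stop(sprintf("training diverged at epoch %d step %d (wce=%g, sim=%g)",
                       epoch, step, s_wce, s_sim), call. = FALSE)
        }
        up <- adam_step(theta, gvec, st, lr = train_cfg$lr)
        theta <- up$theta; st <- up$state
        model$params <- utils::relist(theta, skel)
        step_log[[length(step_log) + 1L]] <-
          c(epoch = epoch, step = step, wce = s_wce, sim = s_sim,
            total = s_total)
        e_wce <- e_wce + s_wce; e_sim <- e_sim + s_sim
      }
      ev <- internal_eval(model, val, weights, S, lambda, train_cfg)
      history[[epoch]] <- data.frame(
        epoch = epoch, wce = e_wce / steps, sim = e_sim / steps,
        total = total_loss(e_wce / steps, e_sim / steps, lambda),
        val_wce = ev$wce, val_sim = ev$sim, val_macro_f1 = ev$macro_f1,
        val_accuracy = ev$accuracy)
      if (ev$macro_f1 > best$val_f1) {
        best <- list(theta = theta, val_f1 = ev$macro_f1, epoch = epoch)
      }
    }
  })
  final_model <- model
  best_model <- model
  best_model$params <- utils::relist(best$theta, skel)
  structure(list(model = best_model, final_model = final_model,
                 history = do.call(rbind, history),
                 steps = do.call(rbind, step_log),
                 best_epoch = best$epoch,
                 class_weights = weights,
                 model_config = model_cfg, train_config = train_cfg,
                 lambda = lambda,
                 prior_matrix = S),
            class = "dg_fit")
}

internal_eval <- function(model, samples, weights, S, lambda, train_cfg) {
  labels <- vapply(samples, function(s) s$label, integer(1))
  K <- model$config$n_classes
  wce <- 0; sim <- 0
  pred <- integer(length(samples))
  for (i in seq_along(samples)) {
    fw <- forward_pass(model, samples[[i]]$volume)
    wce <- wce + -weights[labels[i] + 1L] * log(max(fw$probs[labels[i] + 1L], 1e-12))
    if (!is.null(S)) {
      Dm <- fw$M - S
      d <- sqrt(colSums(Dm^2))
      if (train_cfg$normalize_by_voxels) d <- d / sqrt(nrow(Dm))
      sim <- sim + sum(d)
    }
    pred[i] <- which.max(fw$probs) - 1L
  }
  cm <- confusion(labels, pred, K)
  list(wce = wce / length(samples), sim = sim / length(samples),
       macro_f1 = macro_f1(cm), accuracy = sum(diag(cm$M)) / sum(cm$M))
}

#' Mean similarity loss of a model over a sample set
#'
#' Evaluates the stage-2 similarity objective for any model (e.g. post hoc
#' for a stage-1 baseline), using the same prior preparation as training.
#'
#' @param model a `dg_model` or `dg_fit`.
#' @param samples list of `dg_sample`s.
#' @param priors list of K `dg_prior`s.
#' @param train_cfg a [train_config()] supplying `prior_scale` and
#'   `normalize_by_voxels`.
#' @return scalar mean similarity loss.
#' @export
model_sim_loss <- function(model, samples, priors, train_cfg = train_config()) {
  if (inherits(model, "dg_fit")) model <- model$model
  S <- prior_matrix(priors, model$geom$fdims, train_cfg$prior_scale)
  vals <- vapply(samples, function(s) {
    fw <- forward_pass(model, s$volume)
    d <- sqrt(colSums((fw$M - S)^2))
    if (train_cfg$normalize_by_voxels) d <- d / sqrt(nrow(fw$M))
    sum(d)
  }, numeric(1))
  mean(vals)
}

#' Stage-1 baseline training (weighted cross-entropy only)
#'
#' @param train,val lists of `dg_sample`s.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()]; `lambda` is ignored (forced to 0).
#' @return a `dg_fit` with the best-validation-macro-F1 checkpoint in
#'   `$model`, the last state in `$final_model`, and per-epoch history.
#' @export
train_stage1 <- function(train, val, model_cfg, train_cfg) {
  train_loop(train, val, model_cfg, train_cfg, priors = NULL)
}

#' Stage-2 training with saliency-prior supervision
#'
#' Trains a fresh model (initialization governed by `model_cfg$seed`) on
#' `L_WCE + lambda * L_sim`. With `lambda = 0` this reduces exactly to
#' stage-1 training of the same model.
#'
#' @param train,val lists of `dg_sample`s.
#' @param priors list of K class priors from [build_class_priors()]; all
#'   must be present.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @return a `dg_fit`.
#' @export
train_stage2 <- function(train, val, priors, model_cfg, train_cfg) {
  for (pr in priors) {
    if (inherits(pr, "dg_prior") && isTRUE(pr$absent)) {
      stop(sprintf("prior for class %d is absent; stage-2 training cannot start",
                   pr$class_id), call. = FALSE)
    }
  }
  train_loop(train, val, model_cfg, train_cfg, priors = priors)
}
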