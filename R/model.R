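# The 3D classification model: block-average downsampling, a small stack of
# 3x3x3 convolution + ReLU layers at feature resolution (the encoder), two
# parallel 1x1x1 convolution heads producing K feature channels F' and K
# sigmoid-gated attention channels M, elementwise gating, and a global
# average pooling classifier with softmax. All activations are kept as
# voxel-major matrices (n_voxels x channels); gradients are analytic and are
# verified against finite differences in the test suite.

#' Model configuration
#'
#' @param input_shape integer (D, H, W) of input volumes; each axis must be
#'   divisible by `downsample_factor`.
#' @param n_classes number of classes K (>= 2); default 3 (NC / MCI / AD).
#' @param encoder_channels integer vector of channel widths for the encoder's
#'   convolution layers; the last entry must be >= `n_classes`.
#' @param downsample_factor integer spatial downsampling between input and
#'   feature resolution (>= 1).
#' @param attention_activation gate nonlinearity; only `"sigmoid"` is
#'   provided, so attention values are guaranteed to lie in `[0, 1]`.
#' @param seed integer seed for parameter initialization.
#' @return object of class `dg_model_config`.
#' @export
model_config <- function(input_shape, n_classes = 3L, encoder_channels = 8L,
                         downsample_factor = 4L,
                         attention_activation = "sigmoid", seed = 1L) {
  input_shape <- as.integer(input_shape)
  n_classes <- as.integer(n_classes)
  encoder_channels <- as.integer(encoder_channels)
  downsample_factor <- as.integer(downsample_factor)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (downsample_factor < 1L) stop("downsample_factor must be >= 1", call. = FALSE)
  if (any(input_shape %% downsample_factor != 0L)) {
    stop("input_shape must be divisible by downsample_factor", call. = FALSE)
  }
  if (length(encoder_channels) < 1L || encoder_channels[length(encoder_channels)] < n_classes) {
    stop("final encoder channel width must be >= n_classes", call. = FALSE)
  }
  attention_activation <- match.arg(attention_activation, "sigmoid")
  structure(list(input_shape = input_shape, n_classes = n_classes,
                 encoder_channels = encoder_channels,
                 downsample_factor = downsample_factor,
                 attention_activation = attention_activation,
                 seed = as.integer(seed)),
            class = "dg_model_config")
}

#' Initialize model parameters
#'
#' He-style Gaussian initialization, fully determined by `config$seed`.
#'
#' @param config a [model_config()].
#' @return object of class `dg_model` holding `config`, `params`, and cached
#'   geometry (pooling / convolution index tables).
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "dg_model_config"))
  fdims <- config$input_shape %/% config$downsample_factor
  K <- config$n_classes
  params <- with_seed(config$seed, {
    cin <- 1L
    enc <- list()
    for (C in config$encoder_channels) {
      enc[[length(enc) + 1L]] <- list(
        W = matrix(stats::rnorm(27L * cin * C, sd = sqrt(2 / (27 * cin))),
                   27L * cin, C),
        b = numeric(C))
      cin <- C
    }
    list(enc = enc,
         Wf = matrix(stats::rnorm(cin * K, sd = sqrt(2 / cin)), cin, K),
         bf = numeric(K),
         Wm = matrix(stats::rnorm(cin * K, sd = sqrt(2 / cin)), cin, K),
         bm = numeric(K))
  })
  structure(list(config = config, params = params,
                 geom = list(fdims = fdims,
                             pidx = pool_index(config$input_shape,
                                               config$downsample_factor),
                             ci = conv_indices(fdims))),
            class = "dg_model")
}

check_volume <- function(model, volume) {
  if (!identical(as.integer(dim(volume)), model$config$input_shape)) {
    stop(sprintf("volume shape (%s) does not match model input shape (%s)",
                 paste(dim(volume), collapse = "x"),
                 paste(model$config$input_shape, collapse = "x")), call. = FALSE)
  }
  stopifnot_finite(volume, "input volume")
}

# Full forward pass; cache holds everything backward needs.
forward_pass <- function(model, volume) {
  check_volume(model, volume)
  p <- model$params
  # intensities arrive in [0, 1]; centre at 0 so the zero-mean weight
  # initialization sees a zero-mean input
  v <- avg_pool3(volume, model$geom$pidx) - 0.5
  X <- matrix(v, ncol = 1L)
  acts <- list(X)   # inputs to each conv layer
  Zs <- list(); Ps <- list()
  for (l in seq_along(p$enc)) {
    cf <- conv3_forward(X, p$enc[[l]]$W, p$enc[[l]]$b, model$geom$ci)
    Zs[[l]] <- cf$Z; Ps[[l]] <- cf$P
    X <- cf$Z * (cf$Z > 0)
    acts[[l + 1L]] <- X
  }
  n <- nrow(X)
  Fp <- X %*% p$Wf + rep(p$bf, each = n)
  A  <- X %*% p$Wm + rep(p$bm, each = n)
  M  <- stats::plogis(A)
  Tm <- Fp * M
  logits <- colMeans(Tm)
  probs <- softmax(logits)
  list(probs = probs, logits = logits, M = M, Fp = Fp, Tm = Tm,
       features = X, acts = acts, Zs = Zs, Ps = Ps, n = n)
}

# Backward pass from a gradient on the logits (length K) and an optional
# extra gradient on the attention matrix M (n x K, e.g. from the similarity
# loss). Returns parameter gradients and, optionally, the gradient with
# respect to the input volume.
backward_pass <- function(model, fw, dlogits, dM_extra = NULL,
                          input_grad = FALSE) {
  p <- model$params
  n <- fw$n
  K <- model$config$n_classes
  dT <- matrix(rep(dlogits / n, each = n), n, K)
  dFp <- dT * fw$M
  dM <- dT * fw$Fp
  if (!is.null(dM_extra)) dM <- dM + dM_extra
  dA <- dM * fw$M * (1 - fw$M)
  X <- fw$features
  g <- list(Wf = crossprod(X, dFp), bf = colSums(dFp),
            Wm = crossprod(X, dA), bm = colSums(dA))
  dX <- tcrossprod(dFp, p$Wf) + tcrossprod(dA, p$Wm)
  genc <- vector("list", length(p$enc))
  for (l in rev(seq_along(p$enc))) {
    dZ <- dX * (fw$Zs[[l]] > 0)
    cb <- conv3_backward(dZ, fw$Ps[[l]], p$enc[[l]]$W, model$geom$ci,
                         ncol(fw$acts[[l]]))
    genc[[l]] <- list(W = cb$dW, b = cb$db)
    dX <- cb$dX
  }
  g$enc <- genc
  if (input_grad) {
    g$dinput <- avg_pool3_backward(dX[, 1L], model$geom$pidx)
  }
  g
}

#' Encode a volume into a feature stack
#'
#' Runs the downsampling and convolutional encoder only.
#'
#' @param model a `dg_model`.
#' @param volume 3D numeric array matching the model's input shape.
#' @return object of class `dg_features`: list with `mat` (n_voxels x C
#'   matrix), `dims` (feature grid shape), `channels`.
#' @export
encode <- function(model, volume) {
  fw <- forward_pass(model, volume)
  structure(list(mat = fw$features, dims = model$geom$fdims,
                 channels = ncol(fw$features)),
            class = "dg_features")
}

#' Apply the class-wise attention module
#'
#' Computes `F' = conv1x1(F)`, gates `M = sigmoid(conv1x1(F))`, and the
#' attended features `F' * M` (elementwise). All three are returned.
#'
#' @param model a `dg_model`.
#' @param features a `dg_features` from [encode()].
#' @return list with `fprime`, `attention` (class `dg_attention`, values in
#'   `[0, 1]`), and `attended`, all `dg_features`-like with K channels.
#' @export
attend <- function(model, features) {
  stopifnot(inherits(features, "dg_features"))
  p <- model$params
  if (ncol(features$mat) != nrow(p$Wf)) {
    stop(sprintf("feature stack has %d channels, model expects %d",
                 ncol(features$mat), nrow(p$Wf)), call. = FALSE)
  }
  n <- nrow(features$mat)
  Fp <- features$mat %*% p$Wf + rep(p$bf, each = n)
  M <- stats::plogis(features$mat %*% p$Wm + rep(p$bm, each = n))
  mk <- function(m, cls) structure(list(mat = m, dims = features$dims,
                                        channels = ncol(m)), class = cls)
  list(fprime = mk(Fp, "dg_features"),
       attention = mk(M, c("dg_attention", "dg_features")),
       attended = mk(Fp * M, "dg_features"))
}

#' Global-average-pooling classifier
#'
#' Each of the K attended channels is averaged over its spatial extent to one
#' logit; probabilities are the softmax of the logits.
#'
#' @param attended K-channel `dg_features` (or a K x d x h x w array).
#' @return list with `probs` (length-K, sums to 1), `logits`.
#' @export
classify <- function(attended) {
  m <- if (inherits(attended, "dg_features")) attended$mat
       else if (is.array(attended) && length(dim(attended)) == 4L) {
         matrix(aperm(attended, c(2, 3, 4, 1)), ncol = dim(attended)[1])
       } else stop("attended must be dg_features or a 4D (K,d,h,w) array", call. = FALSE)
  logits <- colMeans(m)
  list(probs = softmax(logits), logits = logits)
}

#' Convert a feature/attention stack to a (C, d, h, w) array
#'
#' @param x a `dg_features` or `dg_attention`.
#' @param ... unused.
#' @return 4D array, channel-first.
#' @export
as.array.dg_features <- function(x, ...) {
  aperm(array(x$mat, dim = c(x$dims, x$channels)), c(4, 1, 2, 3))
}

#' @export
as.array.dg_attention <- function(x, ...) NextMethod()

#' Attention maps for a volume
#'
#' @param model a trained `dg_model`.
#' @param volume input volume.
#' @return K x d x h x w array of attention values in `[0, 1]`.
#' @export
attention_maps <- function(model, volume) {
  fw <- forward_pass(model, volume)
  aperm(array(fw$M, dim = c(model$geom$fdims, model$config$n_classes)),
        c(4, 1, 2, 3))
}

#' Class probabilities for a set of volumes
#'
#' @param model a `dg_model`.
#' @param volumes a list of 3D arrays, or a single 3D array.
#' @return N x K matrix of class probabilities.
#' @export
predict_classes <- function(model, volumes) {
  if (is.array(volumes) && length(dim(volumes)) == 3L) volumes <- list(volumes)
  t(vapply(volumes, function(v) forward_pass(model, v)$probs,
           numeric(model$config$n_classes)))
}
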