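# Evaluation: confusion matrix (rows = true class, columns = predicted),
# macro F1, multiclass Matthews correlation coefficient, and the stratified
# k-fold harness with a 3:1:1 train/validation/test split.

#' Confusion matrix
#'
#' Orientation is fixed: `M[i, j]` counts samples of true class `i - 1`
#' predicted as class `j - 1`.
#'
#' @param labels,predictions integer vectors in `0..K-1`, equal length.
#' @param n_classes K.
#' @return object of class `dg_confusion`: list with `M` (K x K integer
#'   matrix), `K`, and derived totals `t` (true occurrences), `p` (predicted
#'   occurrences), `c` (correct), `s` (total).
#' @export
confusion <- function(labels, predictions, n_classes) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  K <- as.integer(n_classes)
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have equal length", call. = FALSE)
  }
  if (any(c(labels, predictions) < 0L) || any(c(labels, predictions) >= K)) {
    stop("class ids must lie in 0..K-1", call. = FALSE)
  }
  M <- matrix(0L, K, K)
  for (i in seq_along(labels)) {
    M[labels[i] + 1L, predictions[i] + 1L] <- M[labels[i] + 1L, predictions[i] + 1L] + 1L
  }
  structure(list(M = M, K = K,
                 t = rowSums(M), p = colSums(M),
                 c = sum(diag(M)), s = sum(M)),
            class = "dg_confusion")
}

as_confusion <- function(cm) {
  if (inherits(cm, "dg_confusion")) return(cm)
  M <- as.matrix(cm)
  structure(list(M = M, K = nrow(M), t = rowSums(M), p = colSums(M),
                 c = sum(diag(M)), s = sum(M)), class = "dg_confusion")
}

#' Macro F1 score
#'
#' Per class, precision = `M_kk / p_k` and recall = `M_kk / t_k`;
#' `F1_k = 2 P R / (P + R)`, taken as 0 when `P + R = 0` (or when the class
#' was never predicted / never occurred). Macro F1 is the mean of the K
#' per-class F1 scores and lies in `[0, 1]`.
#'
#' @param cm a [confusion()] result or a plain K x K matrix (rows = true).
#' @return scalar in `[0, 1]`.
#' @export
macro_f1 <- function(cm) {
  cm <- as_confusion(cm)
  f1 <- vapply(seq_len(cm$K), function(k) {
    prec <- if (cm$p[k] > 0) cm$M[k, k] / cm$p[k] else 0
    rec  <- if (cm$t[k] > 0) cm$M[k, k] / cm$t[k] else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

#' Multiclass Matthews correlation coefficient
#'
#' `(c s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' with `t_k`, `p_k`, `c`, `s` the true/predicted occurrence counts, correct
#' total and grand total; defined as 0 when either factor under the square
#' root is 0 (e.g. all predictions in one class).
#'
#' @param cm a [confusion()] result or a plain K x K matrix (rows = true).
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  cm <- as_confusion(cm)
  s <- cm$s; c0 <- cm$c
  num <- c0 * s - sum(cm$p * cm$t)
  d1 <- s^2 - sum(cm$p^2)
  d2 <- s^2 - sum(cm$t^2)
  if (d1 <= 0 || d2 <= 0) return(0)
  num / sqrt(d1 * d2)
}

#' Stratified k-fold split plan with a 3:1:1 ratio
#'
#' Samples of each class are shuffled (seeded) and distributed over k folds
#' with near-equal per-class counts (surplus samples spread over
#' non-adjacent folds so every train/val/test partition stays stratified to
#' within one sample per class). Fold `f` is the test set, fold `f + 1`
#' (cyclically) the validation set, and the remaining `k - 2` folds the
#' training set — for `k = 5` exactly the 3:1:1 split.
#'
#' @param labels integer class labels in `0..K-1`.
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return object of class `dg_splitplan`: list of k folds, each with
#'   `train`, `val`, `test` integer index vectors (1-based).
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(counts < k)) {
    stop(sprintf("class %s has fewer than k = %d members",
                 paste(classes[counts < k], collapse = ", "), k), call. = FALSE)
  }
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      nc <- length(idx)
      base <- nc %/% k; r <- nc %% k
      sizes <- rep(base, k)
      if (r > 0L) {
        # spread the r surplus samples over maximally separated folds
        extra_pos <- unique(floor((0:(r - 1)) * k / r)) + 1L
        extra_pos <- extra_pos[seq_len(min(r, length(extra_pos)))]
        if (length(extra_pos) < r) {
          extra_pos <- c(extra_pos, setdiff(seq_len(k), extra_pos)[seq_len(r - length(extra_pos))])
        }
        sizes[extra_pos] <- sizes[extra_pos] + 1L
      }
      stopifnot(sum(sizes) == nc)
      f <- rep(seq_len(k), times = sizes)
      fold_of[idx] <- f
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold_of == f)
    val <- which(fold_of == (f %% k) + 1L)
    train <- which(!(fold_of %in% c(f, (f %% k) + 1L)))
    list(train = train, val = val, test = test)
  })
  structure(list(folds = folds, k = k, labels = labels, seed = as.integer(seed)),
            class = "dg_splitplan")
}

#' Evaluate a model on a labelled sample set
#'
#' @param model a `dg_model` or `dg_fit`.
#' @param samples list of `dg_sample`s.
#' @return list with `labels`, `pred`, `probs`, `cm`, `accuracy`,
#'   `macro_f1`, `mcc`.
#' @export
evaluate_model <- function(model, samples) {
  if (inherits(model, "dg_fit")) model <- model$model
  labels <- vapply(samples, function(s) s$label, integer(1))
  probs <- predict_classes(model, lapply(samples, function(s) s$volume))
  pred <- apply(probs, 1L, function(p) which(p == max(p))[1] - 1L)
  cm <- confusion(labels, pred, model$config$n_classes)
  list(labels = labels, pred = pred, probs = probs, cm = cm,
       accuracy = cm$c / cm$s, macro_f1 = macro_f1(cm), mcc = mcc(cm))
}

#' Aggregate per-fold metrics as mean and standard deviation
#'
#' @param metric_rows data frame with one row per fold and numeric metric
#'   columns.
#' @return data frame with `metric`, `mean`, `sd`.
#' @export
aggregate_folds <- function(metric_rows) {
  num <- vapply(metric_rows, is.numeric, logical(1))
  cols <- names(metric_rows)[num]
  data.frame(metric = cols,
             mean = vapply(cols, function(cn) mean(metric_rows[[cn]]), numeric(1)),
             sd = vapply(cols, function(cn) stats::sd(metric_rows[[cn]]), numeric(1)),
             row.names = NULL)
}
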