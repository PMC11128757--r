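# Low-level tensor primitives for the 3D model: average pooling, im2col
# 3x3x3 convolution with zero padding, and trilinear resampling. All are
# plain double-precision base R; shapes are small (feature grids of a few
# hundred voxels) so matrix products dominate and loops are avoided.

# Map each full-resolution voxel to the linear index of its pooling block.
pool_index <- function(dims, f) {
  dims <- as.integer(dims); f <- as.integer(f)
  if (any(dims %% f != 0L)) {
    stop(sprintf("volume dims (%s) not divisible by downsample factor %d",
                 paste(dims, collapse = "x"), f), call. = FALSE)
  }
  dd <- dims %/% f
  p1 <- rep(seq_len(dd[1]), each = f)
  p2 <- rep(seq_len(dd[2]), each = f)
  p3 <- rep(seq_len(dd[3]), each = f)
  idx <- outer(outer(p1, (p2 - 1L) * dd[1], "+"), (p3 - 1L) * dd[1] * dd[2], "+")
  storage.mode(idx) <- "integer"
  list(idx = idx, pooled_dims = dd, f = f)
}

# Block-average pooling; returns a vector in pooled linear order.
avg_pool3 <- function(x, pidx) {
  if (pidx$f == 1L) return(as.vector(x))
  as.vector(rowsum(as.vector(x), as.vector(pidx$idx), reorder = TRUE)) / pidx$f^3
}

# Backward of avg_pool3: spread pooled-gradient evenly over each block.
avg_pool3_backward <- function(dv, pidx) {
  array(dv[as.vector(pidx$idx)] / pidx$f^3, dim = dim(pidx$idx))
}

# Precomputed gather indices for a same-padded 3x3x3 convolution over a
# d x h x w grid: idx[v, o] is the linear index into the zero-padded grid of
# neighbour o of voxel v; interior[v] maps voxel v into the padded grid.
conv_indices <- function(dims) {
  dims <- as.integer(dims)
  d <- dims[1]; h <- dims[2]; w <- dims[3]
  pd <- dims + 2L
  coord <- as.matrix(expand.grid(i = seq_len(d), j = seq_len(h), k = seq_len(w)))
  off <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
  n <- nrow(coord)
  idx <- matrix(0L, n, 27L)
  for (o in seq_len(27L)) {
    ii <- coord[, 1] + 1L + off[o, 1]
    jj <- coord[, 2] + 1L + off[o, 2]
    kk <- coord[, 3] + 1L + off[o, 3]
    idx[, o] <- ii + (jj - 1L) * pd[1] + (kk - 1L) * pd[1] * pd[2]
  }
  interior <- coord[, 1] + 1L + coord[, 2] * pd[1] + coord[, 3] * pd[1] * pd[2]
  list(idx = idx, interior = interior, pdims = pd, n = n, dims = dims)
}

# X: n x Cin voxel-major activation matrix -> patch matrix n x (27*Cin).
im2col <- function(X, ci) {
  Cin <- ncol(X)
  P <- matrix(0, ci$n, 27L * Cin)
  pad <- numeric(prod(ci$pdims))
  for (c in seq_len(Cin)) {
    pad[] <- 0
    pad[ci$interior] <- X[, c]
    P[, ((c - 1L) * 27L + 1L):(c * 27L)] <- pad[ci$idx]
  }
  P
}

# Scatter patch-gradients back to the activation grid (transpose of im2col).
col2im <- function(dP, ci, Cin) {
  dX <- matrix(0, ci$n, Cin)
  npad <- prod(ci$pdims)
  for (c in seq_len(Cin)) {
    block <- dP[, ((c - 1L) * 27L + 1L):(c * 27L), drop = FALSE]
    s <- rowsum(as.vector(block), as.vector(ci$idx))
    dpad <- numeric(npad)
    dpad[as.integer(rownames(s))] <- s[, 1]
    dX[, c] <- dpad[ci$interior]
  }
  dX
}

conv3_forward <- function(X, W, b, ci) {
  P <- im2col(X, ci)
  Z <- P %*% W
  Z <- Z + rep(b, each = nrow(Z))
  list(Z = Z, P = P)
}

conv3_backward <- function(dZ, P, W, ci, Cin) {
  list(dW = crossprod(P, dZ),
       db = colSums(dZ),
       dX = col2im(tcrossprod(dZ, W), ci, Cin))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Trilinear resampling of a 3D grid
#'
#' Resamples a scalar grid to a new shape using centre-aligned trilinear
#' interpolation (edge-clamped). Constant grids map to constant grids and a
#' linear ramp stays a linear ramp, so the operation is exact for the
#' low-order structure that matters when bridging input-space saliency priors
#' and feature-space attention resolutions.
#'
#' @param x 3D numeric array.
#' @param target_shape integer vector of length 3.
#' @return 3D numeric array with dim `target_shape`.
#' @export
resample_trilinear <- function(x, target_shape) {
  sd <- dim(x)
  td <- as.integer(target_shape)
  if (length(sd) != 3L || length(td) != 3L || any(td < 1L)) {
    stop("resample_trilinear expects a 3D array and a positive length-3 shape", call. = FALSE)
  }
  axis_coord <- function(nt, ns) {
    cc <- (seq_len(nt) - 0.5) * ns / nt - 0.5
    pmin(pmax(cc, 0), ns - 1)
  }
  cs <- lapply(1:3, function(a) axis_coord(td[a], sd[a]))
  lo <- lapply(1:3, function(a) pmin(floor(cs[[a]]), sd[a] - 1))
  fr <- lapply(1:3, function(a) cs[[a]] - lo[[a]])
  i0 <- lapply(1:3, function(a) as.integer(lo[[a]]) + 1L)
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1L, sd[a]))
  out <- array(0, dim = td)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wi <- if (a == 0) 1 - fr[[1]] else fr[[1]]
    wj <- if (b == 0) 1 - fr[[2]] else fr[[2]]
    wk <- if (cc == 0) 1 - fr[[3]] else fr[[3]]
    w <- outer(outer(wi, wj), wk)
    ii <- if (a == 0) i0[[1]] else i1[[1]]
    jj <- if (b == 0) i0[[2]] else i1[[2]]
    kk <- if (cc == 0) i0[[3]] else i1[[3]]
    out <- out + w * x[ii, jj, kk, drop = FALSE]
  }
  out
}
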