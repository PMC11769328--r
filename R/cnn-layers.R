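# Convolution and attention primitives for the hybrid 3D/2D network.
#
# Batched tensors are stored as 5-D arrays [H, W, D, C, N] (height, width,
# spectral depth, channels, batch). Convolutions are valid-mode correlations
# implemented by im2col: patch extraction into a matrix followed by one
# matrix multiplication, with the same index table reused for the backward
# scatter.

# index table mapping output positions x kernel offsets to flat input
# positions, for input dims (H, W, D, C) and kernel (kh, kw, kd)
im2col_index <- function(dims, kshape, n_batch) {
  H <- dims[1L]; W <- dims[2L]; D <- dims[3L]; C <- dims[4L]
  kh <- kshape[1L]; kw <- kshape[2L]; kd <- kshape[3L]
  Ho <- H - kh + 1L; Wo <- W - kw + 1L; Do <- D - kd + 1L
  if (Ho < 1L || Wo < 1L || Do < 1L)
    stop("kernel ", paste(kshape, collapse = "x"), " does not fit input ",
         paste(dims[1:3], collapse = "x"))
  pos <- as.vector(outer(outer(0:(Ho - 1L), H * (0:(Wo - 1L)), "+"),
                         H * W * (0:(Do - 1L)), "+"))
  off <- as.vector(outer(outer(outer(0:(kh - 1L), H * (0:(kw - 1L)), "+"),
                               H * W * (0:(kd - 1L)), "+"),
                         H * W * D * (0:(C - 1L)), "+"))
  idx <- outer(pos, off, "+") + 1L
  stride <- H * W * D * C
  if (n_batch > 1L) {
    idx <- do.call(rbind, lapply(0:(n_batch - 1L), function(n) idx + n * stride))
  }
  list(idx = idx, out_dims = c(Ho, Wo, Do), n_pos = Ho * Wo * Do)
}

# cache of index tables (keyed by shape signature); cleared per fit
new_idx_cache <- function() new.env(parent = emptyenv())
get_im2col <- function(cache, dims, kshape, n_batch) {
  key <- paste(c(dims, kshape, n_batch), collapse = "_")
  if (is.null(cache[[key]])) cache[[key]] <- im2col_index(dims, kshape, n_batch)
  cache[[key]]
}

# X5: [H, W, D, C, N]; kernel: [kh, kw, kd, Cin, Cout]; returns out5 + cache
conv3d_forward <- function(X5, kernel, bias, cache, idx_cache) {
  d <- dim(X5)
  kd <- dim(kernel)
  im <- get_im2col(idx_cache, d[1:4], kd[1:3], d[5L])
  cols <- matrix(X5[im$idx], nrow(im$idx), ncol(im$idx))
  Wmat <- matrix(kernel, ncol = kd[5L])
  out <- cols %*% Wmat
  out <- sweep(out, 2L, bias, "+")
  od <- im$out_dims
  out5 <- aperm(array(out, c(od, d[5L], kd[5L])), c(1L, 2L, 3L, 5L, 4L))
  list(out = out5, cols = cols, im = im, in_dims = d, kdim = kd)
}

conv3d_backward <- function(dOut5, fwd, kernel) {
  kd <- fwd$kdim
  od <- fwd$im$out_dims
  N <- fwd$in_dims[5L]
  dmat <- matrix(aperm(dOut5, c(1L, 2L, 3L, 5L, 4L)), ncol = kd[5L])
  dW <- crossprod(fwd$cols, dmat)
  db <- colSums(dmat)
  Wmat <- matrix(kernel, ncol = kd[5L])
  dCols <- tcrossprod(dmat, Wmat)
  dXflat <- rowsum(as.vector(dCols), group = as.vector(fwd$im$idx))
  dX5 <- array(dXflat, dim = fwd$in_dims)
  list(dX = dX5, dW = array(dW, dim = kd), db = db)
}

relu <- function(x) { x[x < 0] <- 0; x }

# channel gate shared by global attention and squeeze-excitation:
# per-channel pooled mean -> bottleneck dense (ReLU) -> dense (sigmoid) ->
# channel-wise rescaling of the input
gate_forward <- function(X5, W1, b1, W2, b2) {
  d <- dim(X5)
  spatial <- prod(d[1:3])
  Xmat <- matrix(X5, nrow = spatial)           # [HWD, C*N]
  G <- matrix(colMeans(Xmat), d[4L], d[5L])    # [C, N]
  h1 <- relu(W1 %*% G + b1)
  A <- 1 / (1 + exp(-(W2 %*% h1 + b2)))        # [C, N]
  out <- array(sweep(Xmat, 2L, as.vector(A), "*"), dim = d)
  list(out = out, G = G, h1 = h1, A = A, in_dims = d)
}

gate_backward <- function(dOut5, fwd, X5, W1, W2) {
  d <- fwd$in_dims
  spatial <- prod(d[1:3])
  dOmat <- matrix(dOut5, nrow = spatial)
  Xmat <- matrix(X5, nrow = spatial)
  Avec <- as.vector(fwd$A)
  dX <- sweep(dOmat, 2L, Avec, "*")
  dA <- matrix(colSums(dOmat * Xmat), d[4L], d[5L])
  dz2 <- dA * fwd$A * (1 - fwd$A)
  dW2 <- tcrossprod(dz2, fwd$h1)
  db2 <- rowSums(dz2)
  dh1 <- crossprod(W2, dz2)
  dz1 <- dh1 * (fwd$h1 > 0)
  dW1 <- tcrossprod(dz1, fwd$G)
  db1 <- rowSums(dz1)
  dG <- crossprod(W1, dz1)
  dX <- dX + matrix(rep(as.vector(dG), each = spatial), nrow = spatial) / spatial
  list(dX = array(dX, dim = d), dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Reference valid-mode 3D convolution
#'
#' The dot product of kernel weights and each local region of the input
#' volume: output voxel (x, y, z) is `sum(V[x:(x+a-1), y:(y+b-1), z:(z+c-1)]
#' * K)` for an a x b x c kernel, so each output axis shrinks to
#' `in - kernel + 1`. This is the elementary operation the network's 3-D
#' layers apply per input channel and filter.
#'
#' @param volume 3-D numeric array.
#' @param kernel 3-D numeric array, no larger than `volume` on any axis.
#' @return 3-D array of dimension `dim(volume) - dim(kernel) + 1`.
#' @export
conv3d_reference <- function(volume, kernel) {
  dv <- dim(volume); dk <- dim(kernel)
  if (length(dv) != 3L || length(dk) != 3L) stop("volume and kernel must be 3-D arrays")
  if (any(dk > dv)) stop("kernel larger than volume")
  X5 <- array(volume, dim = c(dv, 1L, 1L))
  K5 <- array(kernel, dim = c(dk, 1L, 1L))
  fwd <- conv3d_forward(X5, K5, 0, cache = NULL, idx_cache = new_idx_cache())
  array(fwd$out, dim = dv - dk + 1L)
}

#' Global channel attention over a 4-D feature map
#'
#' Pools a H x W x D x C feature map to one value per channel (mean over
#' height, width and spectral depth), passes the pooled vector through a
#' bottleneck dense layer (ReLU) and an expansion dense layer (sigmoid), and
#' rescales each channel of the input by its attention weight in (0, 1).
#' With all weights and biases zero the gate is sigmoid(0) = 0.5 and the
#' output is exactly half the input.
#'
#' @param I numeric array `[H, W, D, C]`.
#' @param weights `list(W1, b1, W2, b2)` with `W1` of shape `C/2 x C` and
#'   `W2` of shape `C x C/2` (biases of matching length).
#' @return Array of the same shape as `I`.
#' @export
global_attention <- function(I, weights) {
  d <- dim(I)
  if (length(d) != 4L) stop("I must be a H x W x D x C array")
  C <- d[4L]
  if (!all(dim(weights$W1) == c(C %/% 2L, C)) ||
      !all(dim(weights$W2) == c(C, C %/% 2L)))
    stop("weight shapes must be W1: C/2 x C and W2: C x C/2")
  fwd <- gate_forward(array(I, dim = c(d, 1L)), weights$W1, weights$b1,
                      weights$W2, weights$b2)
  array(fwd$out, dim = d)
}

#' Squeeze-and-excitation gate over a 2-D feature map
#'
#' Squeezes a H x W x C map to per-channel means, passes them through a
#' reduction dense layer (ReLU, C/reduction units) and an expansion layer
#' (sigmoid), and rescales each channel by its gate in (0, 1).
#'
#' @param F numeric array `[H, W, C]`.
#' @param weights `list(W1, b1, W2, b2)` with `W1` of shape `C/reduction x C`
#'   and `W2` of shape `C x C/reduction`.
#' @param reduction bottleneck reduction ratio (must divide C; default 2).
#' @return Array of the same shape as `F`.
#' @export
squeeze_excite <- function(F, weights, reduction = 2L) {
  d <- dim(F)
  if (length(d) != 3L) stop("F must be a H x W x C array")
  C <- d[3L]
  if (C %% reduction != 0L) stop("reduction must divide the channel count")
  cr <- as.integer(C %/% reduction)
  if (!all(dim(weights$W1) == c(cr, C)) || !all(dim(weights$W2) == c(C, cr)))
    stop("weight shapes must be W1: C/r x C and W2: C x C/r")
  fwd <- gate_forward(array(F, dim = c(d[1L], d[2L], 1L, d[3L], 1L)),
                      weights$W1, weights$b1, weights$W2, weights$b2)
  array(fwd$out, dim = d)
}

#' Fit a PCA reducer on pixel spectra
#'
#' Treats every pixel as an observation in band space and finds the top-K
#' principal components, so cubes can be reduced from C bands to K channels
#' while preserving spatial structure.
#'
#' @param pixels observations x bands numeric matrix.
#' @param K number of components to keep, `<= ncol(pixels)`.
#' @return An object of class `pca_reducer` with the K x C basis, per-band
#'   means and per-component explained variance fractions (non-increasing).
#' @export
fit_pca <- function(pixels, K) {
  pixels <- as.matrix(pixels)
  if (K > ncol(pixels)) stop("K (", K, ") exceeds band count (", ncol(pixels), ")")
  pc <- stats::prcomp(pixels, center = TRUE, scale. = FALSE, rank. = K)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(rotation = pc$rotation[, seq_len(K), drop = FALSE],
                 center = pc$center, K = K,
                 explained_variance = ev[seq_len(K)]),
            class = "pca_reducer")
}

#' Project a cube onto fitted principal components
#'
#' @param x a H x W x C array, a [spectral_cube()], or a H x W x C x N patch
#'   batch.
#' @param reducer a [fit_pca()] object fitted on C bands.
#' @return Array with the band axis replaced by K component scores.
#' @export
apply_pca <- function(x, reducer) {
  stopifnot(inherits(reducer, "pca_reducer"))
  arr <- if (inherits(x, "spectral_cube")) x$data else x
  d <- dim(arr)
  C <- nrow(reducer$rotation)
  if (length(d) == 3L) {
    if (d[3L] != C) stop("band count mismatch")
    m <- matrix(arr, ncol = C)
    sc <- sweep(m, 2L, reducer$center) %*% reducer$rotation
    array(sc, dim = c(d[1:2], reducer$K))
  } else if (length(d) == 4L) {
    if (d[3L] != C) stop("band count mismatch")
    m <- matrix(aperm(arr, c(1L, 2L, 4L, 3L)), ncol = C)
    sc <- sweep(m, 2L, reducer$center) %*% reducer$rotation
    aperm(array(sc, dim = c(d[1:2], d[4L], reducer$K)), c(1L, 2L, 4L, 3L))
  } else stop("x must be a 3-D or 4-D array")
}
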