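#' Named 3-D kernel-size sets
#'
#' The three kernel-size sets explored for the network's 3-D layers, plus a
#' `"compact"` set for small spectral depths (e.g. K = 8 after PCA), where
#' the named sets would exhaust the depth axis.
#'
#' @param set 1, 2, 3 or `"compact"`.
#' @return List of three `c(kh, kw, kd)` kernel shapes (layers 1-3).
#' @export
kernel_set <- function(set = 1L) {
  if (identical(set, "compact"))
    return(list(c(3L, 3L, 3L), c(3L, 3L, 3L), c(3L, 3L, 3L)))
  switch(as.integer(set),
         list(c(3L, 3L, 7L), c(3L, 3L, 5L), c(3L, 3L, 3L)),
         list(c(3L, 3L, 11L), c(3L, 3L, 9L), c(3L, 3L, 7L)),
         list(c(5L, 5L, 15L), c(5L, 5L, 11L), c(5L, 5L, 9L)),
         stop("set must be 1, 2, 3 or \"compact\""))
}

#' Architecture specification for the hybrid 3D/2D network
#'
#' Declares one of the three network variants: the base hybrid (three 3-D
#' convolution layers, one 2-D convolution layer, two dense layers, task
#' head), the variant with a global-attention gate after the 3-D block, and
#' the variant adding a squeeze-and-excitation gate after the 2-D layer.
#'
#' @param variant `"base"`, `"global_attention"` or `"global_attention_se"`.
#' @param kernels list of three 3-D kernel shapes (see [kernel_set()]).
#' @param conv3d_filters filter counts of the three 3-D layers.
#' @param conv2d_filters filter count of the 2-D layer.
#' @param dense_units widths of the two dense layers.
#' @param task `"regression"` (1 linear output) or `"classification"`
#'   (n_classes softmax outputs).
#' @param n_classes classification classes (default 3: low/medium/high).
#' @param se_reduction squeeze-excite bottleneck ratio (default 2).
#' @return An `arch_spec` list.
#' @export
arch_spec <- function(variant = c("base", "global_attention", "global_attention_se"),
                      kernels = kernel_set(1L), conv3d_filters = c(8L, 16L, 32L),
                      conv2d_filters = 64L, dense_units = c(256L, 128L),
                      task = c("regression", "classification"),
                      n_classes = 3L, se_reduction = 2L) {
  variant <- match.arg(variant)
  task <- match.arg(task)
  stopifnot(length(kernels) == 3L, length(conv3d_filters) == 3L,
            length(dense_units) == 2L)
  structure(list(variant = variant, kernels = kernels,
                 conv3d_filters = as.integer(conv3d_filters),
                 conv2d_filters = as.integer(conv2d_filters),
                 dense_units = as.integer(dense_units), task = task,
                 n_classes = as.integer(n_classes),
                 se_reduction = as.integer(se_reduction)),
            class = "arch_spec")
}

# shape arithmetic through the conv stack; errors if any axis is exhausted
hybridsn_shapes <- function(arch, input_dims) {
  d <- as.integer(input_dims)  # H, W, D
  shapes <- list()
  for (l in 1:3) {
    k <- arch$kernels[[l]]
    d <- c(d[1L] - k[1L] + 1L, d[2L] - k[2L] + 1L, d[3L] - k[3L] + 1L)
    if (any(d < 1L))
      stop("kernel set incompatible with input: axis exhausted at 3-D layer ", l,
           " (", paste(d, collapse = "x"), ")")
    shapes[[l]] <- d
  }
  d2 <- c(d[1L] - 2L, d[2L] - 2L)
  if (any(d2 < 1L)) stop("input too small for the 2-D convolution layer")
  list(conv3d = shapes, conv2d_in_channels = d[3L] * arch$conv3d_filters[3L],
       conv2d_out = d2, flat = prod(d2) * arch$conv2d_filters)
}

init_params <- function(arch, input_dims) {
  sh <- hybridsn_shapes(arch, input_dims)
  gauss <- function(...) {
    dims <- c(...)
    array(stats::rnorm(prod(dims)), dim = dims)
  }
  he <- function(fan_in) sqrt(2 / fan_in)
  p <- list()
  cin <- 1L
  for (l in 1:3) {
    k <- arch$kernels[[l]]; cout <- arch$conv3d_filters[l]
    p[[paste0("c", l, "W")]] <- gauss(k[1L], k[2L], k[3L], cin, cout) * he(prod(k) * cin)
    p[[paste0("c", l, "b")]] <- numeric(cout)
    cin <- cout
  }
  f3 <- arch$conv3d_filters[3L]
  if (arch$variant != "base") {
    cr <- f3 %/% 2L
    p$attW1 <- matrix(stats::rnorm(cr * f3), cr, f3) * he(f3)
    p$attb1 <- numeric(cr)
    p$attW2 <- matrix(stats::rnorm(f3 * cr), f3, cr) * he(cr)
    p$attb2 <- numeric(f3)
  }
  c2in <- sh$conv2d_in_channels
  p$c4W <- gauss(3L, 3L, 1L, c2in, arch$conv2d_filters) * he(9 * c2in)
  p$c4b <- numeric(arch$conv2d_filters)
  if (arch$variant == "global_attention_se") {
    C <- arch$conv2d_filters; cr <- C %/% arch$se_reduction
    p$seW1 <- matrix(stats::rnorm(cr * C), cr, C) * he(C)
    p$seb1 <- numeric(cr)
    p$seW2 <- matrix(stats::rnorm(C * cr), C, cr) * he(cr)
    p$seb2 <- numeric(C)
  }
  p$d1W <- matrix(stats::rnorm(arch$dense_units[1L] * sh$flat),
                  arch$dense_units[1L], sh$flat) * he(sh$flat)
  p$d1b <- numeric(arch$dense_units[1L])
  p$d2W <- matrix(stats::rnorm(prod(arch$dense_units)),
                  arch$dense_units[2L], arch$dense_units[1L]) * he(arch$dense_units[1L])
  p$d2b <- numeric(arch$dense_units[2L])
  k_out <- if (arch$task == "regression") 1L else arch$n_classes
  p$hW <- matrix(stats::rnorm(k_out * arch$dense_units[2L]),
                 k_out, arch$dense_units[2L]) * he(arch$dense_units[2L])
  p$hb <- numeric(k_out)
  p
}

forward_net <- function(arch, p, X5, idx_cache, keep_cache = TRUE) {
  cache <- list(X0 = X5)
  A <- X5
  for (l in 1:3) {
    f <- conv3d_forward(A, p[[paste0("c", l, "W")]], p[[paste0("c", l, "b")]],
                        NULL, idx_cache)
    Z <- f$out
    A <- relu(Z)
    if (keep_cache) cache[[paste0("conv", l)]] <- list(fwd = f, Z = Z)
  }
  if (arch$variant != "base") {
    g <- gate_forward(A, p$attW1, p$attb1, p$attW2, p$attb2)
    if (keep_cache) cache$att <- list(fwd = g, X_in = A)
    A <- g$out
  }
  d <- dim(A)
  A2 <- array(A, dim = c(d[1L], d[2L], 1L, d[3L] * d[4L], d[5L]))
  if (keep_cache) cache$reshape_dims <- d
  f4 <- conv3d_forward(A2, p$c4W, p$c4b, NULL, idx_cache)
  Z4 <- f4$out
  A4 <- relu(Z4)
  if (keep_cache) cache$conv4 <- list(fwd = f4, Z = Z4)
  if (arch$variant == "global_attention_se") {
    g <- gate_forward(A4, p$seW1, p$seb1, p$seW2, p$seb2)
    if (keep_cache) cache$se <- list(fwd = g, X_in = A4)
    A4 <- g$out
  }
  d4 <- dim(A4)
  V <- matrix(A4, nrow = prod(d4[1:4]))      # [flat, N]
  if (keep_cache) cache$flat_dims <- d4
  Z5 <- p$d1W %*% V + p$d1b
  A5 <- relu(Z5)
  Z6 <- p$d2W %*% A5 + p$d2b
  A6 <- relu(Z6)
  out <- p$hW %*% A6 + p$hb                  # [k, N]
  if (arch$task == "classification") {
    m <- apply(out, 2L, max)
    e <- exp(sweep(out, 2L, m))
    probs <- sweep(e, 2L, colSums(e), "/")
    if (keep_cache) cache$dense <- list(V = V, Z5 = Z5, A5 = A5, Z6 = Z6, A6 = A6, probs = probs)
    return(list(out = probs, cache = if (keep_cache) cache))
  }
  if (keep_cache) cache$dense <- list(V = V, Z5 = Z5, A5 = A5, Z6 = Z6, A6 = A6)
  list(out = out, cache = if (keep_cache) cache)
}

backward_net <- function(arch, p, cache, dOut) {
  g <- list()
  dn <- cache$dense
  g$hW <- tcrossprod(dOut, dn$A6); g$hb <- rowSums(dOut)
  dA6 <- crossprod(p$hW, dOut)
  dZ6 <- dA6 * (dn$Z6 > 0)
  g$d2W <- tcrossprod(dZ6, dn$A5); g$d2b <- rowSums(dZ6)
  dA5 <- crossprod(p$d2W, dZ6)
  dZ5 <- dA5 * (dn$Z5 > 0)
  g$d1W <- tcrossprod(dZ5, dn$V); g$d1b <- rowSums(dZ5)
  dV <- crossprod(p$d1W, dZ5)
  dA4 <- array(dV, dim = cache$flat_dims)
  if (arch$variant == "global_attention_se") {
    gb <- gate_backward(dA4, cache$se$fwd, cache$se$X_in, p$seW1, p$seW2)
    g$seW1 <- gb$dW1; g$seb1 <- gb$db1; g$seW2 <- gb$dW2; g$seb2 <- gb$db2
    dA4 <- gb$dX
  }
  dZ4 <- dA4 * (cache$conv4$Z > 0)
  cb <- conv3d_backward(dZ4, cache$conv4$fwd, p$c4W)
  g$c4W <- cb$dW; g$c4b <- cb$db
  dA <- array(cb$dX, dim = cache$reshape_dims)
  if (arch$variant != "base") {
    gb <- gate_backward(dA, cache$att$fwd, cache$att$X_in, p$attW1, p$attW2)
    g$attW1 <- gb$dW1; g$attb1 <- gb$db1; g$attW2 <- gb$dW2; g$attb2 <- gb$db2
    dA <- gb$dX
  }
  for (l in 3:1) {
    cl <- cache[[paste0("conv", l)]]
    dZ <- dA * (cl$Z > 0)
    cb <- conv3d_backward(dZ, cl$fwd, p[[paste0("c", l, "W")]])
    g[[paste0("c", l, "W")]] <- cb$dW
    g[[paste0("c", l, "b")]] <- cb$db
    dA <- cb$dX
  }
  g
}

#' Fit the hybrid 3D/2D convolutional network
#'
#' Trains one of the network variants on seed patches for protein regression
#' (mean-squared-error loss, linear output) or 3-class protein classification
#' (categorical cross-entropy, softmax output), using the Adam optimizer.
#' Training is deterministic on a single CPU for a fixed `rng_seed`.
#'
#' @param x patch batch: `[H, W, D, N]` array (e.g. PCA-reduced crops, D = K
#'   channels) or `[H, W, D, 1, N]`.
#' @param y numeric protein percentages (regression) or a factor of class
#'   labels (classification).
#' @param arch an [arch_spec()].
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param rng_seed integer seed for initialization and shuffling.
#' @param validation optional `list(x =, y =)` scored after each epoch.
#' @param verbose print per-epoch losses.
#' @return An object of class `hybridsn`: fitted parameters, the
#'   architecture, and a `history` data frame of per-epoch losses.
#' @export
hybridsn <- function(x, y, arch = arch_spec(), epochs = 30L, batch_size = 32L,
                     lr = 1e-3, rng_seed = 1L, validation = NULL, verbose = FALSE) {
  if (length(dim(x)) == 4L) x <- array(x, dim = c(dim(x)[1:3], 1L, dim(x)[4L]))
  stopifnot(length(dim(x)) == 5L)
  N <- dim(x)[5L]
  if (arch$task == "classification") {
    y <- as.factor(y)
    if (length(y) != N) stop("length(y) must match the batch axis of x")
    lev <- levels(y)
    if (length(lev) != arch$n_classes)
      stop("y has ", length(lev), " classes; architecture declares ", arch$n_classes)
    Y <- matrix(0, length(lev), N)
    Y[cbind(as.integer(y), seq_len(N))] <- 1
  } else {
    if (!is.numeric(y) || length(y) != N) stop("y must be numeric, one value per patch")
    lev <- NULL
    Y <- matrix(y, 1L, N)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(rng_seed)
  p <- init_params(arch, dim(x)[1:3])
  m <- lapply(p, function(w) w * 0)
  v <- lapply(p, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  idx_cache <- new_idx_cache()
  history <- data.frame(epoch = integer(0), loss = numeric(0), val_loss = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    losses <- numeric(0)
    for (start in seq(1L, N, by = batch_size)) {
      sel <- ord[start:min(start + batch_size - 1L, N)]
      nb <- length(sel)
      Xb <- x[, , , , sel, drop = FALSE]
      Yb <- Y[, sel, drop = FALSE]
      fw <- forward_net(arch, p, Xb, idx_cache, keep_cache = TRUE)
      if (arch$task == "classification") {
        probs <- fw$out
        loss <- -mean(colSums(Yb * log(pmax(probs, 1e-12))))
        dOut <- (probs - Yb) / nb
      } else {
        res <- fw$out - Yb
        loss <- mean(res^2)
        dOut <- 2 * res / nb
      }
      losses <- c(losses, loss)
      grads <- backward_net(arch, p, fw$cache, dOut)
      t <- t + 1L
      for (nm in names(p)) {
        gq <- grads[[nm]]
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gq
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gq^2
        mhat <- m[[nm]] / (1 - b1^t)
        vhat <- v[[nm]] / (1 - b2^t)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_loss <- NA_real_
    if (!is.null(validation)) {
      vx <- validation$x
      if (length(dim(vx)) == 4L) vx <- array(vx, dim = c(dim(vx)[1:3], 1L, dim(vx)[4L]))
      pred <- forward_net(arch, p, vx, idx_cache, keep_cache = FALSE)$out
      val_loss <- if (arch$task == "classification") {
        yv <- factor(validation$y, levels = lev)
        Yv <- matrix(0, length(lev), ncol(pred))
        Yv[cbind(as.integer(yv), seq_len(ncol(pred)))] <- 1
        -mean(colSums(Yv * log(pmax(pred, 1e-12))))
      } else mean((as.numeric(pred) - validation$y)^2)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         val_loss = val_loss))
    if (verbose) cat(sprintf("epoch %3d  loss %.5f  val %.5f\n",
                             ep, mean(losses), val_loss))
  }
  structure(list(params = p, arch = arch, input_dims = dim(x)[1:3],
                 levels = lev, history = history, rng_seed = rng_seed),
            class = "hybridsn")
}

#' @export
print.hybridsn <- function(x, ...) {
  cat(sprintf("<hybridsn> %s %s | input %s | final loss %.5f\n",
              x$arch$variant, x$arch$task,
              paste(x$input_dims, collapse = "x"),
              utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Predict from a fitted hybrid network
#'
#' @param object a fitted [hybridsn()] model.
#' @param newdata patch batch `[H, W, D, N]` or `[H, W, D, 1, N]`.
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return Regression: numeric vector of protein percentages. Classification:
#'   N x n_classes matrix of probabilities (rows sum to 1) with the argmax
#'   labels in attribute `"class"`.
#' @export
predict.hybridsn <- function(object, newdata, batch_size = 64L, ...) {
  x <- newdata
  if (length(dim(x)) == 4L) x <- array(x, dim = c(dim(x)[1:3], 1L, dim(x)[4L]))
  if (!identical(dim(x)[1:3], as.integer(object$input_dims)))
    stop("patch dimensions ", paste(dim(x)[1:3], collapse = "x"),
         " do not match the fitted input ", paste(object$input_dims, collapse = "x"))
  N <- dim(x)[5L]
  idx_cache <- new_idx_cache()
  outs <- lapply(seq(1L, N, by = batch_size), function(start) {
    sel <- start:min(start + batch_size - 1L, N)
    forward_net(object$arch, object$params, x[, , , , sel, drop = FALSE],
                idx_cache, keep_cache = FALSE)$out
  })
  out <- do.call(cbind, outs)
  if (object$arch$task == "classification") {
    probs <- t(out)
    colnames(probs) <- object$levels
    attr(probs, "class_label") <- factor(object$levels[max.col(probs)],
                                         levels = object$levels)
    probs
  } else as.numeric(out)
}
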