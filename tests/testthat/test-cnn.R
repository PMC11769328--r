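# literal triple-loop valid correlation, the independent oracle
conv3d_oracle <- function(V, K) {
  dv <- dim(V); dk <- dim(K)
  do <- dv - dk + 1
  out <- array(0, do)
  for (x in 1:do[1]) for (y in 1:do[2]) for (z in 1:do[3]) {
    s <- 0
    for (i in 1:dk[1]) for (j in 1:dk[2]) for (k in 1:dk[3])
      s <- s + V[x + i - 1, y + j - 1, z + k - 1] * K[i, j, k]
    out[x, y, z] <- s
  }
  out
}

test_that("3-D convolution matches the triple-loop oracle on random volumes", {
  set.seed(23)
  for (rep in 1:30) {
    dv <- c(sample(2:6, 2, replace = TRUE), sample(2:10, 1))
    dk <- pmin(c(sample(1:3, 2, replace = TRUE), sample(1:4, 1)), dv)
    V <- array(rnorm(prod(dv)), dv)
    K <- array(rnorm(prod(dk)), dk)
    expect_lt(max(abs(conv3d_reference(V, K) - conv3d_oracle(V, K))), 1e-9)
  }
  # hand cases
  V1 <- array(runif(27), c(3, 3, 3))
  expect_equal(conv3d_reference(V1, array(2, c(1, 1, 1))), 2 * V1)
  ones <- array(1, c(3, 3, 3))
  expect_equal(conv3d_reference(ones, array(1, c(2, 2, 2))), array(8, c(2, 2, 2)))
  expect_equal(as.numeric(conv3d_reference(V1, V1)), sum(V1 * V1))
  expect_error(conv3d_reference(array(0, c(2, 2, 2)), array(0, c(3, 1, 1))), "larger")
})

test_that("zero-weight attention and SE gates scale the input by exactly 0.5", {
  set.seed(3)
  I <- array(rnorm(4 * 5 * 3 * 6), c(4, 5, 3, 6))
  w0 <- list(W1 = matrix(0, 3, 6), b1 = numeric(3), W2 = matrix(0, 6, 3), b2 = numeric(6))
  expect_identical(global_attention(I, w0), 0.5 * I)
  F <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  s0 <- list(W1 = matrix(0, 4, 8), b1 = numeric(4), W2 = matrix(0, 8, 4), b2 = numeric(8))
  expect_identical(squeeze_excite(F, s0, reduction = 2), 0.5 * F)
})

test_that("two-channel gates match a pencil evaluation and bound gates in (0,1)", {
  # C = 2 attention with hand-set weights
  I <- array(0, c(1, 2, 1, 2))
  I[1, , 1, 1] <- c(1, 3)   # channel 1: mean 2
  I[1, , 1, 2] <- c(2, 6)   # channel 2: mean 4
  w <- list(W1 = matrix(c(0.5, -0.25), 1, 2),  # G -> 0.5*2 - 0.25*4 = 0
            b1 = 0.1,                          # relu(0.1) = 0.1
            W2 = matrix(c(1, 2), 2, 1), b2 = c(0, -0.2))
  A <- c(1 / (1 + exp(-0.1)), 1 / (1 + exp(-0)))
  want <- I
  want[1, , 1, 1] <- I[1, , 1, 1] * A[1]
  want[1, , 1, 2] <- I[1, , 1, 2] * A[2]
  expect_equal(global_attention(I, w), want)
  # SE on a constant map: squeeze is exactly the constant
  Fc <- array(3, c(5, 7, 2))
  sw <- list(W1 = matrix(c(1, 0), 1, 2), b1 = 0, W2 = matrix(c(1, 1), 2, 1), b2 = c(0, 0))
  # z = (3, 3); v = relu(3) = 3; s = sigmoid(3)
  sg <- 1 / (1 + exp(-3))
  expect_equal(squeeze_excite(Fc, sw, reduction = 2), Fc * sg)
  # random gates stay within (0,1): output magnitude never exceeds input
  set.seed(5)
  wr <- list(W1 = matrix(rnorm(2), 1, 2), b1 = rnorm(1),
             W2 = matrix(rnorm(2), 2, 1), b2 = rnorm(2))
  Ir <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  O <- global_attention(Ir, wr)
  expect_true(all(abs(O) < abs(Ir) | Ir == 0))
  expect_identical(dim(O), dim(Ir))
})

test_that("PCA reduction preserves spatial structure and orders variance", {
  set.seed(7)
  # rank-1 pixels: one component explains everything
  base <- runif(20)
  pix <- outer(runif(300, 0.5, 2), base)
  red1 <- fit_pca(pix, K = 1)
  expect_gte(red1$explained_variance[1], 0.999)
  # complete basis reconstructs exactly
  pix2 <- matrix(rnorm(200 * 6), 200, 6)
  red <- fit_pca(pix2, K = 6)
  sc <- sweep(pix2, 2, red$center) %*% red$rotation
  back <- sc %*% t(red$rotation) + rep(red$center, each = 200)
  expect_lt(max(abs(back - pix2)), 1e-8)
  expect_true(all(diff(red$explained_variance) <= 1e-12))
  # cube application preserves spatial dims
  cube <- array(rnorm(5 * 4 * 6), c(5, 4, 6))
  out <- apply_pca(cube, fit_pca(matrix(cube, ncol = 6), K = 3))
  expect_identical(dim(out), c(5L, 4L, 3L))
  expect_error(fit_pca(pix2, K = 7), "exceeds")
})

test_that("architecture shape arithmetic accepts valid stacks and rejects exhausted depth", {
  sh <- hsiseed:::hybridsn_shapes(arch_spec(kernels = kernel_set(1)), c(32, 32, 30))
  expect_identical(sh$conv3d[[3]], c(26L, 26L, 18L))  # 30 - 6 - 4 - 2
  expect_error(hsiseed:::hybridsn_shapes(arch_spec(kernels = kernel_set(3)), c(32, 32, 8)),
               "exhausted")
  expect_identical(length(kernel_set(2)), 3L)
  expect_identical(kernel_set(2)[[1]], c(3L, 3L, 11L))
})

test_that("network gradients match finite differences on a tiny attentive model", {
  set.seed(31)
  arch <- arch_spec("global_attention_se", kernels = list(c(2, 2, 2), c(2, 2, 2), c(1, 1, 1)),
                    conv3d_filters = c(2, 3, 4), conv2d_filters = 4,
                    dense_units = c(6, 5), task = "regression")
  x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 1, 2))
  y <- matrix(rnorm(2), 1, 2)
  p <- hsiseed:::init_params(arch, c(6, 6, 4))
  p <- lapply(p, function(w) w + rnorm(length(w), 0, 0.05))  # move off ReLU kinks
  cache <- hsiseed:::new_idx_cache()
  lossfn <- function(pp) mean((hsiseed:::forward_net(arch, pp, x, cache, keep_cache = FALSE)$out - y)^2)
  fw <- hsiseed:::forward_net(arch, p, x, cache, keep_cache = TRUE)
  g <- hsiseed:::backward_net(arch, p, fw$cache, 2 * (fw$out - y) / 2)
  eps <- 1e-6
  for (nm in names(p)) {
    w <- p[[nm]]
    for (k in sample(seq_along(w), min(3, length(w)))) {
      p2 <- p; p2[[nm]][k] <- w[k] + eps
      p3 <- p; p3[[nm]][k] <- w[k] - eps
      num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][k]) / max(1e-4, abs(num), abs(g[[nm]][k])), 1e-4)
    }
  }
})

test_that("softmax heads normalize and predictions are batch-size invariant", {
  set.seed(41)
  x <- array(rnorm(8 * 8 * 5 * 12), c(8, 8, 5, 12))
  y <- factor(rep(c("low", "medium", "high"), 4), levels = c("low", "medium", "high"))
  arch <- arch_spec("base", kernels = list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2)),
                    conv3d_filters = c(2, 3, 4), conv2d_filters = 4,
                    dense_units = c(8, 6), task = "classification")
  fit <- hybridsn(x, y, arch, epochs = 2, batch_size = 4, rng_seed = 1)
  probs <- predict(fit, x)
  expect_equal(unname(rowSums(probs)), rep(1, 12), tolerance = 1e-6)
  # batchwise vs single-item forward passes agree
  one_by_one <- t(sapply(1:12, function(i)
    predict(fit, x[, , , i, drop = FALSE])[1, ]))
  expect_equal(unname(probs[, ]), unname(one_by_one), tolerance = 1e-5)
})

test_that("training reduces the loss and is deterministic per seed", {
  set.seed(51)
  ds <- generate_seed_dataset(50, patch = 8, wavelengths = seq(400, 2500, length.out = 30),
                              rng_seed = 4)
  red <- fit_pca(matrix(aperm(ds$patches, c(1, 2, 4, 3)), ncol = 30), K = 4)
  xp <- apply_pca(ds$patches, red)
  arch <- arch_spec("base", kernels = list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 1)),
                    conv3d_filters = c(4, 8, 8), conv2d_filters = 8,
                    dense_units = c(32, 16), task = "regression")
  fit <- hybridsn(xp, ds$protein, arch, epochs = 15, batch_size = 16, rng_seed = 9)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  fit2 <- hybridsn(xp, ds$protein, arch, epochs = 15, batch_size = 16, rng_seed = 9)
  expect_identical(fit$history, fit2$history)
  expect_identical(predict(fit, xp), predict(fit2, xp))
  # attentive variants train too (smoke) and reduce loss
  arch_att <- arch_spec("global_attention", kernels = list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 1)),
                        conv3d_filters = c(4, 8, 8), conv2d_filters = 8,
                        dense_units = c(32, 16), task = "regression")
  fit_att <- hybridsn(xp, ds$protein, arch_att, epochs = 8, batch_size = 16, rng_seed = 9)
  expect_lt(tail(fit_att$history$loss, 1), fit_att$history$loss[1])
})

test_that("argmax predictions on a separable toy task recover the training labels", {
  set.seed(61)
  ds <- generate_seed_dataset(60, patch = 8, wavelengths = seq(400, 2500, length.out = 30),
                              protein = "classes", rng_seed = 6)
  red <- fit_pca(matrix(aperm(ds$patches, c(1, 2, 4, 3)), ncol = 30), K = 4)
  xp <- apply_pca(ds$patches, red)
  arch <- arch_spec("base", kernels = list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 1)),
                    conv3d_filters = c(4, 8, 8), conv2d_filters = 8,
                    dense_units = c(32, 16), task = "classification")
  fit <- hybridsn(xp, ds$class_label, arch, epochs = 30, batch_size = 16,
                  lr = 3e-3, rng_seed = 2)
  pred <- attr(predict(fit, xp), "class_label")
  expect_gte(mean(pred == ds$class_label), 0.9)
})
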