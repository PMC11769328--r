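test_that("scale factors are plain dimension ratios", {
  expect_equal(compute_scale(c(200, 200), c(100, 100)), list(scale_h = 2, scale_w = 2))
  expect_equal(compute_scale(c(64, 64), c(64, 64)), list(scale_h = 1, scale_w = 1))
  expect_equal(compute_scale(c(3000, 1200), c(640, 480)),
               list(scale_h = 3000 / 640, scale_w = 1200 / 480))
  expect_error(compute_scale(c(0, 10), c(5, 5)), "positive")
})

test_that("naive area resampling averages the covered blocks", {
  cube <- make_cube(4, 4, 2, seed = 1)
  expect_equal(resample_naive(cube, c(4, 4))$data, cube$data)
  const <- spectral_cube(array(0.7, c(4, 4, 2)), c(400, 410))
  expect_equal(resample_naive(const, c(2, 2))$data, array(0.7, c(2, 2, 2)))
  # hand-averaged 2x2 windows
  M <- matrix(1:16, 4, 4)
  cube2 <- spectral_cube(array(M, c(4, 4, 1)), 500)
  want <- matrix(c(mean(M[1:2, 1:2]), mean(M[3:4, 1:2]),
                   mean(M[1:2, 3:4]), mean(M[3:4, 3:4])), 2, 2)
  expect_equal(resample_naive(cube2, c(2, 2))$data[, , 1], want)
})

test_that("homography application performs the homogeneous division", {
  I <- homography(diag(3))
  expect_equal(apply_homography(c(3, 4), I), cbind(x = 3, y = 4))
  H <- homography(matrix(c(2, 0, 3, 0, 2, -1, 0, 0, 1), 3, 3, byrow = TRUE))
  expect_equal(apply_homography(c(1, 1), H), cbind(x = 5, y = 1))
  Hp <- homography(matrix(c(1, 0, 0, 0, 1, 0, 1, 0, 1), 3, 3, byrow = TRUE))
  expect_equal(apply_homography(c(1, 0), Hp), cbind(x = 0.5, y = 0))
})

test_that("four exact translation pairs recover the translation homography", {
  src <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
  dst <- cbind(src[, 1] + 4.5, src[, 2] - 2.25)
  est <- estimate_homography(cbind(src, dst))
  want <- matrix(c(1, 0, 4.5, 0, 1, -2.25, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_lt(max(abs(est$transform$h - want)), 1e-9)
  expect_equal(est$report$rmse, sqrt(est$report$mse))
})

test_that("RANSAC excludes gross outliers and recovers the generating transform", {
  set.seed(21)
  H <- homography(matrix(c(0.5, 0, 3.2, 0, 0.48, -2.4, 0, 0, 1), 3, 3, byrow = TRUE))
  src <- cbind(runif(12, 0, 250), runif(12, 0, 320))
  dst <- apply_homography(src, H)
  out_src <- cbind(runif(3, 0, 250), runif(3, 0, 320))
  out_dst <- apply_homography(out_src, H) + matrix(runif(6, 60, 120), 3)
  est <- estimate_homography(rbind(cbind(src, dst), cbind(out_src, out_dst)),
                             ransac_threshold = 7.0, rng_seed = 2)
  expect_identical(est$report$inlier_count, 12L)
  prj <- apply_homography(src, est$transform)
  expect_lt(sqrt(mean(rowSums((prj - dst)^2))), 0.5)
})

test_that("collinear tie points are rejected as degenerate", {
  src <- cbind(1:4, 2 * (1:4) + 1)
  expect_error(estimate_homography(cbind(src, src)), "collinear|degenerate")
  expect_error(estimate_homography(cbind(src[1:3, ], src[1:3, ])), "at least 4")
  expect_error(estimate_homography(cbind(rbind(src[1:3, ], src[1, ]),
                                         rbind(src[1:3, ], src[1, ]))), "duplicated")
})

test_that("random scale+translation transforms are recovered from exact tie points", {
  set.seed(31)
  for (rep in 1:10) {
    H <- homography(matrix(c(runif(1, 0.3, 2), 0, runif(1, -10, 10),
                             0, runif(1, 0.3, 2), runif(1, -10, 10),
                             0, 0, 1), 3, 3, byrow = TRUE))
    src <- cbind(runif(10, 0, 300), runif(10, 0, 300))
    est <- estimate_homography(cbind(src, apply_homography(src, H)), rng_seed = rep)
    expect_lt(sqrt(sum((est$transform$h - H$h)^2)), 1e-6)
  }
})

test_that("cube warping is exact for identity and integer translations", {
  cube <- make_cube(6, 6, 3, seed = 7)
  same <- warp_cube(cube, homography(diag(3)), c(6, 6))
  expect_equal(same$data, cube$data)
  Ht <- homography(matrix(c(1, 0, 2, 0, 1, 1, 0, 0, 1), 3, 3, byrow = TRUE))
  shifted <- warp_cube(cube, Ht, c(6, 6))
  expect_equal(shifted$data[2:6, 3:6, ], cube$data[1:5, 1:4, ])
  expect_true(all(shifted$data[1, , ] == 0))  # out-of-frame filled with 0
})

test_that("warping the simulator's VNIR frame lands markers on SWIR markers", {
  spec <- small_scene_spec(n_seeds = 2, noise_sd = 0, rng_seed = 8)
  spec$vnir_wavelengths <- seq(400, 1000, length.out = 8)
  spec$swir_wavelengths <- seq(960, 2500, length.out = 8)
  scene <- generate_scene(spec)
  warped <- warp_cube(scene$vnir, scene$truth_transform, dim(scene$swir$data)[1:2])
  # marker disk centers: bright pixels near each mapped marker
  for (m in seq_len(nrow(scene$markers_swir))) {
    pt <- scene$markers_swir[m, ]
    r <- round(pt[2]) + 1; c <- round(pt[1]) + 1
    expect_gt(warped$data[r, c, 1], 0.7)        # warped VNIR marker present
    expect_gt(scene$swir$data[r, c, 1], 0.7)    # rendered SWIR marker present
  }
})

test_that("stacking concatenates bands and wavelengths VNIR-then-SWIR", {
  v <- spectral_cube(array(1, c(4, 4, 300)), seq(400, 1000, length.out = 300))
  s <- spectral_cube(array(2, c(4, 4, 362)), seq(960, 2500, length.out = 362))
  st <- stack_cubes(v, s)
  expect_identical(dim(st$data)[3], 662L)
  expect_identical(st$wavelengths, c(v$wavelengths, s$wavelengths))
  a <- spectral_cube(array(1, c(2, 2, 1)), 500)
  b <- spectral_cube(array(2, c(2, 2, 1)), 1500)
  expect_identical(dim(stack_cubes(a, b)$data)[3], 2L)
  bad <- spectral_cube(array(2, c(3, 2, 1)), 1500)
  expect_error(stack_cubes(a, bad), "spatial")
})

test_that("held-out marker comparison favors homography once translation exists", {
  # zero-translation pure-scale scene: both methods near-exact
  H0 <- homography(matrix(c(0.5, 0, 0, 0, 0.5, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  spec0 <- small_scene_spec(n_seeds = 2, noise_sd = 0, rng_seed = 9, true_transform = H0)
  spec0$vnir_wavelengths <- seq(400, 1000, length.out = 6)
  spec0$swir_wavelengths <- seq(960, 2500, length.out = 6)
  sc0 <- generate_scene(spec0)
  cm0 <- compare_methods(sc0, rng_seed = 1)
  expect_lt(cm0$rmse[cm0$method == "homography"], 1e-6)
  expect_lt(cm0$rmse[cm0$method == "resampling"], 1e-6)
  # determinism
  expect_identical(cm0, compare_methods(sc0, rng_seed = 1))
})
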