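# a cube with given per-pixel values at the five rule wavelengths
rule_cube <- function(b1, b2, g, r, n) {
  h <- length(b1); vals <- cbind(b1, b2, g, r, n)
  data <- array(0, c(h, 1, 5))
  for (k in 1:5) data[, 1, k] <- vals[, k]
  spectral_cube(data, c(410, 456, 553, 654, 852))
}

test_that("the five-band rule admits seed-like spectra and rejects flat ones", {
  cube <- rule_cube(b1 = c(0.05, 0.5, 0),
                    b2 = c(0.07, 0.5, 0),
                    g  = c(0.10, 0.5, 0),
                    r  = c(0.06, 0.5, 0),
                    n  = c(0.30, 0.5, 0))
  m <- rule_mask(cube)
  expect_identical(as.vector(m), c(1L, 0L, 0L))  # seed, panel-flat, all-zero
  # each bound is active: violate one condition at a time
  viol <- list(
    rule_cube(0.08, 0.07, 0.10, 0.06, 0.30),   # B1 >= B2
    rule_cube(0.05, 0.07, 0.10, 0.02, 0.30),   # R below 0.7*B1
    rule_cube(0.05, 0.07, 0.10, 0.70, 0.30),   # R above 12.5*B1
    rule_cube(0.05, 0.07, 0.10, 0.06, 0.05),   # N below 1.2*B1
    rule_cube(0.05, 0.07, 0.10, 0.06, 0.80),   # N above 15*B1
    rule_cube(0.05, 0.07, 0.08, 0.06, 0.30))   # G below 1.2*B2
  for (v in viol) expect_identical(as.vector(rule_mask(v)), 0L)
})

test_that("morphological opening removes specks, keeps solid blocks, and is idempotent", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  expect_true(all(morphological_open(m) == 0))
  solid <- matrix(0L, 9, 9); solid[3:7, 3:7] <- 1L
  expect_identical(morphological_open(solid), solid)
  withdiag <- solid; withdiag[2, 2] <- 1L
  expect_identical(morphological_open(withdiag), solid)  # diagonal pixel shaved
  set.seed(4)
  noisy <- matrix(rbinom(400, 1, 0.4), 20, 20)
  once <- morphological_open(noisy)
  expect_identical(morphological_open(once), once)
})

test_that("flood-fill hole repair fills enclosed holes and never removes seed pixels", {
  ring <- matrix(0L, 9, 9); ring[3:7, 3:7] <- 1L; ring[5, 5] <- 0L
  rep1 <- repair_holes(ring)
  expect_identical(rep1[5, 5], 1L)
  expect_true(all(rep1[ring == 1L] == 1L))
  expect_true(all(repair_holes(matrix(0L, 5, 5)) == 0L))
  # region touching the frame edge is still reachable through the guard border
  edge <- matrix(0L, 6, 6); edge[1:3, 1:3] <- 1L; edge[2, 2] <- 0L
  expect_identical(repair_holes(edge)[2, 2], 1L)
  set.seed(5)
  rnd <- matrix(rbinom(900, 1, 0.35), 30, 30)
  expect_true(all(repair_holes(rnd)[rnd == 1L] == 1L))
})

test_that("component extraction uses 8-connectivity and the strict area filter", {
  # two blobs touching only diagonally form one 8-connected component
  m <- matrix(0L, 60, 60)
  m[10:27, 10:27] <- 1L   # 18x18 = 324 px
  m[28:45, 28:45] <- 1L   # diagonal neighbor
  ext <- extract_components(m, min_area = 250, max_area = 1500)
  expect_identical(nrow(ext$components), 1L)
  expect_identical(ext$components$area, 648L)
  # small blob dropped, in-window kept, fused oversize dropped
  m2 <- matrix(0L, 120, 60)
  m2[2:11, 2:11] <- 1L                 # 100 px -> dropped
  m2[30:50, 10:39] <- 1L               # 630 px -> kept
  m2[70:109, 10:59] <- 1L              # 2000 px -> dropped
  ext2 <- extract_components(m2)
  expect_identical(nrow(ext2$components), 1L)
  expect_identical(ext2$components$area, 630L)
  # boundary semantics are strict: area exactly 250 or 1500 is excluded
  m3 <- matrix(0L, 60, 60); m3[1:10, 1:25] <- 1L  # 250 px
  expect_identical(nrow(extract_components(m3)$components), 0L)
})

test_that("grid labeling orders rows by y and columns by x", {
  grid <- expand.grid(col = 1:4, row = 1:6)
  comps <- data.frame(component_id = 1:24,
                      area = 628,
                      xmin = grid$col * 50 - 10, xmax = grid$col * 50 + 10,
                      ymin = grid$row * 50 - 8, ymax = grid$row * 50 + 8,
                      centroid_x = grid$col * 50, centroid_y = grid$row * 50)
  comps <- comps[sample(24), ]  # order must not matter
  lab <- grid_label(comps, rows = 6, cols = 4)
  want <- paste0(LETTERS[grid$col[match(lab$component_id, 1:24)]],
                 grid$row[match(lab$component_id, 1:24)])
  expect_identical(lab$grid_label, want)
  single <- comps[1, ]
  expect_identical(grid_label(single, 6, 4)$grid_label, "A1")
  two <- comps[comps$centroid_y == 50, ][1:2, ]
  two <- two[order(-two$centroid_x), ]
  lab2 <- grid_label(two, 6, 4)
  expect_identical(lab2$grid_label[order(two$centroid_x)], c("A1", "B1"))
  expect_error(grid_label(comps, rows = 2, cols = 4), "grid cells")
})

test_that("seed crops are centered, zero-padded and conserve the component mass", {
  spec <- small_scene_spec(n_seeds = 4, noise_sd = 0, rng_seed = 10)
  spec$vnir_wavelengths <- seq(400, 1000, length.out = 8)
  spec$swir_wavelengths <- seq(960, 2500, length.out = 8)
  scene <- generate_scene(spec)
  seg <- segment_scene(scene$vnir, rows = spec$grid_rows, cols = spec$grid_cols)
  comp <- seg$components[1, ]
  crop <- crop_seed(scene$vnir, comp, seg$labels, size = 32)
  expect_identical(dim(crop$patch), c(32L, 32L, 8L))
  # patch centroid of the mask sits at the center +/- 0.5 px (0-based)
  px <- which(crop$mask == 1, arr.ind = TRUE)
  expect_lt(abs(mean(px[, 1]) - 1 - 16), 1)
  expect_lt(abs(mean(px[, 2]) - 1 - 16), 1)
  # masked-sum conservation against the source frame (window wide enough to
  # cover the 40-px major axis of the default seed ellipse)
  crop48 <- crop_seed(scene$vnir, comp, seg$labels, size = 48)
  sel <- seg$labels == comp$component_id
  for (b in c(1L, 5L)) {
    src_sum <- sum(scene$vnir$data[, , b][sel])
    expect_equal(sum(crop48$patch[, , b]), src_sum)
  }
  # corner component: padding fills the outside with zeros
  lab_corner <- matrix(0L, 40, 40); lab_corner[1:20, 1:16] <- 1L
  cube <- spectral_cube(array(1, c(40, 40, 2)), c(500, 600))
  comp_c <- data.frame(component_id = 1, area = 320, xmin = 0, xmax = 15,
                       ymin = 0, ymax = 19, centroid_x = 7.5, centroid_y = 9.5)
  crop_c <- crop_seed(cube, comp_c, lab_corner, size = 32)
  expect_identical(dim(crop_c$patch), c(32L, 32L, 2L))
  expect_equal(sum(crop_c$patch[, , 1]), 320)
})

test_that("RGB composite picks nearest 642/546/460 nm bands in R,G,B order", {
  wl <- seq(400, 1000, length.out = 40)
  set.seed(2)
  cube <- spectral_cube(array(runif(5 * 5 * 40), c(5, 5, 40)), wl)
  rgb <- rgb_composite(cube)
  oracle <- sapply(c(642, 546, 460), function(q) which.min(abs(wl - q)))
  expect_equal(rgb, cube$data[, , oracle, drop = FALSE])
  const <- spectral_cube(array(0.3, c(3, 3, 40)), wl)
  expect_true(all(rgb_composite(const) == 0.3))
})

test_that("end-to-end segmentation recovers every planted seed with high pixel F1", {
  spec <- small_scene_spec(n_seeds = 12, noise_sd = 0.01, rng_seed = 11)
  scene <- generate_scene(spec)
  seg <- segment_scene(scene$vnir, rows = spec$grid_rows, cols = spec$grid_cols)
  expect_identical(nrow(seg$components), 12L)
  expect_gte(pixel_f1(seg$mask, scene$truth_mask), 0.95)
  expect_true(all(seg$components$area > 250 & seg$components$area < 1500))
})
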