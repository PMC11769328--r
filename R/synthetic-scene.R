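#' Synthetic bench-top scene specification
#'
#' Describes a simulated scanning-stage scene: seeds on a rows x cols grid of
#' circular troughs, a 50% reflectance panel strip, and high-contrast fiducial
#' marker disks visible to both sensors. The VNIR frame is the fine-resolution
#' reference geometry; the SWIR frame views the same scene through a known
#' projective transform (anisotropic scale plus a few pixels of translation,
#' emulating the offset between the two line-scan sensors).
#'
#' Seed reflectance follows a smooth base curve scaled multiplicatively
#' downward with protein content (higher protein, lower reflectance at every
#' band) and carries moisture absorption dips near 1450 and 1950 nm whose
#' absolute depth shrinks with protein.
#'
#' @param grid_rows,grid_cols seed grid layout (default 6 x 4 = 24 troughs).
#' @param seed_axes major/minor ellipse axis lengths in VNIR px (default
#'   c(40, 20), area ~628 px, inside the 250-1500 px component filter).
#' @param protein_pct protein percentages, one per seed, each in
#'   [7.69, 19.65]. `NULL` draws one per trough uniformly from that range.
#' @param marker_count number of fiducial marker disks (>= 4, default 12).
#' @param noise_sd i.i.d. Gaussian reflectance noise per pixel/band
#'   (default 0.01).
#' @param vnir_wavelengths,swir_wavelengths band centers in nm (defaults: 300
#'   bands 400-1000 nm; 362 bands 960-2500 nm).
#' @param true_transform [homography()] mapping VNIR to SWIR pixel
#'   coordinates; default anisotropic scale (0.5, 0.48) with a translation of
#'   (3.2, -2.4) SWIR px.
#' @param orientation `"ventral"` or `"dorsal"`; dorsal faces are smoother and
#'   slightly brighter by `orientation_contrast`.
#' @param orientation_contrast relative reflectance increase of the dorsal
#'   face (default 0.03).
#' @param alpha strength of the protein-reflectance link (default 0.35: the
#'   highest-protein seed is 35% darker than the lowest).
#' @param rng_seed integer seed for protein draws and noise.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(grid_rows = 6L, grid_cols = 4L, seed_axes = c(40, 20),
                       protein_pct = NULL, marker_count = 12L, noise_sd = 0.01,
                       vnir_wavelengths = seq(400, 1000, length.out = 300L),
                       swir_wavelengths = seq(960, 2500, length.out = 362L),
                       true_transform = NULL,
                       orientation = c("ventral", "dorsal"),
                       orientation_contrast = 0.03,
                       alpha = 0.35, rng_seed = 1L) {
  orientation <- match.arg(orientation)
  if (is.null(true_transform))
    true_transform <- homography(matrix(c(0.5, 0, 3.2,
                                          0, 0.48, -2.4,
                                          0, 0, 1), 3L, 3L, byrow = TRUE))
  if (is.null(protein_pct)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(rng_seed)
    protein_pct <- stats::runif(grid_rows * grid_cols, 7.69, 19.65)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  spec <- list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
               seed_axes = seed_axes, protein_pct = as.numeric(protein_pct),
               marker_count = as.integer(marker_count), noise_sd = noise_sd,
               vnir_wavelengths = vnir_wavelengths, swir_wavelengths = swir_wavelengths,
               true_transform = true_transform, orientation = orientation,
               orientation_contrast = orientation_contrast,
               alpha = alpha, rng_seed = as.integer(rng_seed))
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (grid_rows * grid_cols < length(protein_pct))
      stop("more seeds (", length(protein_pct), ") than grid cells (",
           grid_rows * grid_cols, "): seeds would overlap")
    if (length(protein_pct) && (any(protein_pct < 7.69) || any(protein_pct > 19.65)))
      stop("protein_pct values must lie in [7.69, 19.65]")
    if (marker_count < 4L) stop("marker_count must be >= 4")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (any(diff(vnir_wavelengths) <= 0) || any(diff(swir_wavelengths) <= 0))
      stop("wavelength lists must be strictly increasing")
    if (any(seed_axes <= 0)) stop("seed_axes must be positive")
  })
  invisible(spec)
}

# ---- reflectance model -----------------------------------------------------

# smooth seed base curve anchored so the 410/456/553/654/852 nm segmentation
# rule holds with margin for every protein level (the link is multiplicative)
seed_base_curve <- function(wl) {
  anchors_x <- c(400, 410, 456, 553, 654, 852, 1000, 1200, 1450, 1700, 1950, 2200, 2500)
  anchors_y <- c(0.085, 0.095, 0.16, 0.30, 0.36, 0.55, 0.60, 0.62, 0.60, 0.63, 0.60, 0.58, 0.50)
  f <- stats::splinefun(anchors_x, anchors_y, method = "natural")
  pmax(f(wl), 0.02)
}

# moisture absorption dips (relative depth); multiplicative on the scaled
# curve, so the absolute dip depth decreases as protein rises
moisture_dips <- function(wl) {
  1 - 0.25 * exp(-((wl - 1450) / 40)^2) - 0.30 * exp(-((wl - 1950) / 45)^2)
}

#' Generative protein-reflectance link of the simulator
#'
#' Reflectance of a seed at the given wavelengths:
#' `base(lambda) * dips(lambda) * (1 - alpha * (p - 7.69) / 11.96)`, times
#' `(1 + orientation_contrast)` for dorsal faces. Strictly decreasing in
#' protein at every band.
#'
#' @param wl wavelengths in nm.
#' @param protein_pct protein percentage.
#' @param alpha link strength in (0, 1).
#' @param orientation `"ventral"` or `"dorsal"`.
#' @param orientation_contrast dorsal brightness increase.
#' @return Reflectance vector, one value per wavelength.
#' @export
seed_reflectance <- function(wl, protein_pct, alpha = 0.35,
                             orientation = "ventral", orientation_contrast = 0.03) {
  scale <- 1 - alpha * (protein_pct - 7.69) / 11.96
  orient <- if (orientation == "dorsal") 1 + orientation_contrast else 1
  seed_base_curve(wl) * moisture_dips(wl) * scale * orient
}

tray_reflectance <- function(wl) 0.085 - 0.04 * (wl - 400) / 2100

# SWIR frame dimensions: for scale+translation transforms the frame is the
# VNIR frame scaled exactly (so naive resampling's dimension ratio equals the
# true scale); otherwise the bounding box of the mapped VNIR frame
swir_frame_dims <- function(h_v, w_v, H) {
  h <- H$h
  if (all(abs(h[c(2, 3, 4, 6)]) < 1e-12)) {  # h21, h31, h12, h32 all zero
    c(as.integer(round(h_v * h[2, 2])), as.integer(round(w_v * h[1, 1])))
  } else {
    corners <- apply_homography(cbind(c(0, w_v - 1, 0, w_v - 1),
                                      c(0, 0, h_v - 1, h_v - 1)), H)
    c(as.integer(ceiling(max(corners[, 2L]))) + 4L,
      as.integer(ceiling(max(corners[, 1L]))) + 4L)
  }
}

# ---- geometry --------------------------------------------------------------

scene_layout <- function(spec) {
  margin <- 40; pitch <- 52
  cols <- spec$grid_cols; rows <- spec$grid_rows
  cx <- margin + (seq_len(cols) - 1L) * pitch           # seed centers, x
  cy <- margin + (seq_len(rows) - 1L) * pitch           # seed centers, y
  width <- margin + (cols - 1L) * pitch + margin + 60   # room for panel strip
  height <- 2 * margin + (rows - 1L) * pitch
  panel <- list(x0 = width - 44, x1 = width - 14, y0 = 14, y1 = height - 14)
  # fiducial disks along left and right borders, clear of seeds and panel
  k <- spec$marker_count
  n_left <- ceiling(k / 2); n_right <- k - n_left
  my_l <- seq(16, height - 16, length.out = n_left)
  my_r <- seq(22, height - 22, length.out = max(n_right, 1L))[seq_len(n_right)]
  markers <- cbind(x = c(rep(12, n_left), rep(width - 56, n_right)),
                   y = c(my_l, my_r))
  n_seed <- length(spec$protein_pct)
  centers <- if (n_seed) {
    g <- expand.grid(col = seq_len(cols), row = seq_len(rows))[seq_len(n_seed), ]
    cbind(x = cx[g$col], y = cy[g$row], row = g$row, col = g$col)
  } else matrix(numeric(0), 0L, 4L, dimnames = list(NULL, c("x", "y", "row", "col")))
  list(width = width, height = height, panel = panel, markers = markers,
       centers = centers, marker_radius = 5)
}

# region id at continuous scene coordinates (VNIR frame):
# 0 tray, -1 panel, -2 marker, k > 0 seed k
region_at <- function(x, y, layout, spec) {
  lab <- integer(length(x))
  p <- layout$panel
  lab[x >= p$x0 & x <= p$x1 & y >= p$y0 & y <= p$y1] <- -1L
  mr2 <- layout$marker_radius^2
  for (m in seq_len(nrow(layout$markers))) {
    hit <- (x - layout$markers[m, 1L])^2 + (y - layout$markers[m, 2L])^2 <= mr2
    lab[hit] <- -2L
  }
  a <- spec$seed_axes[1L] / 2; b <- spec$seed_axes[2L] / 2
  for (k in seq_len(nrow(layout$centers))) {
    hit <- ((x - layout$centers[k, "x"]) / a)^2 + ((y - layout$centers[k, "y"]) / b)^2 <= 1
    lab[hit] <- k
  }
  lab
}

render_frame <- function(labels, wl, spec, h, w) {
  n_seed <- length(spec$protein_pct)
  # spectra per region id, in order: tray, panel, marker, seeds 1..n
  spectra <- rbind(tray_reflectance(wl),
                   rep(0.5, length(wl)),
                   rep(0.9, length(wl)))
  if (n_seed)
    spectra <- rbind(spectra, t(vapply(spec$protein_pct, function(p)
      seed_reflectance(wl, p, spec$alpha, spec$orientation, spec$orientation_contrast),
      numeric(length(wl)))))
  ridx <- ifelse(labels == 0L, 1L, ifelse(labels == -1L, 2L,
                 ifelse(labels == -2L, 3L, labels + 3L)))
  array(spectra[ridx, ], dim = c(h, w, length(wl)))
}

#' Generate a synthetic VNIR/SWIR scene pair
#'
#' Renders the scene described by a [scene_spec()] in both sensor frames.
#' Seeds are filled ellipses on a dark tray; the reflectance panel is a
#' constant-0.5 strip; fiducial markers are 0.9-reflectance disks. The SWIR
#' frame is the same scene geometry observed through `true_transform` on its
#' coarser pixel grid (each SWIR pixel center is mapped back to scene
#' coordinates and evaluated analytically). Gaussian noise of `noise_sd` is
#' added independently per pixel and band, clipped at 0.
#'
#' @param spec a [scene_spec()].
#' @return A `scene_pair` list: `vnir` and `swir` [spectral_cube()]s,
#'   `truth_mask` (VNIR-frame 0/1 matrix), `truth_components` (data frame of
#'   seed id, area, bbox, centroid, grid label), `truth_transform`,
#'   `protein_by_seed` (named vector), `markers_vnir`/`markers_swir`
#'   (continuous marker center coordinates in each frame), and `spec`.
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  layout <- scene_layout(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$rng_seed)

  h_v <- layout$height; w_v <- layout$width
  xv <- rep(0:(w_v - 1L), each = h_v); yv <- rep(0:(h_v - 1L), times = w_v)
  lab_v <- matrix(region_at(xv, yv, layout, spec), h_v, w_v)
  vnir <- render_frame(lab_v, spec$vnir_wavelengths, spec, h_v, w_v)

  H <- spec$true_transform
  ds <- swir_frame_dims(h_v, w_v, H)
  h_s <- ds[1L]; w_s <- ds[2L]
  Hinv <- homography(solve(H$h))
  xs <- rep(0:(w_s - 1L), each = h_s); ys <- rep(0:(h_s - 1L), times = w_s)
  back <- apply_homography(cbind(xs, ys), Hinv)
  lab_s <- matrix(region_at(back[, 1L], back[, 2L], layout, spec), h_s, w_s)
  swir <- render_frame(lab_s, spec$swir_wavelengths, spec, h_s, w_s)

  if (spec$noise_sd > 0) {
    vnir <- pmax(vnir + stats::rnorm(length(vnir), 0, spec$noise_sd), 0)
    swir <- pmax(swir + stats::rnorm(length(swir), 0, spec$noise_sd), 0)
  }

  n_seed <- length(spec$protein_pct)
  comps <- if (n_seed) {
    rows <- lapply(seq_len(n_seed), function(k) {
      px <- which(lab_v == k, arr.ind = TRUE)
      data.frame(component_id = k, area = nrow(px),
                 xmin = min(px[, 2L]) - 1L, xmax = max(px[, 2L]) - 1L,
                 ymin = min(px[, 1L]) - 1L, ymax = max(px[, 1L]) - 1L,
                 centroid_x = mean(px[, 2L]) - 1, centroid_y = mean(px[, 1L]) - 1,
                 grid_label = paste0(LETTERS[layout$centers[k, "col"]],
                                     layout$centers[k, "row"]))
    })
    do.call(rbind, rows)
  } else {
    data.frame(component_id = integer(0), area = integer(0),
               xmin = integer(0), xmax = integer(0), ymin = integer(0),
               ymax = integer(0), centroid_x = numeric(0), centroid_y = numeric(0),
               grid_label = character(0))
  }
  protein <- spec$protein_pct
  names(protein) <- comps$grid_label

  structure(list(
    vnir = spectral_cube(vnir, spec$vnir_wavelengths, units = "reflectance"),
    swir = spectral_cube(swir, spec$swir_wavelengths, units = "reflectance"),
    truth_mask = (lab_v > 0L) * 1L,
    truth_components = comps,
    truth_transform = H,
    protein_by_seed = protein,
    markers_vnir = layout$markers,
    markers_swir = apply_homography(layout$markers, H),
    spec = spec), class = "scene_pair")
}

#' @export
print.scene_pair <- function(x, ...) {
  cat(sprintf("<scene_pair> %d seeds | VNIR %s | SWIR %s\n",
              length(x$protein_by_seed),
              paste(dim(x$vnir$data), collapse = "x"),
              paste(dim(x$swir$data), collapse = "x")))
  invisible(x)
}

#' Generate dark/bright calibration frames consistent with a scene
#'
#' Builds the fixtures a radiometric calibration needs: a dark-current frame,
#' a bright white-reference frame, and the known panel reflectance and
#' integration time. The forward sensor model is
#' `DN = L * response * t_int + dark`, with scene radiance
#' `L = reflectance * true_radiance_scale` under spectrally flat illumination;
#' [compose_raw()] applies it, and running the calibration module on composed
#' raw frames recovers the scene's reflectance.
#'
#' @param spec a [scene_spec()] (fixes frame dimensions and rng seed).
#' @param true_radiance_scale radiance of a 100%-reflectance surface, > 0.
#' @param sensor `"vnir"` or `"swir"`: which frame to build fixtures for.
#' @param integration_time integration time in seconds.
#' @return A `calibration_fixtures` list: `dark_frame`, `bright_frame`
#'   (DN cubes), `panel_reflectance`, `integration_time`, `panel_radiance`,
#'   `response` (truth response array) and `true_radiance_scale`.
#' @export
generate_calibration_fixtures <- function(spec, true_radiance_scale = 200,
                                          sensor = c("vnir", "swir"),
                                          integration_time = 0.01) {
  sensor <- match.arg(sensor)
  if (true_radiance_scale <= 0) stop("true_radiance_scale must be > 0")
  validate_scene_spec(spec)
  layout <- scene_layout(spec)
  wl <- if (sensor == "vnir") spec$vnir_wavelengths else spec$swir_wavelengths
  if (sensor == "vnir") {
    h <- layout$height; w <- layout$width
  } else {
    ds <- swir_frame_dims(layout$height, layout$width, spec$true_transform)
    h <- ds[1L]; w <- ds[2L]
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$rng_seed + 7L)
  d <- c(h, w, length(wl))
  # smoothly varying positive response and a structured dark frame
  response <- array(100 * (1 + 0.2 * sin(seq(0, 4 * pi, length.out = prod(d)))), dim = d)
  dark <- array(40 + stats::runif(prod(d), 0, 2), dim = d)
  panel_radiance <- 0.5 * true_radiance_scale
  bright <- dark + response * panel_radiance * integration_time
  structure(list(
    dark_frame = spectral_cube(dark, wl, units = "dn"),
    bright_frame = spectral_cube(bright, wl, units = "dn"),
    panel_reflectance = 0.5,
    integration_time = integration_time,
    panel_radiance = panel_radiance,
    response = response,
    true_radiance_scale = true_radiance_scale,
    wavelengths = wl), class = "calibration_fixtures")
}

#' Forward-simulate a raw DN scan from a reflectance cube
#'
#' Applies the simulator's sensor model (`DN = reflectance *
#' true_radiance_scale * response * t_int + dark`) so calibration can be
#' exercised as a round trip.
#'
#' @param cube reflectance [spectral_cube()] matching the fixture dimensions.
#' @param fixtures a `calibration_fixtures` object.
#' @return A DN [spectral_cube()].
#' @export
compose_raw <- function(cube, fixtures) {
  stopifnot(inherits(fixtures, "calibration_fixtures"))
  if (!identical(dim(cube$data), dim(fixtures$dark_frame$data)))
    stop("cube dimensions do not match calibration fixtures")
  L <- cube$data * fixtures$true_radiance_scale
  dn <- L * fixtures$response * fixtures$integration_time + fixtures$dark_frame$data
  spectral_cube(dn, cube$wavelengths, units = "dn", interleave = cube$interleave)
}

#' Generate a standalone per-seed patch dataset
#'
#' Produces single-seed crops directly (bypassing full-scene rendering) for
#' model benchmarking: each patch holds one elliptical seed with jittered size
#' and subpixel position on a zeroed background, with reflectance following
#' the simulator's protein link plus Gaussian noise.
#'
#' @param n number of seeds.
#' @param patch spatial patch size in px (square).
#' @param wavelengths band centers in nm (default 120 bands, 400-2500 nm).
#' @param protein either `"uniform"` (protein ~ U(7.69, 19.65)) or
#'   `"classes"` (balanced, well-separated low/medium/high clusters at
#'   roughly 8.6, 12 and 17%).
#' @param noise_sd Gaussian reflectance noise (default 0.01).
#' @param alpha protein link strength.
#' @param rng_seed integer seed.
#' @return List with `patches` (patch x patch x bands x n array), `mask`
#'   (patch x patch x n), `protein` (length-n vector), `class_label`
#'   (factor low/medium/high per [protein_class()]), and `wavelengths`.
#' @export
generate_seed_dataset <- function(n, patch = 16L, wavelengths = seq(400, 2500, length.out = 120L),
                                  protein = c("uniform", "classes"), noise_sd = 0.01,
                                  alpha = 0.35, rng_seed = 1L) {
  protein <- match.arg(protein)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(rng_seed)
  p <- switch(protein,
    uniform = stats::runif(n, 7.69, 19.65),
    classes = {
      cls <- rep_len(c("low", "medium", "high"), n)[sample.int(n)]
      ifelse(cls == "low", pmin(pmax(stats::rnorm(n, 8.6, 0.3), 7.69), 9.5),
      ifelse(cls == "medium", pmin(pmax(stats::rnorm(n, 12, 0.4), 10.6), 13.4),
             pmin(pmax(stats::rnorm(n, 17, 0.5), 14.7), 19.65)))
    })
  nb <- length(wavelengths)
  patches <- array(0, dim = c(patch, patch, nb, n))
  mask <- array(0L, dim = c(patch, patch, n))
  ctr <- (patch - 1) / 2
  xg <- rep(0:(patch - 1L), each = patch); yg <- rep(0:(patch - 1L), times = patch)
  for (i in seq_len(n)) {
    a <- stats::runif(1, 0.33, 0.42) * patch   # semi-axes scale with patch size
    b <- stats::runif(1, 0.24, 0.32) * patch
    dx <- stats::runif(1, -0.8, 0.8); dy <- stats::runif(1, -0.8, 0.8)
    inside <- ((xg - ctr - dx) / a)^2 + ((yg - ctr - dy) / b)^2 <= 1
    m <- matrix(inside, patch, patch)
    spec_i <- seed_reflectance(wavelengths, p[i], alpha = alpha)
    cube <- array(outer(as.numeric(m), spec_i), dim = c(patch, patch, nb))
    if (noise_sd > 0) {
      noise <- array(stats::rnorm(patch * patch * nb, 0, noise_sd), dim = dim(cube))
      cube <- pmax(cube + noise * as.numeric(m), 0)  # noise only on seed pixels
    }
    patches[, , , i] <- cube
    mask[, , i] <- m
  }
  list(patches = patches, mask = mask, protein = p,
       class_label = factor(vapply(p, protein_class, character(1)),
                            levels = c("low", "medium", "high")),
       wavelengths = wavelengths)
}
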