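# Shared fixtures: all built in code at test time.

# small random cube
make_cube <- function(h = 8, w = 8, b = 5, seed = 1, interleave = "bil") {
  set.seed(seed)
  spectral_cube(array(round(runif(h * w * b), 4), dim = c(h, w, b)),
                seq(400, 400 + 10 * (b - 1), by = 10), interleave = interleave)
}

# a reduced-band scene spec that keeps tests fast; band counts are scaled
# down, geometry and defaults are the simulator's own
small_scene_spec <- function(n_seeds = 24, noise_sd = 0.01, rng_seed = 1, ...) {
  spec <- scene_spec(noise_sd = noise_sd,
                     vnir_wavelengths = seq(400, 1000, length.out = 60),
                     swir_wavelengths = seq(960, 2500, length.out = 72),
                     rng_seed = rng_seed, ...)
  spec$protein_pct <- spec$protein_pct[seq_len(n_seeds)]
  spec
}

pixel_f1 <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  2 * tp / (2 * tp + fp + fn)
}

# standalone seed dataset -> list of crop-like objects for spectra_matrix()
dataset_crops <- function(ds) {
  lapply(seq_along(ds$protein), function(i)
    list(patch = ds$patches[, , , i], mask = ds$mask[, , i],
         wavelengths = ds$wavelengths))
}
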