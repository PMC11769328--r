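#' Mean spectrum of a seed crop
#'
#' Per-band mean over the crop's seed pixels only (the zeroed background is
#' excluded via the crop mask).
#'
#' @param crop a `seed_crop` from [crop_seed()], or any list with `patch`
#'   (h x w x bands) and `mask` (h x w) elements.
#' @return Numeric vector, one value per band.
#' @export
mean_spectrum <- function(crop) {
  sel <- crop$mask > 0
  if (!any(sel)) stop("crop contains no seed pixels")
  apply(crop$patch, 3L, function(M) mean(M[sel]))
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Local least-squares polynomial smoothing; with the default window of 7 and
#' polynomial order 3 the filter passes cubics through unchanged while
#' attenuating high-frequency noise.
#'
#' @param spectrum numeric vector.
#' @param window odd filter window length (default 7), `<= length(spectrum)`.
#' @param polyorder polynomial order (default 3), `< window`.
#' @return Smoothed vector of the same length.
#' @export
smooth_spectrum <- function(spectrum, window = 7L, polyorder = 3L) {
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (window > length(spectrum)) stop("window (", window,
                                      ") exceeds spectrum length (", length(spectrum), ")")
  as.numeric(signal::sgolayfilt(spectrum, p = polyorder, n = window))
}

#' All pairwise band ratios of a spectrum
#'
#' For every band pair (j, k) with j < k, in lexicographic order, computes
#' R_jk = X_j / X_k, giving C(C-1)/2 derived features for C bands. A
#' denominator below `eps` yields 0 for that ratio (shape-stable epsilon
#' guard) with an attribute flagging the affected positions.
#'
#' @param spectrum numeric vector of length C.
#' @param eps denominator guard (default 1e-8).
#' @return Numeric vector of length `C*(C-1)/2`, named `ratio:<j>/<k>` by
#'   band position (see [band_ratio_names()] for wavelength-based names).
#' @export
band_ratios <- function(spectrum, eps = 1e-8) {
  C <- length(spectrum)
  if (C < 2L) return(numeric(0))
  jk <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  jk <- jk[order(jk[, 1L], jk[, 2L]), , drop = FALSE]
  num <- spectrum[jk[, 1L]]; den <- spectrum[jk[, 2L]]
  guarded <- abs(den) < eps
  out <- ifelse(guarded, 0, num / den)
  names(out) <- paste0("ratio:", jk[, 1L], "/", jk[, 2L])
  if (any(guarded)) attr(out, "guarded") <- which(guarded)
  out
}

#' Feature names for bands and ratios at given wavelengths
#'
#' @param wavelengths band-center wavelengths in nm.
#' @param what `"bands"`, `"ratios"` or `"both"`.
#' @return Character vector of `band:<nm>` and/or `ratio:<nm>/<nm>` names.
#' @export
fmt_wl <- function(x) trimws(formatC(x, format = "g", digits = 8))

band_ratio_names <- function(wavelengths, what = c("both", "bands", "ratios")) {
  what <- match.arg(what)
  wl <- fmt_wl(wavelengths)
  bands <- paste0("band:", wl)
  if (what == "bands") return(bands)
  C <- length(wavelengths)
  ratios <- if (C >= 2L) {
    jk <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
    jk <- jk[order(jk[, 1L], jk[, 2L]), , drop = FALSE]
    paste0("ratio:", wl[jk[, 1L]], "/", wl[jk[, 2L]])
  } else character(0)
  if (what == "ratios") ratios else c(bands, ratios)
}

#' Min-max normalization fitted on training data
#'
#' Per-column (x - min) / (max - min), with min and max taken from the
#' training matrix only; the same affine map is applied to any further
#' matrices (values outside the training range may fall outside [0, 1] and
#' are not clipped). Constant training columns map to 0 everywhere.
#'
#' @param train numeric matrix (samples x features).
#' @param ... further matrices with the same columns.
#' @return A list of normalized matrices (`train` first), with the fitted
#'   `min` and `range` attached as attributes of the list.
#' @export
minmax_fit_apply <- function(train, ...) {
  if (!nrow(train)) stop("training matrix is empty")
  mins <- apply(train, 2L, min)
  rngs <- apply(train, 2L, max) - mins
  constant <- rngs == 0
  rngs[constant] <- 1
  norm1 <- function(m) {
    out <- sweep(sweep(m, 2L, mins), 2L, rngs, "/")
    out[, constant] <- 0
    out
  }
  out <- lapply(c(list(train), list(...)), norm1)
  names(out) <- c("train", names(list(...)))
  attr(out, "min") <- mins
  attr(out, "range") <- rngs
  out
}

#' Protein class from a percentage
#'
#' Below 10% is low, 10-14% (inclusive on both ends) is medium, above 14% is
#' high — the 3-class scheme used for protein classification.
#'
#' @param p protein percentage, >= 0.
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
protein_class <- function(p) {
  if (p < 0) stop("protein percentage must be >= 0")
  if (p < 10) "low" else if (p <= 14) "medium" else "high"
}

#' Summary statistics of a protein distribution
#'
#' The eleven ground-truth statistics reported for protein labels: mean,
#' median, mode (most frequent value after rounding to 0.01), range,
#' variance, standard deviation, IQR, Q1, Q3, skewness and excess kurtosis.
#' Quartiles use linear interpolation (R's default type 7).
#'
#' @param values numeric vector of percentages, length >= 2.
#' @return Named list of the eleven statistics.
#' @export
summarize_protein <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  r <- round(values, 2)
  tab <- table(r)
  mode_val <- as.numeric(names(tab)[which.max(tab)])
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  n <- length(values)
  m <- mean(values); s <- stats::sd(values)
  skew <- mean((values - m)^3) / (mean((values - m)^2))^1.5
  kurt <- mean((values - m)^4) / (mean((values - m)^2))^2 - 3
  list(mean = m, median = stats::median(values), mode = mode_val,
       range = max(values) - min(values), variance = stats::var(values),
       sd = s, iqr = q[2L] - q[1L], q1 = q[1L], q3 = q[2L],
       skewness = skew, kurtosis = kurt)
}

round_half_up <- function(x) floor(x + 0.5)

#' Train/test/validation split counts and assignment
#'
#' Splits n samples with a test:train ratio of 3:1 and a validation:train
#' ratio of 4:1, i.e. `n_test = round(n/4)` and `n_val = round((n - n_test)/5)`
#' with half-up rounding (the only rounding convention that reproduces the
#' published 5057 -> (3034, 1264, 759) and 4746 -> (2847, 1187, 712) triples),
#' and the remainder training. Assignment is by seeded shuffle.
#'
#' @param n_total total sample count, >= 5.
#' @param rng_seed integer seed for the shuffle.
#' @return `list(n_total, n_train, n_test, n_val, assignment)` where
#'   `assignment` is a factor of length `n_total` with levels
#'   train/test/validation.
#' @export
split_dataset <- function(n_total, rng_seed = 1L) {
  if (n_total < 5L) stop("n_total must be >= 5")
  n_test <- round_half_up(n_total / 4)
  n_val <- round_half_up((n_total - n_test) / 5)
  n_train <- n_total - n_test - n_val
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(rng_seed)
  idx <- sample.int(n_total)
  assignment <- factor(rep(NA_character_, n_total),
                       levels = c("train", "test", "validation"))
  assignment[idx[seq_len(n_train)]] <- "train"
  assignment[idx[n_train + seq_len(n_test)]] <- "test"
  assignment[idx[n_train + n_test + seq_len(n_val)]] <- "validation"
  list(n_total = n_total, n_train = n_train, n_test = n_test, n_val = n_val,
       assignment = assignment)
}

#' Per-seed feature matrix from crops
#'
#' Computes masked mean spectra for a list of seed crops, optionally smooths
#' each spectrum (Savitzky-Golay 7/3), and returns a samples x bands matrix
#' with `band:<nm>` column names.
#'
#' @param crops list of `seed_crop` objects sharing one wavelength grid.
#' @param smooth apply [smooth_spectrum()] to each mean spectrum.
#' @param window,polyorder smoothing parameters.
#' @return Numeric matrix (length(crops) x bands).
#' @export
spectra_matrix <- function(crops, smooth = TRUE, window = 7L, polyorder = 3L) {
  stopifnot(length(crops) > 0L)
  wl <- crops[[1L]]$wavelengths
  X <- t(vapply(crops, function(cr) {
    s <- mean_spectrum(cr)
    if (smooth) smooth_spectrum(s, window, polyorder) else s
  }, numeric(length(wl))))
  colnames(X) <- band_ratio_names(wl, "bands")
  X
}
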