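#' Build one of the three feature dataset variants
#'
#' Variant 1: all spectral bands. Variant 2: the top 100 bands by permutation
#' importance plus all pairwise ratios of those bands. Variant 3: all bands
#' plus all pairwise ratios. Ratios are computed on raw (pre-normalization)
#' reflectance.
#'
#' @param spectra samples x bands matrix with `band:<nm>` column names (see
#'   [spectra_matrix()]).
#' @param wavelengths band-center wavelengths, one per column of `spectra`.
#' @param variant 1, 2 or 3.
#' @param importance importance table from [permutation_importance()];
#'   required for variant 2.
#' @param top_k how many top bands variant 2 keeps (default 100).
#' @return Numeric matrix with named columns per the variant definition.
#' @export
build_variant <- function(spectra, wavelengths, variant, importance = NULL, top_k = 100L) {
  stopifnot(variant %in% 1:3, ncol(spectra) == length(wavelengths))
  if (variant == 1L) return(spectra)
  if (variant == 2L) {
    if (is.null(importance)) stop("variant 2 requires a permutation-importance table")
    top_wl <- select_top_bands(importance, k = top_k)
    keep <- match(paste0("band:", fmt_wl(top_wl)), colnames(spectra))
    keep <- sort(keep)
    spectra <- spectra[, keep, drop = FALSE]
    wavelengths <- wavelengths[keep]
  }
  ratios <- t(apply(spectra, 1L, band_ratios))
  colnames(ratios) <- band_ratio_names(wavelengths, "ratios")
  cbind(spectra, ratios)
}

#' Fit a feature-based protein regressor
#'
#' Wraps the two regressor families used for protein estimation: a
#' random-forest ensemble (500 trees by default) and radial-kernel support
#' vector regression (C = 10, epsilon = 0.1 by default). Fitting is
#' deterministic given `rng_seed`.
#'
#' @param X samples x features numeric matrix.
#' @param y protein percentages, one per row of `X`.
#' @param family `"rf"` or `"svr"`.
#' @param ntree,cost,epsilon hyperparameters of the respective family.
#' @param rng_seed integer seed.
#' @return An object of class `protein_regressor` with a `predict` method.
#' @export
train_regressor <- function(X, y, family = c("rf", "svr"), ntree = 500L,
                            cost = 10, epsilon = 0.1, rng_seed = 1L) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(rng_seed)
  fit <- switch(family,
    rf = randomForest::randomForest(x = X, y = y, ntree = ntree),
    svr = e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                     cost = cost, epsilon = epsilon))
  structure(list(fit = fit, family = family, rng_seed = rng_seed,
                 features = colnames(X)), class = "protein_regressor")
}

#' @export
predict.protein_regressor <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, as.matrix(newdata)))
}

#' @export
print.protein_regressor <- function(x, ...) {
  cat(sprintf("<protein_regressor> family: %s, %d features\n",
              x$family, length(x$features)))
  invisible(x)
}

#' Permutation feature importance
#'
#' Importance of a feature is the drop in held-out R2 when that feature's
#' column is randomly shuffled: baseline score minus the mean score over
#' `n_repeats` independent shuffles. Features named `band:<nm>` get their
#' wavelength parsed into the table.
#'
#' @param model a `protein_regressor`.
#' @param X,y evaluation data (a held-out fold, not the training rows, to
#'   avoid optimistic baselines).
#' @param n_repeats shuffles per feature (default 10).
#' @param rng_seed integer seed.
#' @return `data.frame(feature, wavelength, importance, sd)` sorted as the
#'   columns of `X`.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 10L, rng_seed = 1L) {
  X <- as.matrix(X)
  baseline <- regression_metrics(y, predict(model, X))$r2
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(rng_seed)
  nmz <- colnames(X)
  res <- vapply(seq_len(ncol(X)), function(j) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      baseline - regression_metrics(y, predict(model, Xp))$r2
    }, numeric(1))
    c(mean(drops), stats::sd(drops))
  }, numeric(2))
  wl <- suppressWarnings(as.numeric(sub("^band:", "", nmz)))
  data.frame(feature = nmz, wavelength = wl,
             importance = res[1L, ], sd = res[2L, ])
}

#' Select the most important spectral bands
#'
#' Ranks band features by descending mean importance (ties broken toward the
#' lower wavelength) and returns the top k wavelengths.
#'
#' @param importance table from [permutation_importance()].
#' @param k number of bands to keep (default 100).
#' @return Numeric vector of k wavelengths.
#' @export
select_top_bands <- function(importance, k = 100L) {
  bands <- importance[!is.na(importance$wavelength), , drop = FALSE]
  if (nrow(bands) < k) stop("only ", nrow(bands), " band features; cannot select ", k)
  ord <- order(-bands$importance, bands$wavelength)
  bands$wavelength[ord[seq_len(k)]]
}
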