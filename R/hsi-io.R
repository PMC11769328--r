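#' Construct a hyperspectral cube
#'
#' A `spectral_cube` is the package's container for a height x width x bands
#' volume of sensor data together with its per-band wavelengths. Units travel
#' with the cube as a tag (`"dn"` for raw digital numbers, `"radiance"` for
#' W/sr.m^2.nm, `"reflectance"` for fractions) so calibration stages can check
#' what they are being fed.
#'
#' @param data numeric array of dimension `c(height, width, bands)`. A matrix
#'   is accepted for a single-band cube.
#' @param wavelengths numeric vector of band-center wavelengths in nm, strictly
#'   increasing, one per band.
#' @param units one of `"dn"`, `"radiance"`, `"reflectance"`.
#' @param interleave storage order used when the cube is written to ENVI:
#'   `"bil"`, `"bip"` or `"bsq"`.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelengths, units = c("reflectance", "radiance", "dn"),
                          interleave = c("bil", "bip", "bsq")) {
  units <- match.arg(units)
  interleave <- match.arg(interleave)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a height x width x bands array")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length(wavelengths) must equal the number of bands (",
         dim(data)[3L], "), got ", length(wavelengths))
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(data))) stop("cube data must be finite")
  structure(list(data = data, wavelengths = wavelengths,
                 units = units, interleave = interleave),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d px, %d bands (%.1f-%.1f nm), units: %s\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths), x$units))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

cube_height <- function(cube) dim(cube$data)[1L]
cube_width  <- function(cube) dim(cube$data)[2L]
cube_bands  <- function(cube) dim(cube$data)[3L]

#' Find the band nearest a wavelength
#'
#' Resolves a requested wavelength (e.g. the 410/456/553/654/852 nm bands used
#' by the segmentation rule) to the index of the stored band whose center is
#' nearest. Ties go to the lower index. Requests further than one inter-band
#' step outside the cube's wavelength range are rejected.
#'
#' @param cube a [spectral_cube()].
#' @param wavelength_nm requested wavelength in nm.
#' @return Integer band index.
#' @export
band_at <- function(cube, wavelength_nm) {
  w <- cube$wavelengths
  if (length(w) == 0L) stop("cube has no bands")
  step <- if (length(w) > 1L) stats::median(diff(w)) else Inf
  if (wavelength_nm < min(w) - step || wavelength_nm > max(w) + step)
    stop(sprintf("wavelength %.6g nm outside cube range [%.6g, %.6g] nm (+/- one band step)",
                 wavelength_nm, min(w), max(w)))
  # which.min returns the first (lower) index on exact ties
  which.min(abs(w - wavelength_nm))
}

# ---- ENVI format -----------------------------------------------------------
# ENVI stores an ASCII `.hdr` describing a raw binary. `samples` is image
# width (columns), `lines` is height (rows). Within the binary, samples vary
# fastest along a line; interleave decides how lines/bands nest.

envi_data_types <- c(`1` = "integer", `2` = "integer", `3` = "integer",
                     `4` = "double", `5` = "double", `12` = "integer")
envi_type_size  <- c(`1` = 1L, `2` = 2L, `3` = 4L, `4` = 4L, `5` = 8L, `12` = 2L)

parse_envi_header <- function(header_path) {
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  if (!grepl("^ENVI", txt)) stop("not an ENVI header: ", header_path)
  fields <- list()
  # match `key = value` where value may be a {...} block spanning lines
  pat <- gregexpr("([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt, perl = TRUE)
  for (m in regmatches(txt, pat)[[1]]) {
    key <- tolower(trimws(sub("\\s*=.*$", "", m)))
    val <- trimws(sub("^[^=]*=\\s*", "", m))
    fields[[key]] <- val
  }
  fields
}

parse_envi_list <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1]]))
}

#' Read an ENVI hyperspectral cube
#'
#' Reads the ASCII header and its paired raw binary. The header must declare
#' `samples`, `lines`, `bands`, `interleave`, `data type` and a `wavelength`
#' block. Wavelengths stated in micrometers (all values < 10) are converted to
#' nm. The binary file size must agree with the declared dimensions.
#'
#' @param header_path path to the `.hdr` file; the binary is looked up as the
#'   same path without the `.hdr` extension (or with `.img`/`.dat` appended).
#' @param units unit tag to attach to the cube (ENVI headers do not carry one).
#' @return A [spectral_cube()].
#' @export
read_envi <- function(header_path, units = "reflectance") {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  h <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  if (is.null(h[["wavelength"]])) stop("ENVI header missing wavelength block")
  samples <- as.integer(h[["samples"]]); lines <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  interleave <- tolower(trimws(h[["interleave"]]))
  dtype <- trimws(h[["data type"]])
  if (!dtype %in% names(envi_data_types)) stop("unsupported ENVI data type: ", dtype)
  wl <- parse_envi_list(h[["wavelength"]])
  if (length(wl) != bands)
    stop("header declares ", bands, " bands but ", length(wl), " wavelengths")
  if (all(wl < 10)) wl <- wl * 1000  # micrometers -> nm
  stem <- sub("\\.hdr$", "", header_path)
  bin <- c(stem, paste0(stem, ".img"), paste0(stem, ".dat"))
  bin <- bin[file.exists(bin)][1]
  if (is.na(bin)) stop("binary file for ", header_path, " not found")
  size1 <- envi_type_size[[dtype]]
  n <- samples * lines * bands
  if (file.info(bin)$size != n * size1)
    stop("binary size ", file.info(bin)$size, " inconsistent with header (expected ",
         n * size1, " bytes)")
  endian <- if (!is.null(h[["byte order"]]) && trimws(h[["byte order"]]) == "1") "big" else "little"
  con <- file(bin, "rb"); on.exit(close(con))
  raw <- readBin(con, what = envi_data_types[[dtype]], n = n, size = size1,
                 endian = endian, signed = TRUE)
  # reorder flat vector into [row(line), col(sample), band]
  arr <- switch(interleave,
    bsq = aperm(array(raw, dim = c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(raw, dim = c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(raw, dim = c(bands, samples, lines)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave))
  spectral_cube(arr, wl, units = units, interleave = interleave)
}

#' Write a cube as an ENVI header + binary pair
#'
#' Writes 32-bit float data (ENVI data type 4) by default, little-endian, with
#' the cube's interleave and wavelength list in the header.
#'
#' @param cube a [spectral_cube()].
#' @param out_path output path; a `.hdr` extension is appended if absent (the
#'   binary is written at the path without `.hdr`).
#' @param data_type ENVI data type code: 4 (float32, default) or 5 (float64).
#' @return The header path, invisibly.
#' @export
write_envi <- function(cube, out_path, data_type = 4L) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube_bands(cube) < 1L || any(dim(cube$data) == 0L)) stop("cannot write an empty cube")
  if (!data_type %in% c(4L, 5L)) stop("data_type must be 4 (float32) or 5 (float64)")
  hdr <- if (grepl("\\.hdr$", out_path)) out_path else paste0(out_path, ".hdr")
  bin <- sub("\\.hdr$", "", hdr)
  d <- dim(cube$data)
  flat <- switch(cube$interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  con <- file(bin, "wb")
  writeBin(as.numeric(flat), con, size = envi_type_size[[as.character(data_type)]],
           endian = "little")
  close(con)
  lines <- c(
    "ENVI",
    "description = { hsiseed spectral cube }",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", cube$interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(formatC(cube$wavelengths, format = "g", digits = 10), collapse = ", "),
           " }"))
  writeLines(lines, hdr)
  invisible(hdr)
}
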