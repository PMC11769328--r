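#' Radiometric response of a pushbroom sensor
#'
#' Bundles the per-pixel, per-band response matrix (digital numbers produced
#' per unit radiance and second), the integration time and the known radiance
#' of the white-reference panel during the bright scan. Built by
#' [compute_response()] and consumed by [to_radiance()].
#'
#' @param response array with the dimensions of a cube: DN per radiance unit
#'   per second of integration.
#' @param integration_time integration time in seconds, > 0.
#' @param panel_radiance radiance of the reference panel during the bright
#'   scan (same units as the radiances to recover).
#' @param invalid logical array flagging pixels whose bright signal did not
#'   exceed dark; those cannot be calibrated.
#' @return An object of class `radiometric_response`.
#' @export
radiometric_response <- function(response, integration_time, panel_radiance,
                                 invalid = NULL) {
  if (integration_time <= 0) stop("integration_time must be > 0")
  if (panel_radiance <= 0) stop("panel_radiance must be > 0")
  if (is.null(invalid)) invalid <- array(FALSE, dim = dim(response))
  structure(list(response = response, integration_time = integration_time,
                 panel_radiance = panel_radiance, invalid = invalid),
            class = "radiometric_response")
}

check_same_shape <- function(a, b, what) {
  if (!identical(dim(a$data), dim(b$data)))
    stop(what, ": cube dimensions differ (",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), ")")
}

#' Subtract the dark-current frame from a raw scan
#'
#' Removes the sensor's background electronic signal, measured with no light,
#' from a raw digital-number cube. Negative differences (dark-noise
#' excursions) are clipped to zero: a negative photon count is physically
#' spurious.
#'
#' @param raw,dark DN cubes of identical dimensions.
#' @return A DN [spectral_cube()] of the background-subtracted signal.
#' @export
subtract_background <- function(raw, dark) {
  check_same_shape(raw, dark, "subtract_background")
  spectral_cube(pmax(raw$data - dark$data, 0), raw$wavelengths,
                units = "dn", interleave = raw$interleave)
}

#' Compute the radiometric response from a bright panel scan
#'
#' The background-subtracted bright signal divided by the panel's known
#' radiance gives each pixel/band's DN-per-radiance response. Pixels whose
#' bright signal does not exceed dark are flagged invalid rather than given a
#' nonpositive response.
#'
#' @param bright,dark DN cubes of identical dimensions (panel filling the
#'   frame during the bright scan).
#' @param panel_radiance known radiance of the panel during the bright scan.
#' @param integration_time integration time in seconds used for the scans.
#' @return A [radiometric_response()].
#' @export
compute_response <- function(bright, dark, panel_radiance, integration_time = 1) {
  check_same_shape(bright, dark, "compute_response")
  if (panel_radiance <= 0) stop("panel_radiance must be > 0")
  num <- bright$data - dark$data
  invalid <- num <= 0
  if (any(invalid))
    warning(sum(invalid), " pixel/band cells have bright <= dark; flagged invalid")
  resp <- num / (panel_radiance * integration_time)
  resp[invalid] <- NA_real_
  radiometric_response(resp, integration_time, panel_radiance, invalid)
}

#' Convert a background-subtracted signal to spectral radiance
#'
#' Divides the signal by response times integration time, recovering radiance
#' in W/sr.m^2.nm at the sensor's entrance pupil. Invalid response cells
#' propagate as zero radiance.
#'
#' @param signal background-subtracted DN cube (see [subtract_background()]).
#' @param resp a [radiometric_response()] with dimensions matching `signal`.
#' @return A radiance [spectral_cube()].
#' @export
to_radiance <- function(signal, resp) {
  stopifnot(inherits(resp, "radiometric_response"))
  if (resp$integration_time <= 0) stop("integration_time must be > 0")
  if (!identical(dim(signal$data), dim(resp$response)))
    stop("to_radiance: signal and response dimensions differ")
  L <- signal$data / (resp$response * resp$integration_time)
  L[resp$invalid] <- 0
  spectral_cube(L, signal$wavelengths, units = "radiance",
                interleave = signal$interleave)
}

#' Convert scene radiance to reflectance via the reference panel
#'
#' Per band, scene radiance is divided by the mean radiance over the declared
#' panel region of interest and multiplied by the panel's nominal reflectance
#' (0.5 for the 50% Spectralon standard). The mean is the aggregation over the
#' panel region; a band whose panel radiance is not positive is an error.
#'
#' @param scene radiance cube of the scene.
#' @param panel either a radiance cube of the panel alone, or the same scene
#'   cube when `panel_region` is supplied.
#' @param panel_reflectance nominal panel reflectance in (0, 1].
#' @param panel_region optional `list(rows =, cols =)` of indices delimiting
#'   the panel within `panel`; defaults to the whole of `panel`.
#' @return A reflectance [spectral_cube()].
#' @export
to_reflectance <- function(scene, panel, panel_reflectance = 0.5, panel_region = NULL) {
  if (panel_reflectance <= 0 || panel_reflectance > 1)
    stop("panel_reflectance must be in (0, 1]")
  pd <- panel$data
  if (!is.null(panel_region)) pd <- pd[panel_region$rows, panel_region$cols, , drop = FALSE]
  panel_mean <- apply(pd, 3L, mean)
  if (any(!is.finite(panel_mean)) || any(panel_mean <= 0))
    stop("panel radiance not positive in ", sum(panel_mean <= 0), " band(s)")
  refl <- sweep(scene$data, 3L, panel_mean, "/") * panel_reflectance
  spectral_cube(refl, scene$wavelengths, units = "reflectance",
                interleave = scene$interleave)
}
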