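## Grey-level to Hounsfield-unit calibration.
##
## The HU scale is anchored at two physical references: air maps to -1000 HU
## and water to 0 HU. Given the scanner grey levels observed for the two
## references, the affine transform is fully determined.

#' Fit the two-anchor linear HU calibration
#'
#' Solves for the affine map sending the grey level of air to -1000 HU and
#' the grey level of water to 0 HU:
#' `slope = 1000 / (g_water - g_air)`, `intercept = -1000 - slope * g_air`.
#' Both anchors are reproduced to machine precision.
#'
#' @param g_air Grey level measured in an air reference region.
#' @param g_water Grey level measured in a water reference region.
#' @return A `calibration_model` with fields `g_air`, `g_water`, `slope`,
#'   `intercept`.
#' @export
#' @examples
#' m <- fit_calibration(g_air = 0, g_water = 1000)
#' m$slope      # 1
#' m$intercept  # -1000
fit_calibration <- function(g_air, g_water) {
  g_air <- as.numeric(g_air); g_water <- as.numeric(g_water)
  if (length(g_air) != 1L || length(g_water) != 1L ||
      !is.finite(g_air) || !is.finite(g_water))
    stop("anchor grey values must be single finite numbers", call. = FALSE)
  if (g_air == g_water)
    stop("degenerate calibration: air and water grey levels are equal",
         call. = FALSE)
  slope <- 1000 / (g_water - g_air)
  intercept <- -1000 - slope * g_air
  structure(list(g_air = g_air, g_water = g_water,
                 slope = slope, intercept = intercept),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> HU = %.6g * grey + %.6g  (air %.6g -> -1000, water %.6g -> 0)\n",
              x$slope, x$intercept, x$g_air, x$g_water))
  invisible(x)
}

#' Fit the calibration from air/water reference masks
#'
#' Convenience wrapper when the anchors are sampled as the mean grey level
#' inside user-supplied reference regions rather than given directly.
#'
#' @param volume Uncalibrated [scan_volume()].
#' @param air_mask,water_mask [voxel_mask()]s congruent with `volume`.
#' @return A `calibration_model`.
#' @export
fit_calibration_from_masks <- function(volume, air_mask, water_mask) {
  stopifnot(inherits(volume, "scan_volume"))
  check_congruent(volume, air_mask)
  check_congruent(volume, water_mask)
  if (!any(air_mask$values) || !any(water_mask$values))
    stop("empty reference mask", call. = FALSE)
  fit_calibration(mean(volume$values[air_mask$values]),
                  mean(volume$values[water_mask$values]))
}

#' Apply a calibration model to a grey-level volume
#'
#' Element-wise affine transform; spacing and phase are untouched and the
#' `calibrated` flag is set. Calibrating an already calibrated volume is an
#' error — double calibration silently corrupts the HU scale. Values are not
#' clamped: out-of-range HU are passed through for the densitometry stage to
#' classify.
#'
#' @param volume Uncalibrated [scan_volume()].
#' @param model A `calibration_model` from [fit_calibration()].
#' @return A calibrated [scan_volume()].
#' @export
apply_calibration <- function(volume, model) {
  stopifnot(inherits(volume, "scan_volume"), inherits(model, "calibration_model"))
  if (volume$calibrated)
    stop("volume is already calibrated to HU; refusing to calibrate twice",
         call. = FALSE)
  scan_volume(model$slope * volume$values + model$intercept,
              volume$spacing, phase = volume$phase, calibrated = TRUE)
}
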