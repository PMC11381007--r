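## Total-lung segmentation from a calibrated HU volume.
##
## Deterministic stand-in for an operator-driven semiautomatic procedure:
## 1. body extraction — air connected to the grid border is background;
## 2. aerated-voxel thresholding inside the body;
## 3. connected components, dropping specks below a physical volume floor
##    and keeping the largest lobes;
## 4. morphological closing with a physical radius, which folds dense
##    fibrotic pockets back into the *total* lung map.
## Densely consolidated lungs with no aerated seed raise an explicit error —
## the cue that a manually drawn mask (accept_manual_mask) is required.

#' Lung segmentation parameters
#'
#' @param aerated_hu_upper HU threshold below which a voxel is an aerated
#'   lung candidate (default -200 HU).
#' @param body_hu_lower HU threshold separating body tissue from background
#'   air (default -500 HU): voxels below it that connect to the grid border
#'   are background.
#' @param closing_radius_mm Radius (mm) of the spherical closing element that
#'   fills fibrotic pockets into the total lung map.
#' @param min_component_mm3 Minimum connected-component volume (mm^3) kept.
#' @param keep_components How many largest components to keep after the size
#'   filter (2 by default: left and right lung may disconnect at the carina).
#' @return A validated `segmentation_params` list.
#' @export
segmentation_params <- function(aerated_hu_upper = -200,
                                body_hu_lower = -500,
                                closing_radius_mm = 0.3,
                                min_component_mm3 = 1,
                                keep_components = 2L) {
  if (aerated_hu_upper >= 0)
    stop("`aerated_hu_upper` must be negative (aerated lung is air-like)",
         call. = FALSE)
  if (body_hu_lower > aerated_hu_upper)
    stop("`body_hu_lower` must not exceed `aerated_hu_upper`: background air is denser-than-aerated nonsense otherwise",
         call. = FALSE)
  if (closing_radius_mm < 0 || min_component_mm3 < 0)
    stop("radii and volumes must be non-negative", call. = FALSE)
  structure(list(aerated_hu_upper = aerated_hu_upper,
                 body_hu_lower = body_hu_lower,
                 closing_radius_mm = closing_radius_mm,
                 min_component_mm3 = min_component_mm3,
                 keep_components = as.integer(keep_components)),
            class = "segmentation_params")
}

## Offsets (voxels) of an ellipsoidal ball of physical radius r_mm under
## anisotropic spacing; includes the centre.
ball_offsets <- function(r_mm, spacing) {
  rv <- pmax(0L, as.integer(floor(r_mm / spacing)))
  g <- expand.grid(a = -rv[1]:rv[1], b = -rv[2]:rv[2], c = -rv[3]:rv[3])
  keep <- (g$a * spacing[1])^2 + (g$b * spacing[2])^2 + (g$c * spacing[3])^2 <=
    r_mm^2 + 1e-12
  as.matrix(g[keep, , drop = FALSE])
}

storage_int_matrix <- function(m) {
  m <- as.matrix(m); storage.mode(m) <- "integer"; dimnames(m) <- NULL; m
}

## Morphological closing with a physical radius.
binary_close <- function(mask_arr, r_mm, spacing) {
  if (r_mm <= 0) return(mask_arr)
  off <- storage_int_matrix(ball_offsets(r_mm, spacing))
  if (nrow(off) <= 1L) return(mask_arr)
  dil <- .binary_dilate3d(mask_arr, off)
  .binary_erode3d(dil, off)
}

## Background air: below body_hu_lower and 6-connected to the grid border.
background_air <- function(values, body_hu_lower) {
  air <- values < body_hu_lower
  if (!any(air)) return(array(FALSE, dim = dim(values)))
  lab <- .cc_label3d(air)
  d <- dim(values)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0]
  bg <- array(lab %in% border, dim = d)
  bg
}

#' Segment the total lung from a calibrated volume
#'
#' @param volume Calibrated [scan_volume()].
#' @param params A [segmentation_params()].
#' @return A [voxel_mask()] labelled `"lung"`, congruent with the volume.
#'   Raises an `empty-segmentation` error when no aerated candidate voxels
#'   exist (the manual-mask path).
#' @export
segment_lung <- function(volume, params = segmentation_params()) {
  stopifnot(inherits(volume, "scan_volume"))
  if (!volume$calibrated)
    stop("volume must be calibrated to HU before segmentation", call. = FALSE)
  vals <- volume$values
  spacing <- volume$spacing

  bg <- background_air(vals, params$body_hu_lower)
  candidates <- (vals < params$aerated_hu_upper) & !bg
  if (!any(candidates))
    stop("empty segmentation: no aerated voxels inside the body; supply a manual mask",
         call. = FALSE)

  lab <- .cc_label3d(candidates)
  ncomp <- attr(lab, "n_components")
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  min_vox <- params$min_component_mm3 / prod(spacing)
  keep <- which(sizes >= min_vox)
  if (length(keep) == 0L)
    stop("empty segmentation: all aerated components below the size floor; supply a manual mask",
         call. = FALSE)
  if (length(keep) > params$keep_components)
    keep <- keep[order(sizes[keep], decreasing = TRUE)][seq_len(params$keep_components)]
  mask_arr <- array(lab %in% keep, dim = dim(vals))

  mask_arr <- binary_close(mask_arr, params$closing_radius_mm, spacing)
  voxel_mask(mask_arr, spacing, label = "lung")
}

#' Accept a manually drawn lung mask
#'
#' Loads a mask drawn in an external tool, binarises it (any nonzero value is
#' foreground), verifies congruence with the volume and passes it through
#' unchanged, recording provenance.
#'
#' @param volume The [scan_volume()] the mask belongs to.
#' @param mask_path Path to the mask file, or an in-memory [voxel_mask()].
#' @return A [voxel_mask()] labelled `"lung"` with attribute
#'   `provenance = "manual"`.
#' @export
accept_manual_mask <- function(volume, mask_path) {
  stopifnot(inherits(volume, "scan_volume"))
  m <- if (inherits(mask_path, "voxel_mask")) {
    voxel_mask(mask_path$values, mask_path$spacing, label = "lung")
  } else {
    read_mask(mask_path, label = "lung")
  }
  check_congruent(volume, m)
  attr(m, "provenance") <- "manual"
  message(sprintf("manual lung mask accepted (%d voxels)", sum(m$values)))
  m
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b [voxel_mask()]s on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("masks are not congruent", call. = FALSE)
  inter <- sum(a$values & b$values)
  denom <- sum(a$values) + sum(b$values)
  if (denom == 0) return(1)
  2 * inter / denom
}
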