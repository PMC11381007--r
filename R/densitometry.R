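## Per-phase lung densitometry: readouts, aeration compartments, cross-phase
## biomarkers and the HU frequency histogram.
##
## All quantities derive from four primitives measured over the segmented
## lung: N (voxel count), V = N x voxel volume, MLA = mean HU, and
## Gas = V x MLA / (-1000). Aeration compartments partition the HU axis into
## normo-aerated [-860, -435], hypo-aerated (-435, -121) and non-aerated
## [-121, 121]; HU outside [-860, 121] is reported in an explicit
## "unclassified" bucket rather than discarded, so the four percentages
## always sum to 100.

#' Aeration compartment HU ranges
#'
#' The bracket semantics follow the interval notation literally: the
#' normo-aerated interval is closed (so -435 HU is normo), the hypo-aerated
#' interval is open at both ends, and the non-aerated interval is closed
#' (so -121 HU is non-aerated).
#'
#' @param normo,hypo,non Length-2 numeric HU intervals.
#' @return An `aeration_ranges` list.
#' @export
aeration_ranges <- function(normo = c(-860, -435),
                            hypo = c(-435, -121),
                            non = c(-121, 121)) {
  if (!(normo[2] == hypo[1] && hypo[2] == non[1]))
    stop("compartment intervals must be contiguous", call. = FALSE)
  if (normo[1] >= normo[2] || hypo[1] >= hypo[2] || non[1] >= non[2])
    stop("each interval must have positive width", call. = FALSE)
  structure(list(normo = normo, hypo = hypo, non = non),
            class = "aeration_ranges")
}

#' Classify HU values into aeration compartments
#'
#' Vectorised total function: every finite HU maps to exactly one of
#' `"Normo"`, `"Hypo"`, `"Non"` or `"Unclassified"`.
#'
#' @param hu Numeric vector of HU values.
#' @param ranges An [aeration_ranges()].
#' @return Factor with levels `Normo`, `Hypo`, `Non`, `Unclassified`.
#' @export
#' @examples
#' classify_voxel(c(-600, -435, -121, -900, 500))
classify_voxel <- function(hu, ranges = aeration_ranges()) {
  if (any(!is.finite(hu))) stop("HU values must be finite", call. = FALSE)
  out <- rep("Unclassified", length(hu))
  out[hu >= ranges$normo[1] & hu <= ranges$normo[2]] <- "Normo"
  out[hu > ranges$hypo[1] & hu < ranges$hypo[2]] <- "Hypo"
  out[hu >= ranges$non[1] & hu <= ranges$non[2]] <- "Non"
  factor(out, levels = c("Normo", "Hypo", "Non", "Unclassified"))
}

#' Per-phase densitometric readouts over a lung mask
#'
#' Computes the voxel count `N_p`, lung volume `V_p = N_p x voxel volume`
#' (mm^3), mean lung attenuation `MLA_p` (HU), gas content
#' `Gas_p = V_p x MLA_p / (-1000)` (mm^3) and the compartment percentages of
#' `N_p`. A positive MLA yields a negative gas volume; it is reported
#' unclamped and flagged via `gas_negative` because it signals a pathological
#' mask rather than a quantity to hide.
#'
#' @param volume Calibrated [scan_volume()] with its phase set.
#' @param mask Congruent [voxel_mask()] (the total lung map).
#' @param ranges An [aeration_ranges()].
#' @return A `densitometry_result` list: `phase`, `N`, `V`, `MLA`, `Gas`,
#'   `pct_normo`, `pct_hypo`, `pct_non`, `pct_unclassified`, `gas_negative`.
#' @export
compute_readouts <- function(volume, mask, ranges = aeration_ranges()) {
  stopifnot(inherits(volume, "scan_volume"), inherits(mask, "voxel_mask"))
  if (!volume$calibrated)
    stop("volume must be calibrated to HU before densitometry", call. = FALSE)
  if (is.na(volume$phase))
    stop("volume phase (P01/P02) must be set for densitometry", call. = FALSE)
  check_congruent(volume, mask)
  hu <- volume$values[mask$values]
  n <- length(hu)
  if (n < 1L) stop("empty lung mask", call. = FALSE)
  v <- n * voxel_volume(volume)
  mla <- mean(hu)
  gas <- v * mla / (-1000)
  cls <- classify_voxel(hu, ranges)
  counts <- tabulate(cls, nbins = 4L)
  pct <- 100 * counts / n
  structure(list(
    phase = volume$phase, N = n, V = v, MLA = mla, Gas = gas,
    pct_normo = pct[1], pct_hypo = pct[2], pct_non = pct[3],
    pct_unclassified = pct[4], gas_negative = gas < 0),
    class = "densitometry_result")
}

#' @export
print.densitometry_result <- function(x, ...) {
  cat(sprintf(
    "<densitometry_result> %s: N=%d V=%.2f mm^3 MLA=%.1f HU Gas=%.2f mm^3\n  %%Normo=%.1f %%Hypo=%.1f %%Non=%.1f %%Unclassified=%.1f\n",
    x$phase, x$N, x$V, x$MLA, x$Gas,
    x$pct_normo, x$pct_hypo, x$pct_non, x$pct_unclassified))
  invisible(x)
}

#' Cross-phase structural biomarkers
#'
#' From the per-phase readouts derives the tissue volume
#' `Tissue = V_P02 - Gas_P02` (mm^3, end-expiration) and the gas percentages
#' `%Gas_p = Gas_p x 100 / V_p` for both phases. Note the algebraic identity
#' `%Gas_p = -MLA_p / 10`, used as an internal consistency check in the test
#' suite.
#'
#' @param result_a,result_b `densitometry_result`s for the two phases of the
#'   same animal and time-point, in either order.
#' @return A `biomarker_set` list: `tissue`, `pct_gas_P01`, `pct_gas_P02`.
#' @export
compute_biomarkers <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "densitometry_result"),
            inherits(result_b, "densitometry_result"))
  phases <- c(result_a$phase, result_b$phase)
  if (anyDuplicated(phases) || !setequal(phases, c("P01", "P02")))
    stop("need exactly one P01 and one P02 result", call. = FALSE)
  r <- list(result_a, result_b)
  p01 <- r[[match("P01", phases)]]
  p02 <- r[[match("P02", phases)]]
  structure(list(
    tissue = p02$V - p02$Gas,
    pct_gas_P01 = p01$Gas * 100 / p01$V,
    pct_gas_P02 = p02$Gas * 100 / p02$V),
    class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("<biomarker_set> Tissue=%.2f mm^3  %%Gas_P01=%.1f  %%Gas_P02=%.1f\n",
              x$tissue, x$pct_gas_P01, x$pct_gas_P02))
  invisible(x)
}

#' HU frequency histogram over the lung mask
#'
#' Equal-width bins on `[lo, hi]`; the defaults reproduce the standard lung
#' display window (min -860 HU, max +121 HU, 163 bins). Counts conserve the
#' number of masked voxels inside `[lo, hi]`; each bin is annotated with the
#' compartment of its midpoint for colour-coded rendering.
#'
#' @param volume Calibrated [scan_volume()].
#' @param mask Congruent [voxel_mask()].
#' @param lo,hi Histogram range in HU.
#' @param n_bins Number of equal-width bins.
#' @param ranges An [aeration_ranges()] for bin annotation.
#' @return Data frame with columns `bin_lo`, `bin_hi`, `mid`, `count`,
#'   `compartment`, plus attributes `n_in_range` and `n_masked`.
#' @export
hu_histogram <- function(volume, mask, lo = -860, hi = 121, n_bins = 163L,
                         ranges = aeration_ranges()) {
  stopifnot(inherits(volume, "scan_volume"), inherits(mask, "voxel_mask"))
  if (!(lo < hi) || n_bins < 1L) stop("need lo < hi and n_bins >= 1", call. = FALSE)
  check_congruent(volume, mask)
  hu <- volume$values[mask$values]
  if (length(hu) == 0L) stop("empty lung mask", call. = FALSE)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  inside <- hu >= lo & hu <= hi
  ## values exactly at hi go in the last bin (rightmost closed)
  bin <- findInterval(hu[inside], breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  out <- data.frame(bin_lo = breaks[-(n_bins + 1L)], bin_hi = breaks[-1],
                    mid = mids, count = counts,
                    compartment = classify_voxel(mids, ranges))
  attr(out, "n_in_range") <- sum(inside)
  attr(out, "n_masked") <- length(hu)
  out
}

#' Compartment label map for overlay rendering
#'
#' Produces an integer label volume congruent with the input: 0 outside the
#' mask, then 1 = Normo, 2 = Hypo, 3 = Non, 4 = Unclassified (the
#' conventional blue/green/red colour coding plus a catch-all), consistent
#' voxel-for-voxel with [classify_voxel()].
#'
#' @param volume Calibrated [scan_volume()].
#' @param mask Congruent [voxel_mask()].
#' @param ranges An [aeration_ranges()].
#' @return Integer array with a `labels` attribute naming the codes.
#' @export
render_compartment_overlay <- function(volume, mask, ranges = aeration_ranges()) {
  stopifnot(inherits(volume, "scan_volume"), inherits(mask, "voxel_mask"))
  if (!volume$calibrated)
    stop("volume must be calibrated to HU", call. = FALSE)
  check_congruent(volume, mask)
  lab <- array(0L, dim = dim(volume$values))
  idx <- which(mask$values)
  lab[idx] <- as.integer(classify_voxel(volume$values[idx], ranges))
  attr(lab, "labels") <- c("1" = "Normo", "2" = "Hypo", "3" = "Non",
                           "4" = "Unclassified")
  lab
}

#' One-row densitometry report for an animal and time-point
#'
#' Assembles both phases plus the biomarkers into the flat column layout used
#' by the reporting CSVs. Compartment percentages come from the phase given
#' by `pct_phase` (default end-expiration, the phase fibrosis compartments
#' are conventionally reported at).
#'
#' @param result_a,result_b The two per-phase `densitometry_result`s.
#' @param animal,day Identifiers copied into the row.
#' @param pct_phase `"P02"` (default) or `"P01"`.
#' @return One-row data frame with columns `animal`, `day`, `N_P01`, `V_P01`,
#'   `MLA_P01`, `Gas_P01`, `N_P02`, `V_P02`, `MLA_P02`, `Gas_P02`,
#'   `pct_normo`, `pct_hypo`, `pct_non`, `pct_unclassified`, `tissue`,
#'   `pct_gas_P01`, `pct_gas_P02`.
#' @export
densitometry_row <- function(result_a, result_b, animal = NA, day = NA,
                             pct_phase = c("P02", "P01")) {
  pct_phase <- match.arg(pct_phase)
  phases <- c(result_a$phase, result_b$phase)
  r <- list(result_a, result_b)
  p01 <- r[[match("P01", phases)]]
  p02 <- r[[match("P02", phases)]]
  bm <- compute_biomarkers(result_a, result_b)
  pr <- if (pct_phase == "P02") p02 else p01
  data.frame(animal = animal, day = day,
             N_P01 = p01$N, V_P01 = p01$V, MLA_P01 = p01$MLA, Gas_P01 = p01$Gas,
             N_P02 = p02$N, V_P02 = p02$V, MLA_P02 = p02$MLA, Gas_P02 = p02$Gas,
             pct_normo = pr$pct_normo, pct_hypo = pr$pct_hypo,
             pct_non = pr$pct_non, pct_unclassified = pr$pct_unclassified,
             tissue = bm$tissue, pct_gas_P01 = bm$pct_gas_P01,
             pct_gas_P02 = bm$pct_gas_P02)
}
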