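## Synthetic paired-phase lung phantom with exact ground truth.
##
## The phantom is deliberately simple geometry: two lung ellipsoids inside a
## soft-tissue cylinder surrounded by background air. Parenchymal HU are
## Gaussian per respiratory phase (end-inspiration is more aerated, hence a
## more negative mean); fibrotic lesions are a patchy subset of the lung
## obtained by thresholding a Gaussian-smoothed white-noise field, which
## reproduces blob-like consolidation with a single tunable length scale.
## Because every voxel's generating distribution is known, compartment
## fractions downstream have closed-form expectations.

#' Parameters of the synthetic lung phantom
#'
#' @param grid_shape Integer length-3 voxel grid, internal (z, y, x) order.
#' @param voxel_spacing Numeric length-3 spacing in mm.
#' @param lung_fraction Fraction of the grid volume occupied by the two lung
#'   ellipsoids combined.
#' @param mu_normo_P01,mu_normo_P02 Mean parenchymal HU at end-inspiration /
#'   end-expiration. Inspiration must be at least as aerated (as negative).
#' @param sigma_parenchyma Parenchymal HU noise SD.
#' @param lesion_fraction Target fraction of lung voxels converted to lesion.
#' @param mu_lesion,sigma_lesion Lesion HU mean / SD.
#' @param lesion_blob_scale Gaussian smoothing length (voxels) of the lesion
#'   texture field; larger values give coarser patches.
#' @param body_hu,background_hu HU of the soft-tissue shell and the air
#'   background.
#' @param quantize Round HU to integers (off by default so analytic
#'   identities stay exact).
#' @param seed Integer RNG seed; a fixed seed gives bit-identical phantoms.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(96L, 96L, 96L),
                           voxel_spacing = c(0.1, 0.1, 0.1),
                           lung_fraction = 0.15,
                           mu_normo_P01 = -750,
                           mu_normo_P02 = -650,
                           sigma_parenchyma = 30,
                           lesion_fraction = 0.2,
                           mu_lesion = -250,
                           sigma_lesion = 40,
                           lesion_blob_scale = 3,
                           body_hu = 40,
                           background_hu = -1000,
                           quantize = FALSE,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(is.na(grid_shape)) || any(grid_shape < 8L))
    stop("`grid_shape` must be three integers >= 8", call. = FALSE)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0))
    stop("`voxel_spacing` must be three strictly positive values", call. = FALSE)
  if (!is.finite(lung_fraction) || lung_fraction <= 0 || lung_fraction > 0.35)
    stop("`lung_fraction` must be in (0, 0.35] so the lungs fit in the body",
         call. = FALSE)
  if (mu_normo_P01 > mu_normo_P02)
    stop("`mu_normo_P01` must be <= `mu_normo_P02`: inspiration is more aerated",
         call. = FALSE)
  if (!is.finite(lesion_fraction) || lesion_fraction < 0 || lesion_fraction > 1)
    stop("`lesion_fraction` must lie in [0, 1]", call. = FALSE)
  if (sigma_parenchyma <= 0 || sigma_lesion <= 0 || lesion_blob_scale <= 0)
    stop("scale parameters must be strictly positive", call. = FALSE)
  structure(list(
    grid_shape = grid_shape, voxel_spacing = voxel_spacing,
    lung_fraction = lung_fraction,
    mu_normo_P01 = mu_normo_P01, mu_normo_P02 = mu_normo_P02,
    sigma_parenchyma = sigma_parenchyma,
    lesion_fraction = lesion_fraction,
    mu_lesion = mu_lesion, sigma_lesion = sigma_lesion,
    lesion_blob_scale = lesion_blob_scale,
    body_hu = body_hu, background_hu = background_hu,
    quantize = isTRUE(quantize), seed = as.integer(seed)),
    class = "phantom_params")
}

## Run `expr` under a fixed seed, restoring the caller's RNG state.
with_phantom_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

## Periodic Gaussian smoothing of a 3-D field via FFT. Wrap-around is
## harmless here: the field is only consumed inside the lung, far from the
## grid faces.
gaussian_smooth3d <- function(field, sigma_vox) {
  d <- dim(field)
  kern1 <- function(n, s) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-0.5 * (x / s)^2)
    k / sum(k)
  }
  kz <- kern1(d[1], sigma_vox)
  ky <- kern1(d[2], sigma_vox)
  kx <- kern1(d[3], sigma_vox)
  kernel <- outer(outer(kz, ky), kx)
  dim(kernel) <- d
  Re(fft(fft(field) * fft(kernel), inverse = TRUE)) / prod(d)
}

## Lung geometry: two ellipsoids (left/right) inside a soft-tissue cylinder.
## Returns logical arrays for body and lung plus a failure-proof check that
## the requested lung_fraction fits.
phantom_geometry <- function(params) {
  d <- params$grid_shape
  cz <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
  body_r <- 0.47 * min(d[2], d[3])

  ## semi-axis shape ratios (z elongated like a lung field); solve the scale
  ## so the two ellipsoids jointly cover lung_fraction of the grid
  rz <- 1.4; ry <- 1.1; rx <- 0.75
  s <- (params$lung_fraction * prod(d) / (2 * 4 / 3 * pi * rz * ry * rx))^(1 / 3)
  az <- rz * s; ay <- ry * s; ax <- rx * s
  gap <- max(4, 0.05 * d[3])             # carina gap, > 2x default closing radius
  off <- ax + gap / 2
  if (az > 0.48 * d[1] || ay > body_r - 1 || off + ax > body_r - 1)
    stop("lung ellipsoids do not fit the grid; reduce `lung_fraction` or enlarge the grid",
         call. = FALSE)

  z <- seq_len(d[1]); y <- seq_len(d[2]); x <- seq_len(d[3])
  zz2 <- ((z - cz) / az)^2
  yy2 <- ((y - cy) / ay)^2
  ell <- function(cx_i) {
    xx2 <- ((x - cx_i) / ax)^2
    q <- outer(outer(zz2, yy2, `+`), xx2, `+`)
    q <= 1
  }
  lung <- ell(cx - off) | ell(cx + off)

  yyb <- (y - cy)^2
  xxb <- (x - cx)^2
  body2d <- outer(yyb, xxb, `+`) <= body_r^2
  body <- aperm(array(body2d, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  list(body = body, lung = lung)
}

#' Generate a paired-phase synthetic scan with ground truth
#'
#' Produces end-inspiration (P01) and end-expiration (P02) calibrated HU
#' volumes sharing identical lung and lesion geometry, plus the exact truth
#' needed for recovery tests: the lung and lesion masks, the realised lesion
#' fraction, and the analytic compartment fractions expected under the
#' generating Gaussians.
#'
#' @param params A [phantom_params()].
#' @return A list with elements `p01`, `p02` ([scan_volume()]s) and `truth`
#'   (class `phantom_truth`: `lung_mask`, `lesion_mask`,
#'   `realized_lesion_fraction`, `expected_compartment_fractions` — a matrix
#'   with rows `P01`/`P02` and columns
#'   `pct_normo`/`pct_hypo`/`pct_non`/`pct_unclassified`).
#' @export
generate_scan_pair <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  geom <- phantom_geometry(params)
  d <- params$grid_shape

  with_phantom_seed(params$seed, {
    lung_idx <- which(geom$lung)
    n_lung <- length(lung_idx)

    ## patchy lesion: smoothed white noise thresholded at the quantile that
    ## yields lesion_fraction of the lung
    lesion <- array(FALSE, dim = d)
    if (params$lesion_fraction > 0) {
      noise <- array(rnorm(prod(d)), dim = d)
      tex <- gaussian_smooth3d(noise, params$lesion_blob_scale)
      tex_lung <- tex[lung_idx]
      k <- round(params$lesion_fraction * n_lung)
      if (k >= n_lung) {
        lesion[lung_idx] <- TRUE
      } else if (k > 0) {
        thr <- sort(tex_lung, decreasing = TRUE)[k]
        lesion[lung_idx] <- tex_lung >= thr
      }
    }
    realized <- sum(lesion) / n_lung

    fill_phase <- function(mu_normo, phase) {
      vals <- array(params$background_hu, dim = d)
      vals[geom$body] <- params$body_hu
      normo_idx <- lung_idx[!lesion[lung_idx]]
      les_idx <- lung_idx[lesion[lung_idx]]
      vals[normo_idx] <- rnorm(length(normo_idx), mu_normo, params$sigma_parenchyma)
      vals[les_idx] <- rnorm(length(les_idx), params$mu_lesion, params$sigma_lesion)
      if (params$quantize) vals <- round(vals)
      scan_volume(vals, params$voxel_spacing, phase = phase, calibrated = TRUE)
    }
    p01 <- fill_phase(params$mu_normo_P01, "P01")
    p02 <- fill_phase(params$mu_normo_P02, "P02")

    truth <- structure(list(
      lung_mask = voxel_mask(geom$lung, params$voxel_spacing, label = "lung"),
      lesion_mask = voxel_mask(lesion, params$voxel_spacing, label = "lesion"),
      realized_lesion_fraction = realized,
      expected_compartment_fractions =
        expected_compartment_fractions(params, lesion_fraction = realized)),
      class = "phantom_truth")

    list(p01 = p01, p02 = p02, truth = truth)
  })
}

#' Analytic compartment fractions expected from the phantom's Gaussians
#'
#' The lung HU distribution is the two-component mixture
#' `(1 - f) * N(mu_normo_p, sigma_parenchyma) + f * N(mu_lesion, sigma_lesion)`;
#' expected compartment percentages are the mixture masses on the aeration
#' intervals, computed from the normal CDF.
#'
#' @param params A [phantom_params()].
#' @param lesion_fraction Mixture weight to use (defaults to the requested
#'   `params$lesion_fraction`; pass the realised fraction for exact truth).
#' @param ranges An [aeration_ranges()].
#' @return Matrix with rows `P01`, `P02` and columns `pct_normo`, `pct_hypo`,
#'   `pct_non`, `pct_unclassified` (percent).
#' @export
expected_compartment_fractions <- function(params,
                                           lesion_fraction = params$lesion_fraction,
                                           ranges = aeration_ranges()) {
  f <- lesion_fraction
  mass <- function(mu, s, lo, hi) pnorm(hi, mu, s) - pnorm(lo, mu, s)
  one_phase <- function(mu_normo) {
    mix <- function(lo, hi)
      (1 - f) * mass(mu_normo, params$sigma_parenchyma, lo, hi) +
        f * mass(params$mu_lesion, params$sigma_lesion, lo, hi)
    p_normo <- mix(ranges$normo[1], ranges$normo[2])
    p_hypo <- mix(ranges$hypo[1], ranges$hypo[2])
    p_non <- mix(ranges$non[1], ranges$non[2])
    c(pct_normo = 100 * p_normo, pct_hypo = 100 * p_hypo,
      pct_non = 100 * p_non,
      pct_unclassified = 100 * (1 - p_normo - p_hypo - p_non))
  }
  rbind(P01 = one_phase(params$mu_normo_P01),
        P02 = one_phase(params$mu_normo_P02))
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> lung %d voxels, lesion fraction %.3f\n",
              sum(x$lung_mask$values), x$realized_lesion_fraction))
  invisible(x)
}

## --- Histology fixtures -------------------------------------------------------

#' Generate synthetic histology fixtures with known ground truth
#'
#' Emits (i) per-field Ashcroft scores drawn from a requested
#' mild/moderate/severe class mix, (ii) a paired tissue / stain-positive mask
#' whose positive fraction is controlled, and (iii) skin-section junction
#' polylines (epidermal-dermal, dermal-subcutaneous, muscle) with known layer
#' thicknesses, optionally wavy for oracle testing.
#'
#' @param n_fields Number of microscopic fields to score.
#' @param severity_mix Length-3 fractions (mild, moderate, severe) summing
#'   to 1. Mild fields get scores in 0..3, moderate exactly 4, severe 5..8.
#' @param seed Integer RNG seed.
#' @param stain_target_fraction Target stain-positive fraction of the tissue.
#' @param stain_size Side (pixels) of the square stain image.
#' @param dermal_um,hypodermal_um True layer thicknesses in micrometres.
#' @param pixel_size_um Micrometres per pixel of the section coordinates.
#' @param wave_amplitude_um Amplitude of a sinusoidal perturbation applied to
#'   all junctions (0 keeps them parallel and the thickness exact).
#' @return A list with elements `ashcroft` (data frame: `field_idx`,
#'   `severity_class`, `score`), `stain` (tissue/positive masks and the
#'   realised fraction) and `skin` (a [skin_section()] plus the true
#'   thicknesses).
#' @export
generate_histology_fixtures <- function(n_fields,
                                        severity_mix,
                                        seed = 1L,
                                        stain_target_fraction = 0.23,
                                        stain_size = 128L,
                                        dermal_um = 250,
                                        hypodermal_um = 400,
                                        pixel_size_um = 2,
                                        wave_amplitude_um = 0) {
  n_fields <- as.integer(n_fields)
  if (is.na(n_fields) || n_fields < 1L)
    stop("`n_fields` must be a positive integer", call. = FALSE)
  severity_mix <- as.numeric(severity_mix)
  if (length(severity_mix) != 3L || any(severity_mix < 0) ||
      abs(sum(severity_mix) - 1) > 1e-8)
    stop("`severity_mix` must be three non-negative fractions summing to 1",
         call. = FALSE)
  if (stain_target_fraction < 0 || stain_target_fraction > 1)
    stop("`stain_target_fraction` must lie in [0, 1]", call. = FALSE)

  with_phantom_seed(seed, {
    cls <- sample(c("mild", "moderate", "severe"), n_fields,
                  replace = TRUE, prob = severity_mix)
    score <- integer(n_fields)
    score[cls == "mild"] <- sample(0:3, sum(cls == "mild"), replace = TRUE)
    score[cls == "moderate"] <- 4L
    score[cls == "severe"] <- sample(5:8, sum(cls == "severe"), replace = TRUE)
    ashcroft <- data.frame(field_idx = seq_len(n_fields),
                           severity_class = cls, score = score,
                           stringsAsFactors = FALSE)

    ## stain fixture: elliptical tissue, positive = top-k of smoothed noise
    n <- stain_size
    yy <- matrix(rep(seq_len(n), n), n)
    xx <- t(yy)
    c0 <- (n + 1) / 2
    tissue <- ((yy - c0) / (0.45 * n))^2 + ((xx - c0) / (0.45 * n))^2 <= 1
    noise <- matrix(rnorm(n * n), n)
    sm <- Re(fft(fft(noise) * fft(smooth_kernel2d(n, 3)), inverse = TRUE)) / (n * n)
    positive <- matrix(FALSE, n, n)
    tidx <- which(tissue)
    k <- round(stain_target_fraction * length(tidx))
    if (k > 0) {
      v <- sm[tidx]
      thr <- sort(v, decreasing = TRUE)[k]
      positive[tidx] <- v >= thr
    }
    stain <- list(tissue_mask = tissue, positive_mask = positive,
                  target_fraction = stain_target_fraction,
                  realized_fraction = sum(positive) / length(tidx))

    ## skin fixture: three junctions stacked along y, ordered along x
    x_um <- seq(0, 2000, by = 10)
    wave <- if (wave_amplitude_um > 0)
      wave_amplitude_um * sin(2 * pi * x_um / 500) else 0
    epi <- cbind(x = x_um, y = 0 + wave)
    derm <- cbind(x = x_um, y = dermal_um + wave)
    musc <- cbind(x = x_um, y = dermal_um + hypodermal_um + wave)
    section <- skin_section(epidermal_dermal = epi / pixel_size_um,
                            dermal_subcutaneous = derm / pixel_size_um,
                            muscle = musc / pixel_size_um,
                            pixel_size = pixel_size_um)
    skin <- list(section = section,
                 true_dermal_um = dermal_um,
                 true_hypodermal_um = hypodermal_um)

    list(ashcroft = ashcroft, stain = stain, skin = skin)
  })
}

smooth_kernel2d <- function(n, sigma) {
  x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-0.5 * (x / sigma)^2)
  k <- k / sum(k)
  outer(k, k)
}
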