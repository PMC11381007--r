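## Histology quantifications: Ashcroft score aggregation and severity
## frequency distribution, stain-positive area fractions, skin layer
## thicknesses and fold-increase normalisation.

#' Aggregate per-field Ashcroft scores for one animal
#'
#' @param animal_id Identifier.
#' @param field_scores Integer scores, each in 0..8.
#' @return An `ashcroft_record` with the arithmetic `mean_score`.
#' @export
ashcroft_record <- function(animal_id, field_scores) {
  field_scores <- as.integer(field_scores)
  if (length(field_scores) < 1L)
    stop("at least one field score is required", call. = FALSE)
  if (any(is.na(field_scores)) || any(field_scores < 0L | field_scores > 8L))
    stop("Ashcroft scores must be integers in 0..8", call. = FALSE)
  structure(list(animal_id = animal_id, field_scores = field_scores,
                 mean_score = mean(field_scores)),
            class = "ashcroft_record")
}

#' Classify Ashcroft scores into severity classes
#'
#' Mild covers scores 0–3, moderate is exactly 4, severe covers 5–8; the
#' classification is total on the score range.
#'
#' @param scores Integer scores in 0..8.
#' @return Factor with levels `mild`, `moderate`, `severe`.
#' @export
classify_severity <- function(scores) {
  scores <- as.integer(scores)
  if (any(is.na(scores)) || any(scores < 0L | scores > 8L))
    stop("Ashcroft scores must be integers in 0..8", call. = FALSE)
  cls <- ifelse(scores <= 3L, "mild", ifelse(scores == 4L, "moderate", "severe"))
  factor(cls, levels = c("mild", "moderate", "severe"))
}

#' Severity frequency distribution over microscopic fields
#'
#' Classifies every field score as mild (0–3), moderate (4) or severe (5–8)
#' and reports the class percentages over all fields. By default the
#' classification is per field; `per_animal_mean = TRUE` instead classifies
#' each animal's rounded mean score, for the reading of severity grouping
#' that operates on animal means.
#'
#' @param records A single [ashcroft_record()], a list of them, or a bare
#'   vector of field scores.
#' @param per_animal_mean Classify per-animal mean scores instead of
#'   individual fields.
#' @return A `severity_distribution`: `pct_mild`, `pct_moderate`,
#'   `pct_severe` (summing to 100) plus the unit count `n`.
#' @export
#' @examples
#' severity_distribution(c(1, 2, 3, 4, 5)) # 60 / 20 / 20
severity_distribution <- function(records, per_animal_mean = FALSE) {
  if (inherits(records, "ashcroft_record")) records <- list(records)
  if (is.numeric(records)) records <- list(ashcroft_record("pooled", records))
  if (!length(records)) stop("no records supplied", call. = FALSE)
  units <- if (per_animal_mean) {
    vapply(records, function(r) as.integer(round(r$mean_score)), integer(1))
  } else {
    unlist(lapply(records, function(r) r$field_scores))
  }
  cls <- classify_severity(units)
  n <- length(cls)
  counts <- tabulate(cls, nbins = 3L)
  structure(list(pct_mild = 100 * counts[1] / n,
                 pct_moderate = 100 * counts[2] / n,
                 pct_severe = 100 * counts[3] / n,
                 n = n),
            class = "severity_distribution")
}

#' @export
print.severity_distribution <- function(x, ...) {
  cat(sprintf("<severity_distribution> mild %.1f%%  moderate %.1f%%  severe %.1f%%  (n=%d)\n",
              x$pct_mild, x$pct_moderate, x$pct_severe, x$n))
  invisible(x)
}

#' Stain-positive area fraction of a tissue section
#'
#' Percentage of the tissue area occupied by the stain-positive mask
#' (collagen on Picrosirius-red sections, matrix proteins on
#' immunofluorescence). Positive pixels falling outside the tissue mask are
#' counted only where inside tissue, with a warning.
#'
#' @param positive_mask,tissue_mask Congruent logical matrices (or 0/1).
#' @param pixel_area Physical area of one pixel (any unit), used for the
#'   reported absolute areas.
#' @return A `stain_quant`: `positive_area`, `tissue_area`, `pct_occupied`.
#' @export
stain_fraction <- function(positive_mask, tissue_mask, pixel_area = 1) {
  positive_mask <- positive_mask != 0
  tissue_mask <- tissue_mask != 0
  if (!identical(dim(positive_mask), dim(tissue_mask)))
    stop("masks are not congruent", call. = FALSE)
  n_tissue <- sum(tissue_mask)
  if (n_tissue == 0L) stop("empty tissue mask", call. = FALSE)
  outside <- sum(positive_mask & !tissue_mask)
  if (outside > 0L)
    warning(sprintf("%d positive pixels outside the tissue mask were ignored",
                    outside), call. = FALSE)
  n_pos <- sum(positive_mask & tissue_mask)
  structure(list(positive_area = n_pos * pixel_area,
                 tissue_area = n_tissue * pixel_area,
                 pct_occupied = 100 * n_pos / n_tissue),
            class = "stain_quant")
}

#' Read a binary section mask from TIFF
#'
#' Any nonzero pixel is foreground; multi-channel images are collapsed by
#' maximum.
#'
#' @param path TIFF file path.
#' @return Logical matrix.
#' @export
read_section_mask <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), max)
  img != 0
}

## --- Skin layer thickness -----------------------------------------------------

#' Skin section junction polylines
#'
#' Coordinates are in pixels; `pixel_size` converts to micrometres. Each
#' polyline is a two-column (x, y) matrix ordered along the section axis.
#'
#' @param epidermal_dermal,dermal_subcutaneous,muscle Two-column matrices;
#'   any of them may be `NULL` when the corresponding layer is not measured.
#' @param pixel_size Micrometres per pixel.
#' @return A `skin_section`.
#' @export
skin_section <- function(epidermal_dermal = NULL, dermal_subcutaneous = NULL,
                         muscle = NULL, pixel_size = 1) {
  check_poly <- function(p, nm) {
    if (is.null(p)) return(NULL)
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 2L)
      stop(sprintf("`%s` must be a two-column matrix with >= 2 vertices", nm),
           call. = FALSE)
    if (is.unsorted(p[, 1], strictly = FALSE))
      stop(sprintf("`%s` must be ordered along the section axis", nm),
           call. = FALSE)
    unname(p)
  }
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  structure(list(
    epidermal_dermal = check_poly(epidermal_dermal, "epidermal_dermal"),
    dermal_subcutaneous = check_poly(dermal_subcutaneous, "dermal_subcutaneous"),
    muscle = check_poly(muscle, "muscle"),
    pixel_size = pixel_size),
    class = "skin_section")
}

## Minimum distance from each point (rows of pts) to a polyline.
point_polyline_distance <- function(pts, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1e-300
  apply(pts, 1, function(p) {
    t <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- a[, 1] + t * ab[, 1] - p[1]
    dy <- a[, 2] + t * ab[, 2] - p[2]
    sqrt(min(dx * dx + dy * dy))
  })
}

## Do any two segments of the two polylines intersect? (boundary crossing)
polylines_cross <- function(p, q) {
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(nrow(p) - 1L)) {
    a <- p[i, ]; b <- p[i + 1L, ]
    ## prune by x-interval overlap
    j_lo <- min(max(1L, findInterval(min(a[1], b[1]), q[, 1]) - 1L),
                nrow(q) - 1L)
    for (j in seq(j_lo, nrow(q) - 1L)) {
      c_ <- q[j, ]; d_ <- q[j + 1L, ]
      if (max(c_[1], d_[1]) < min(a[1], b[1])) next
      if (min(c_[1], d_[1]) > max(a[1], b[1])) break
      o1 <- orient(a[1], a[2], b[1], b[2], c_[1], c_[2])
      o2 <- orient(a[1], a[2], b[1], b[2], d_[1], d_[2])
      o3 <- orient(c_[1], c_[2], d_[1], d_[2], a[1], a[2])
      o4 <- orient(c_[1], c_[2], d_[1], d_[2], b[1], b[2])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0) return(TRUE)
    }
  }
  FALSE
}

#' Mean layer thickness from bounding junction polylines
#'
#' Thickness of the dermal layer (epidermal-dermal to dermal-subcutaneous
#' junction) or the hypodermal layer (dermal-subcutaneous junction to muscle
#' layer), measured as the mean over sampled points of the upper boundary of
#' the minimum distance to the lower boundary, in micrometres. Crossing
#' boundaries are a validation error. Identical boundaries give 0.
#'
#' @param section A [skin_section()].
#' @param layer `"dermal"` or `"hypodermal"`.
#' @param n_samples Number of equally spaced sample points along the upper
#'   boundary.
#' @return Mean thickness in micrometres.
#' @export
layer_thickness <- function(section, layer = c("dermal", "hypodermal"),
                            n_samples = 200L) {
  stopifnot(inherits(section, "skin_section"))
  layer <- match.arg(layer)
  upper <- switch(layer, dermal = section$epidermal_dermal,
                  hypodermal = section$dermal_subcutaneous)
  lower <- switch(layer, dermal = section$dermal_subcutaneous,
                  hypodermal = section$muscle)
  if (is.null(upper) || is.null(lower))
    stop(sprintf("both bounding polylines are required for the %s layer", layer),
         call. = FALSE)
  if (!identical(dim(upper), dim(lower)) || !isTRUE(all.equal(upper, lower))) {
    if (polylines_cross(upper, lower))
      stop("bounding polylines cross: negative thickness is not meaningful",
           call. = FALSE)
  }
  pts <- resample_polyline(upper, n_samples)
  mean(point_polyline_distance(pts, lower)) * section$pixel_size
}

## Equally spaced (by arc length) points along a polyline.
resample_polyline <- function(poly, n) {
  seg <- sqrt(rowSums((poly[-1, , drop = FALSE] - poly[-nrow(poly), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(poly[rep(1, n), , drop = FALSE])
  s <- seq(0, total, length.out = n)
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(poly) - 1L)
  t <- (s - cum[i]) / seg[i]
  poly[i, , drop = FALSE] + t * (poly[i + 1L, , drop = FALSE] - poly[i, , drop = FALSE])
}

#' Fold increase over the control group mean
#'
#' Each treated measurement divided by the mean of the control group; the
#' normalisation used for immunofluorescence signal quantification relative
#' to saline.
#'
#' @param values Treated measurements.
#' @param control_values Control-group measurements.
#' @return Numeric vector of fold changes, one per treated value.
#' @export
#' @examples
#' fold_increase(c(2, 6), c(1, 3)) # control mean 2 -> folds 1, 3
fold_increase <- function(values, control_values) {
  if (!length(control_values)) stop("no control values", call. = FALSE)
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0)
    stop("control mean must be strictly positive", call. = FALSE)
  values / m
}
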