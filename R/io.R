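## Volume / mask containers and file I/O.
##
## Internal axis convention: arrays are kept in their storage order and
## spacing[i] is the physical step (mm) along dim(values)[i]. The phantom
## generator emits (z, y, x); nothing downstream depends on axis identity,
## only on the spacing/dim pairing, so no transposition ever happens.

#' Scan volume container
#'
#' Bundles a 3-D scalar grid (grey levels or Hounsfield units) with its voxel
#' spacing, the respiratory phase it was reconstructed at, and a flag saying
#' whether the values are calibrated HU.
#'
#' @param values Numeric 3-D array.
#' @param spacing Numeric length-3 vector, mm per voxel along each array axis.
#' @param phase `"P01"` (end-inspiration), `"P02"` (end-expiration) or `NA`.
#' @param calibrated Logical; `TRUE` when `values` are Hounsfield units.
#' @return An object of class `scan_volume`.
#' @export
scan_volume <- function(values, spacing, phase = NA_character_,
                        calibrated = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (any(dim(values) < 1L)) stop("volume grid is empty", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  if (!is.na(phase) && !phase %in% c("P01", "P02"))
    stop("`phase` must be \"P01\", \"P02\" or NA", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, phase = phase,
         calibrated = isTRUE(calibrated)),
    class = "scan_volume")
}

#' Binary voxel mask congruent with a scan volume
#'
#' @param values Logical (or 0/1 coercible) 3-D array; any nonzero value is
#'   treated as foreground.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param label Free-text label, e.g. `"lung"` or `"lesion"`.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(values, spacing, label = "mask") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  v <- array(as.logical(values != 0), dim = dim(values))
  structure(list(values = v, spacing = spacing, label = as.character(label)),
            class = "voxel_mask")
}

#' @export
print.scan_volume <- function(x, ...) {
  cat(sprintf("<scan_volume> %s, spacing %s mm, phase %s, %s\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              ifelse(is.na(x$phase), "unset", x$phase),
              if (x$calibrated) "HU" else "grey levels"))
  invisible(x)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> '%s' %s, %d foreground voxels\n", x$label,
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' Physical voxel volume of a volume or mask
#'
#' @param x A `scan_volume` or `voxel_mask`.
#' @return Volume of one voxel in mm^3 (the product of the header spacings).
#' @export
voxel_volume <- function(x) prod(x$spacing)

## Congruence check shared by every stage that pairs a mask with a volume.
check_congruent <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$values)))
    stop(sprintf("mask grid %s does not match volume grid %s",
                 paste(dim(mask$values), collapse = "x"),
                 paste(dim(volume$values), collapse = "x")), call. = FALSE)
  if (max(abs(volume$spacing - mask$spacing)) > 1e-6)
    stop("mask spacing does not match volume spacing", call. = FALSE)
  invisible(TRUE)
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_metaimage_path <- function(path) grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)

encode_descrip <- function(phase, calibrated) {
  sprintf("fibrocast;phase=%s;calibrated=%d",
          ifelse(is.na(phase), "NA", phase), as.integer(calibrated))
}

decode_descrip <- function(descrip) {
  out <- list(phase = NA_character_, calibrated = NA)
  if (is.null(descrip) || !nzchar(descrip) || !startsWith(descrip, "fibrocast"))
    return(out)
  ph <- sub(".*phase=([^;]+).*", "\\1", descrip)
  cal <- sub(".*calibrated=([01]).*", "\\1", descrip)
  if (ph %in% c("P01", "P02")) out$phase <- ph
  if (cal %in% c("0", "1")) out$calibrated <- cal == "1"
  out
}

#' Read a volume from NIfTI or MetaImage
#'
#' Voxel spacing is taken from the file header and is mandatory: volumetric
#' quantification is meaningless without it, so a header reporting
#' non-positive spacing is a hard error. Phase and calibration state are
#' recovered from metadata written by [write_volume()] when present;
#' arguments override metadata.
#'
#' @param path File path (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @param phase Optional phase override (`"P01"`/`"P02"`).
#' @param calibrated Optional logical override of the calibration flag.
#' @return A [scan_volume()].
#' @export
read_volume <- function(path, phase = NULL, calibrated = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[seq_len(3)]
    meta <- decode_descrip(RNifti::niftiHeader(img)$descrip)
    values <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
  } else if (is_metaimage_path(path)) {
    mi <- read_metaimage(path)
    spacing <- mi$spacing
    meta <- decode_descrip(mi$descrip)
    values <- mi$values
  } else {
    stop("unsupported container (expected .nii/.nii.gz/.mha/.mhd)", call. = FALSE)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume header carries no usable voxel spacing", call. = FALSE)
  ph <- if (!is.null(phase)) phase else meta$phase
  cal <- if (!is.null(calibrated)) isTRUE(calibrated) else isTRUE(meta$calibrated)
  scan_volume(values, spacing, phase = ph, calibrated = cal)
}

#' Write a volume to NIfTI or MetaImage
#'
#' Spacing goes into the container header; phase and calibration state are
#' stored in the NIfTI description field (or a MetaImage comment) so that a
#' round trip through [read_volume()] restores the full object.
#'
#' @param volume A [scan_volume()].
#' @param path Output path; the extension selects the container.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scan_volume"))
  if (is_nifti_path(path)) {
    a <- volume$values
    attr(a, "pixdim") <- volume$spacing
    img <- RNifti::asNifti(a)
    img$descrip <- encode_descrip(volume$phase, volume$calibrated)
    RNifti::writeNifti(img, path)
  } else if (is_metaimage_path(path)) {
    write_metaimage(volume$values, volume$spacing, path,
                    element_type = "MET_DOUBLE",
                    descrip = encode_descrip(volume$phase, volume$calibrated))
  } else {
    stop("unsupported container (expected .nii/.nii.gz/.mha/.mhd)", call. = FALSE)
  }
  invisible(path)
}

#' Read a binary mask, checking congruence against a reference volume
#'
#' Any nonzero stored value (some tools write 255) is foreground.
#'
#' @param path Mask file (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @param reference Optional `scan_volume` the mask must be congruent with.
#' @param label Label for the returned mask.
#' @return A [voxel_mask()].
#' @export
read_mask <- function(path, reference = NULL, label = "mask") {
  vol <- read_volume(path)
  m <- voxel_mask(vol$values, vol$spacing, label = label)
  if (!is.null(reference)) check_congruent(reference, m)
  m
}

#' Write a binary mask as unsigned 8-bit
#'
#' @param mask A [voxel_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (is_nifti_path(path)) {
    a <- array(as.integer(mask$values), dim = dim(mask$values))
    attr(a, "pixdim") <- mask$spacing
    img <- RNifti::asNifti(a, datatype = "uint8")
    RNifti::writeNifti(img, path)
  } else if (is_metaimage_path(path)) {
    write_metaimage(array(as.integer(mask$values), dim = dim(mask$values)),
                    mask$spacing, path, element_type = "MET_UCHAR")
  } else {
    stop("unsupported container (expected .nii/.nii.gz/.mha/.mhd)", call. = FALSE)
  }
  invisible(path)
}

## --- MetaImage (.mha single-file / .mhd + raw) -------------------------------
## Minimal reader/writer for the uncompressed research-format subset: no
## installed R package speaks this container, so the key=value header plus a
## raw little-endian payload is parsed here directly.

metaimage_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header", call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3-D MetaImage volumes are supported", call. = FALSE)
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else rep(NA_real_, 3)
  type <- metaimage_types[[hdr$ElementType]]
  if (is.null(type)) stop(sprintf("unsupported ElementType %s", hdr$ElementType), call. = FALSE)
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True") ||
    identical(hdr$ElementByteOrderMSB, "True")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- readBin(raw_con, what = type$what, n = n, size = type$size,
                  signed = type$signed, endian = if (msb) "big" else "little")
  if (length(vals) != n) stop("MetaImage payload shorter than DimSize", call. = FALSE)
  list(values = array(as.numeric(vals), dim = dims), spacing = spacing,
       descrip = hdr$Comment)
}

write_metaimage <- function(values, spacing, path,
                            element_type = "MET_DOUBLE", descrip = NULL) {
  type <- metaimage_types[[element_type]]
  if (is.null(type)) stop("unsupported ElementType", call. = FALSE)
  dims <- dim(values)
  mhd <- grepl("\\.mhd$", path, ignore.case = TRUE)
  raw_name <- if (mhd) sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    if (!is.null(descrip)) sprintf("Comment = %s", descrip),
    sprintf("DimSize = %s", paste(dims, collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(spacing, digits = 17), collapse = " ")),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", if (mhd) raw_name else "LOCAL"))
  payload <- if (type$what == "integer") as.integer(values) else as.numeric(values)
  if (mhd) {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(payload, con, size = type$size, endian = "little")
  } else {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(hdr, con)
    writeBin(payload, con, size = type$size, endian = "little")
  }
  invisible(path)
}

## --- Tabular I/O --------------------------------------------------------------

#' Write a records table as CSV with full float precision
#'
#' Column order is preserved; numeric columns are serialised with 17
#' significant digits so a read-back reproduces the doubles bit for bit.
#'
#' @param records Non-empty data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data frame", call. = FALSE)
  out <- records
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_table()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
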