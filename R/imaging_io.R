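#' tmequant: spatial quantification of tumor immune microenvironments
#'
#' Tools for quantifying immune-cell spatial organization in fluorescence
#' immunohistochemistry (cell segmentation, distance-to-stroma metrics, grid
#' occupancy), tumor vessel volume in 3D MR angiography, and the survival and
#' cytometry/qPCR summaries that accompany such studies. A synthetic-data
#' module generates ground-truth fields, vessel phantoms and censored cohorts
#' for end-to-end validation.
#'
#' @section Conventions:
#' Images are numeric matrices indexed `[row, col]`, 1-based, with pixel
#' centers at integer coordinates (pixel `i` covers the interval
#' `[i - 0.5, i + 0.5)`). Physical scale is carried as `pixel_scale` in
#' pixels per micrometer; `distance_um = distance_px / pixel_scale`.
#' Intensities are non-negative and are never rescaled on load
#' (constant-exposure convention): thresholds are meaningful only because all
#' fields of a study share acquisition settings.
#'
#' @docType package
#' @name tmequant-package
#' @aliases tmequant
#' @keywords internal
"_PACKAGE"

#' Construct a multi-channel fluorescence field
#'
#' The unit of all IHC analysis: a set of equally shaped single-channel
#' intensity matrices with a physical pixel scale.
#'
#' @param channels named list of numeric matrices (intensity in arbitrary
#'   units, non-negative), all of identical dimension. Typical channel names
#'   are `"DAPI"`, `"CD3"`, `"aSMA"`, `"F480"`, `"CD11c"`.
#' @param pixel_scale pixels per micrometer (default 1.98, a common 10x
#'   widefield configuration).
#' @param field_id identifier used in result tables.
#' @param group_label optional treatment-group label (kept separate from
#'   analysis stages; see [run_pipeline()] on blinding).
#' @return An object of class `fluorescence_field` with elements `channels`,
#'   `height`, `width`, `pixel_scale`, `field_id`, `group_label`.
#' @export
fluorescence_field <- function(channels, pixel_scale = 1.98,
                               field_id = "field", group_label = NA_character_) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1L))) ||
      any(vapply(channels, function(m) length(dim(m)) != 2L, logical(1L)))) {
    stop("every channel must be a 2D matrix")
  }
  d0 <- dims[[1L]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1L)))) {
    stop("all channels must share identical height x width")
  }
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L ||
      !is.finite(pixel_scale) || pixel_scale <= 0) {
    stop("`pixel_scale` must be a single positive number")
  }
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (!all(is.finite(v)) || any(v < 0)) {
      stop("channel '", nm, "' contains negative or non-finite intensities")
    }
  }
  structure(
    list(channels = channels, height = d0[1L], width = d0[2L],
         pixel_scale = pixel_scale, field_id = as.character(field_id),
         group_label = as.character(group_label)),
    class = "fluorescence_field")
}

#' @export
print.fluorescence_field <- function(x, ...) {
  cat(sprintf("<fluorescence_field '%s'> %d x %d px (%.1f x %.1f um), %.2f px/um\n",
              x$field_id, x$height, x$width,
              x$height / x$pixel_scale, x$width / x$pixel_scale, x$pixel_scale))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a 3D angiography volume
#'
#' @param intensity 3D numeric array of MR signal intensities.
#' @param voxel_size_um isotropic voxel edge length in micrometers
#'   (default 50).
#' @param volume_id identifier.
#' @return An object of class `angio_volume`.
#' @export
angio_volume <- function(intensity, voxel_size_um = 50, volume_id = "volume") {
  if (length(dim(intensity)) != 3L) stop("`intensity` must be a 3D array")
  if (any(dim(intensity) < 1L)) stop("all volume dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a single positive number")
  }
  structure(list(intensity = intensity, voxel_size_um = voxel_size_um,
                 volume_id = as.character(volume_id)),
            class = "angio_volume")
}

#' @export
print.angio_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<angio_volume '%s'> %d x %d x %d voxels at %g um isotropic\n",
              x$volume_id, d[1L], d[2L], d[3L], x$voxel_size_um))
  invisible(x)
}

#' Read a multi-channel fluorescence field from a multi-page TIFF
#'
#' Pages map to channels in file order; channel names are supplied by the
#' caller (configuration), never guessed from metadata. No intensity
#' rescaling is performed: integer TIFFs are returned in native digital
#' numbers, float TIFFs as stored.
#'
#' @param path TIFF file with one page per channel.
#' @param channel_names character vector naming the pages, in order.
#' @param pixel_scale pixels per micrometer.
#' @inheritParams fluorescence_field
#' @return A [fluorescence_field()].
#' @export
read_field <- function(path, channel_names, pixel_scale = 1.98,
                       field_id = sub("\\.tiff?$", "", basename(path)),
                       group_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  if (is.data.frame(info)) n_pages <- nrow(info) else n_pages <- length(info)
  fmt <- if (is.data.frame(info) && "sample.format" %in% names(info)) {
    info$sample.format
  } else "uint"
  if (n_pages != length(channel_names)) {
    stop("channel-count mismatch: TIFF has ", n_pages, " page(s) but ",
         length(channel_names), " channel name(s) were given")
  }
  # as.is=TRUE returns native integers for uint samples but misdecodes
  # float samples; float pages are read in natural (already-float) units
  as_is <- all(fmt == "uint")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2L) {
      stop("TIFF page is not single-sample 2D (RGB/multi-sample pages unsupported)")
    }
  }
  names(pages) <- channel_names
  fluorescence_field(pages, pixel_scale = pixel_scale,
                     field_id = field_id, group_label = group_label)
}

#' Write a fluorescence field to a multi-page TIFF
#'
#' Integer-valued channels are stored as 16-bit unsigned samples and
#' round-trip bit-exactly through [read_field()]; non-integer channels are
#' stored as 32-bit float (single precision).
#'
#' @param field a [fluorescence_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "fluorescence_field"))
  chans <- field$channels
  int_ok <- all(vapply(chans, function(m) all(m == round(m)) && max(m) <= 65535,
                       logical(1L)))
  if (int_ok) {
    pages <- lapply(chans, function(m) m / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(lapply(chans, identity), path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a 3D angiography volume
#'
#' Accepts NIfTI-1 (`.nii`/`.nii.gz`). If the container declares a voxel
#' spacing that disagrees with `voxel_size_um`, a warning is emitted and the
#' argument wins; pass `voxel_size_um = NULL` to take the header value.
#'
#' @param path NIfTI file.
#' @param voxel_size_um voxel edge in micrometers, or `NULL` to use the
#'   header spacing (interpreted as millimeters, the NIfTI default unit).
#' @param volume_id identifier.
#' @return An [angio_volume()].
#' @export
read_volume <- function(path, voxel_size_um = 50,
                        volume_id = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop NIfTI bookkeeping
  d <- dim(arr)
  # tolerate trailing singleton dims some writers add
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(arr) <- d
  }
  if (length(d) != 3L) stop("volume is not 3D (got ", length(d), " dimensions)")
  hdr_mm <- tryCatch(RNifti::pixdim(img)[1L], error = function(e) NA_real_)
  hdr_um <- if (is.finite(hdr_mm) && hdr_mm > 0) hdr_mm * 1000 else NA_real_
  if (is.null(voxel_size_um)) {
    if (!is.finite(hdr_um)) stop("no usable spacing in header and none supplied")
    voxel_size_um <- hdr_um
  } else if (is.finite(hdr_um) &&
             abs(hdr_um - voxel_size_um) > 1e-6 * max(hdr_um, voxel_size_um)) {
    warning(sprintf(
      "header spacing %.3f um differs from supplied voxel_size_um %.3f um; using the argument",
      hdr_um, voxel_size_um))
  }
  angio_volume(arr, voxel_size_um = voxel_size_um, volume_id = volume_id)
}

#' Write a 3D angiography volume to NIfTI
#'
#' @param vol an [angio_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "angio_volume"))
  img <- RNifti::asNifti(vol$intensity)
  mm <- vol$voxel_size_um / 1000
  RNifti::pixdim(img) <- c(mm, mm, mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write tabular results to CSV or JSON
#'
#' Floats are serialized at full precision (>= 6 significant digits), so a
#' read-back differs by at most rounding in the last digit.
#'
#' @param records a non-empty data.frame.
#' @param path output path.
#' @param format `"csv"` (RFC-4180 with header row) or `"json"`
#'   (array of row objects).
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a non-empty data.frame")
  }
  if (format == "csv") {
    utils::write.csv(format(records, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, na = "null")
  }
  invisible(path)
}

#' Convert pixel distances to micrometers
#'
#' @param distance_px distance(s) in pixels.
#' @param pixel_scale pixels per micrometer.
#' @return distance(s) in micrometers.
#' @export
px_to_um <- function(distance_px, pixel_scale) {
  stopifnot(pixel_scale > 0)
  distance_px / pixel_scale
}

#' Convert micrometer distances to pixels
#'
#' @inheritParams px_to_um
#' @param distance_um distance(s) in micrometers.
#' @export
um_to_px <- function(distance_um, pixel_scale) {
  stopifnot(pixel_scale > 0)
  distance_um * pixel_scale
}
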