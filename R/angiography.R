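#' Binarize an angiography volume at a relative intensity threshold
#'
#' The threshold is `v_min + fraction * (v_max - v_min)` where `v_min`/`v_max`
#' are taken over the volume after optionally discarding intensity
#' percentiles (clipping off extreme outliers; off by default). A voxel is
#' positive when its intensity is strictly greater than the threshold.
#' Because the threshold is relative to the per-volume range, the result is
#' invariant to affine intensity rescaling `v -> a*v + b` (`a > 0`) when
#' clipping is off.
#'
#' @param vol an [angio_volume()].
#' @param fraction relative threshold in (0, 1); default 0.5 (the 50%
#'   intensity threshold conventional for MR angiography vessel maps).
#' @param clip_percentiles length-2 vector of lower/upper percentiles (in
#'   \[0, 100\]) used to compute the range; default `c(0, 100)` (no clipping).
#' @return Logical 3D array with attributes `threshold_value` and
#'   `threshold_fraction`.
#' @export
binarize_volume <- function(vol, fraction = 0.5, clip_percentiles = c(0, 100)) {
  stopifnot(inherits(vol, "angio_volume"))
  if (!(fraction > 0 && fraction < 1)) stop("`fraction` must be in (0, 1)")
  v <- vol$intensity
  if (identical(as.numeric(clip_percentiles), c(0, 100))) {
    vmin <- min(v); vmax <- max(v)
  } else {
    q <- stats::quantile(v, probs = clip_percentiles / 100, names = FALSE,
                         type = 7)
    vmin <- q[1L]; vmax <- q[2L]
  }
  if (vmax <= vmin) stop("constant volume: relative threshold undefined")
  thr <- vmin + fraction * (vmax - vmin)
  out <- v > thr
  attr(out, "threshold_value") <- thr
  attr(out, "threshold_fraction") <- fraction
  out
}

#' Vessel volume from a binary vessel map
#'
#' Counts positive voxels and converts to cubic millimeters via the voxel
#' volume `(voxel_size_um / 1000)^3`.
#'
#' @param binary logical 3D array (e.g. from [binarize_volume()]).
#' @param voxel_size_um isotropic voxel edge in micrometers.
#' @return An object of class `vessel_quant`: `positive_voxels`,
#'   `voxel_volume_mm3`, `vessel_volume_mm3`, `threshold_fraction`,
#'   `threshold_value` (the latter two taken from the binary map's
#'   attributes when present).
#' @export
vessel_volume <- function(binary, voxel_size_um) {
  if (length(dim(binary)) != 3L) stop("`binary` must be a 3D array")
  if (voxel_size_um <= 0) stop("`voxel_size_um` must be positive")
  npos <- sum(binary != 0)
  vox_mm3 <- (voxel_size_um / 1000)^3
  structure(list(positive_voxels = npos,
                 voxel_volume_mm3 = vox_mm3,
                 vessel_volume_mm3 = npos * vox_mm3,
                 threshold_fraction = attr(binary, "threshold_fraction"),
                 threshold_value = attr(binary, "threshold_value")),
            class = "vessel_quant")
}

#' @export
print.vessel_quant <- function(x, ...) {
  cat(sprintf("<vessel_quant> %d voxels = %.4f mm^3", x$positive_voxels,
              x$vessel_volume_mm3))
  if (!is.null(x$threshold_fraction)) {
    cat(sprintf(" (threshold %.0f%% of range = %.4g)",
                100 * x$threshold_fraction, x$threshold_value))
  }
  cat("\n")
  invisible(x)
}

#' Maximum intensity projection
#'
#' @param vol an [angio_volume()] or 3D array.
#' @param axis axis to project along: 1, 2 or 3.
#' @return 2D matrix of per-position maxima; shape is the volume shape with
#'   `axis` removed.
#' @export
mip <- function(vol, axis = 3) {
  v <- if (inherits(vol, "angio_volume")) vol$intensity else vol
  if (length(dim(v)) != 3L) stop("need a 3D volume")
  if (!axis %in% 1:3) stop("`axis` must be 1, 2 or 3")
  apply(v, setdiff(1:3, axis), max)
}

#' Percent change of a treated quantity relative to control
#'
#' `100 * (treated - control) / control`; the convention used to report
#' group differences such as vessel-volume increases.
#'
#' @param treated,control positive quantities in the same units.
#' @return Percent change (signed).
#' @export
percent_change <- function(treated, control) {
  if (!is.finite(control) || control <= 0) stop("`control` must be > 0")
  100 * (treated - control) / control
}
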