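#' Segmentation parameters
#'
#' Intensity, size and morphology bounds applied to connected components of
#' the thresholded channel. The same parameter set is intended to be applied
#' to every field of a study (constant-exposure convention), so thresholds
#' remain comparable across images.
#'
#' @param intensity_threshold binarization threshold in intensity units;
#'   pixels strictly greater than the threshold are foreground. Typically
#'   obtained from a no-primary control via [estimate_threshold()].
#' @param min_area_px,max_area_px inclusive component area bounds in pixels^2.
#' @param min_solidity minimum solidity (component area / convex hull area)
#'   in (0, 1]; permissive default 0.7 keeps blob-like cells and rejects
#'   ragged debris.
#' @param max_eccentricity maximum ellipse eccentricity in \[0, 1\]; default
#'   0.99 rejects only near-degenerate linear objects (e.g. fibers).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(intensity_threshold, min_area_px = 5,
                                max_area_px = 500, min_solidity = 0.7,
                                max_eccentricity = 0.99) {
  if (!is.finite(intensity_threshold) || intensity_threshold < 0) {
    stop("`intensity_threshold` must be finite and >= 0")
  }
  if (!(min_area_px > 0 && min_area_px <= max_area_px)) {
    stop("need 0 < min_area_px <= max_area_px")
  }
  if (!(min_solidity > 0 && min_solidity <= 1)) stop("min_solidity must be in (0, 1]")
  if (!(max_eccentricity >= 0 && max_eccentricity <= 1)) {
    stop("max_eccentricity must be in [0, 1]")
  }
  structure(list(intensity_threshold = intensity_threshold,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 min_solidity = min_solidity,
                 max_eccentricity = max_eccentricity),
            class = "segmentation_params")
}

#' Estimate a channel threshold from a no-primary control field
#'
#' Background fluorescence and non-specific staining are measured on sections
#' stained with secondary antibodies only; the detection threshold for the
#' study is then `mean + k * SD` of the control intensities. Deterministic
#' given the control image.
#'
#' @param control_field a [fluorescence_field()] acquired from a
#'   secondary-antibody-only control section.
#' @param channel channel name.
#' @param k number of standard deviations above the control mean (default 3).
#'   With a constant control (SD = 0) the mean is returned.
#' @return Threshold in intensity units.
#' @export
estimate_threshold <- function(control_field, channel, k = 3) {
  stopifnot(inherits(control_field, "fluorescence_field"))
  img <- .get_channel(control_field, channel)
  v <- as.numeric(img)
  s <- stats::sd(v)
  if (!is.finite(s)) s <- 0  # single-pixel control
  mean(v) + k * s
}

#' Segment marker-positive cells in one channel
#'
#' Binarizes at the intensity threshold (strict `>`), labels 8-connected
#' components, discards components violating the area / solidity /
#' eccentricity bounds, and reports each surviving component's centroid
#' (unweighted mean of member pixel coordinates) and area.
#'
#' @param field a [fluorescence_field()].
#' @param channel channel name (e.g. `"CD3"`).
#' @param params a [segmentation_params()].
#' @return An object of class `cell_set`: list with `channel`,
#'   `cells` (data.frame `label_id`, `row`, `col`, `area_px`),
#'   `source_field_id`, and the `params` used.
#'   An all-background image yields an empty (zero-row) cell set.
#' @export
segment_cells <- function(field, channel, params) {
  stopifnot(inherits(field, "fluorescence_field"),
            inherits(params, "segmentation_params"))
  img <- .get_channel(field, channel)
  mask <- img > params$intensity_threshold
  lab <- label_components(mask)
  feats <- .component_features(lab, params)
  structure(list(channel = channel, cells = feats,
                 source_field_id = field$field_id, params = params,
                 field_shape = c(field$height, field$width)),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> %d %s+ cell(s) in field '%s'\n",
              nrow(x$cells), x$channel, x$source_field_id))
  invisible(x)
}

#' Label connected components with 8-connectivity
#'
#' Components connected through edges or corners receive one label.
#' Implemented as a 4-connected labeling pass followed by a union-find merge
#' of labels adjacent along the two diagonals.
#'
#' @param mask logical (or 0/1) matrix.
#' @return Integer matrix of the same shape; 0 is background, components are
#'   labeled 1..n in first-pixel (column-major) order.
#' @export
label_components <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask)          # 4-connected
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (nmax > 1L) {
    H <- nrow(lab); W <- ncol(lab)
    # diagonal neighbor label pairs (down-right and down-left)
    a <- lab[-H, -W]; b <- lab[-1, -1]
    sel <- a > 0L & b > 0L & a != b
    pairs1 <- cbind(a[sel], b[sel])
    a <- lab[-H, -1]; b <- lab[-1, -W]
    sel <- a > 0L & b > 0L & a != b
    pairs <- rbind(pairs1, cbind(a[sel], b[sel]))
    if (nrow(pairs)) {
      parent <- seq_len(nmax)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (r in seq_len(nrow(pairs))) {
        ri <- find(pairs[r, 1L]); rj <- find(pairs[r, 2L])
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      root <- vapply(seq_len(nmax), find, integer(1L))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  # compact labels to 1..n in first-occurrence order
  u <- unique(lab[lab > 0L])
  remap <- integer(max(u)); remap[u] <- seq_along(u)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# per-component area, centroid, eccentricity, solidity; filtered by params
.component_features <- function(lab, params) {
  empty <- data.frame(label_id = integer(), row = numeric(), col = numeric(),
                      area_px = numeric())
  n <- max(lab)
  if (n == 0L) return(empty)
  H <- nrow(lab)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  area <- tabulate(labs, nbins = n)
  keep <- which(area >= params$min_area_px & area <= params$max_area_px)
  if (!length(keep)) return(empty)
  sel <- labs %in% keep
  labs <- labs[sel]; rows <- rows[sel]; cols <- cols[sel]
  cr <- rowsum(rows, labs) / area[keep]
  cc <- rowsum(cols, labs) / area[keep]
  # central second moments -> ellipse eccentricity
  mu20 <- rowsum(rows^2, labs) / area[keep] - cr^2
  mu02 <- rowsum(cols^2, labs) / area[keep] - cc^2
  mu11 <- rowsum(rows * cols, labs) / area[keep] - cr * cc
  half_tr <- (mu20 + mu02) / 2
  disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- half_tr + disc
  l2 <- pmax(half_tr - disc, 0)
  ecc <- ifelse(l1 <= 0, 0, sqrt(pmax(1 - l2 / l1, 0)))
  ok_ecc <- ecc <= params$max_eccentricity
  # solidity only for survivors of the cheap filters
  split_r <- split(rows, labs)
  split_c <- split(cols, labs)
  ord <- as.integer(names(split_r))          # label ids, sorted
  sol <- rep(NA_real_, length(keep))
  pos <- match(ord, keep)
  for (i in seq_along(ord)) {
    if (!ok_ecc[pos[i]]) next
    sol[pos[i]] <- .pixel_solidity(split_r[[i]], split_c[[i]])
  }
  ok <- ok_ecc & !is.na(sol) & sol >= params$min_solidity
  out <- data.frame(label_id = keep[ok],
                    row = as.numeric(cr[ok]), col = as.numeric(cc[ok]),
                    area_px = as.numeric(area[keep][ok]))
  out[order(out$label_id), , drop = FALSE]
}

# regionprops-style solidity: component area over the pixel count of its
# convex hull image (lattice points inside the hull of member pixel centers)
.pixel_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2L) return(1)
  h <- grDevices::chull(cols, rows)  # clockwise vertices in (x, y) = (col, row)
  if (length(h) < 3L) return(1)      # collinear component
  hx <- cols[h]; hy <- rows[h]
  rr <- min(rows):max(rows); cc <- min(cols):max(cols)
  px <- rep(cc, each = length(rr)); py <- rep(rr, times = length(cc))
  inside <- rep(TRUE, length(px))
  m <- length(h)
  for (k in seq_len(m)) {
    k2 <- k %% m + 1L
    crs <- (hx[k2] - hx[k]) * (py - hy[k]) - (hy[k2] - hy[k]) * (px - hx[k])
    inside <- inside & crs <= 1e-9
  }
  hull_px <- sum(inside)
  if (hull_px <= n) return(1)
  n / hull_px
}

#' Segment a structure-positive area (binary region mask)
#'
#' Thresholds a structure channel (e.g. alpha-SMA) and reports the mask and
#' its exact positive-area fraction.
#'
#' @inheritParams segment_cells
#' @param intensity_threshold threshold in intensity units; pixels strictly
#'   greater are positive.
#' @return An object of class `region_mask`: list with `channel`, `mask`
#'   (logical matrix) and `area_fraction`.
#' @export
segment_area <- function(field, channel, intensity_threshold) {
  stopifnot(inherits(field, "fluorescence_field"))
  img <- .get_channel(field, channel)
  region_mask(img > intensity_threshold, channel = channel)
}

#' Construct a region mask
#'
#' @param mask logical (or 0/1) matrix.
#' @param channel channel label the mask was derived from.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(mask, channel = "structure") {
  if (length(dim(mask)) != 2L) stop("`mask` must be a 2D matrix")
  mask <- mask != 0
  structure(list(channel = channel, mask = mask,
                 area_fraction = sum(mask) / length(mask)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s+ area fraction %.4f (%d x %d px)\n",
              x$channel, x$area_fraction, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Advisory quality-control flags for a field
#'
#' Screens for the acquisition problems that exclude fields from analysis:
#' saturated pixels, near-empty tissue (out-of-focus or artifact-dominated
#' fields mostly fail this), and strong illumination gradients. Advisory
#' only; nothing is modified.
#'
#' @param field a [fluorescence_field()].
#' @param channel channel to screen, default the first.
#' @param sat_value intensity treated as sensor saturation. Default guesses
#'   the dtype ceiling from the data: 255 if no pixel exceeds 255, else
#'   65535 for integer data; for float data `Inf` (no saturation flag).
#' @param empty_floor minimum foreground fraction (pixels above 5% of
#'   `sat_value`) below which the field is flagged `near_empty`.
#' @param gradient_factor maximum allowed ratio between the largest and
#'   smallest smoothed row/column median before `illumination_gradient` is
#'   flagged.
#' @return Character vector of flags (possibly empty): subset of
#'   `"saturation"`, `"near_empty"`, `"illumination_gradient"`.
#' @export
qc_flags <- function(field, channel = names(field$channels)[1L],
                     sat_value = NULL, empty_floor = 0.01,
                     gradient_factor = 4) {
  stopifnot(inherits(field, "fluorescence_field"))
  img <- .get_channel(field, channel)
  flags <- character()
  if (is.null(sat_value)) {
    if (all(img == round(img))) {
      sat_value <- if (max(img) <= 255) 255 else 65535
    } else {
      sat_value <- Inf
    }
  }
  if (is.finite(sat_value) && any(img >= sat_value)) flags <- c(flags, "saturation")
  fg_thresh <- if (is.finite(sat_value)) 0.05 * sat_value else 0.05 * max(img, 1)
  if (mean(img > fg_thresh) < empty_floor) flags <- c(flags, "near_empty")
  rmed <- stats::runmed(apply(img, 1L, stats::median), k = .odd_k(nrow(img)))
  cmed <- stats::runmed(apply(img, 2L, stats::median), k = .odd_k(ncol(img)))
  for (m in list(rmed, cmed)) {
    lo <- min(m); hi <- max(m)
    if (hi > 0 && lo > 0 && hi / lo > gradient_factor) {
      flags <- c(flags, "illumination_gradient")
      break
    }
  }
  flags
}

.odd_k <- function(n) {
  k <- max(3L, min(31L, as.integer(n %/% 8) * 2L + 1L))
  min(k, if (n %% 2L == 1L) n else n - 1L)
}

.get_channel <- function(field, channel) {
  if (!channel %in% names(field$channels)) {
    stop("channel '", channel, "' not present in field '", field$field_id,
         "' (has: ", paste(names(field$channels), collapse = ", "), ")")
  }
  field$channels[[channel]]
}
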