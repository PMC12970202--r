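#' Per-cell distance to the nearest structure-positive pixel
#'
#' For each cell centroid, the Euclidean distance (pixel-center to
#' pixel-center geometry) to the nearest mask-positive pixel center,
#' converted to micrometers. A centroid whose containing pixel is itself
#' mask-positive has distance exactly 0 (cells inside the structure are
#' recorded at 0, not excluded).
#'
#' The search is exact: a Euclidean distance transform of the mask bounds
#' the search radius for each centroid, and the true minimum is then taken
#' over all candidate positive pixel centers inside that radius.
#'
#' @param cells a [segment_cells()] result (`cell_set`).
#' @param mask a [region_mask()] of the same field shape, with at least one
#'   positive pixel.
#' @param pixel_scale pixels per micrometer.
#' @param edges_um bin edges passed to [bin_distances()]; default `c(0, 20)`
#'   reports the fraction of cells within 20 um of the structure and the
#'   fraction beyond 20 um.
#' @return An object of class `distance_result`: `per_cell_um`, `mean_um`,
#'   `bin_edges_um`, `bin_fractions`, `n_cells`, `empty` (flag). With an
#'   empty cell set, `per_cell_um` is empty and `mean_um`/`bin_fractions`
#'   are `NA`, flagged via `empty = TRUE`.
#' @export
nearest_structure_distances <- function(cells, mask, pixel_scale,
                                        edges_um = c(0, 20)) {
  stopifnot(inherits(cells, "cell_set"), inherits(mask, "region_mask"))
  if (pixel_scale <= 0) stop("`pixel_scale` must be positive")
  m <- mask$mask
  if (!any(m)) stop("mask has no positive pixels: distance undefined")
  if (!is.null(cells$field_shape) &&
      !identical(as.integer(cells$field_shape), as.integer(dim(m)))) {
    stop("cells and mask come from differently shaped fields")
  }
  n <- nrow(cells$cells)
  if (n == 0L) {
    res <- structure(list(per_cell_um = numeric(), mean_um = NA_real_,
                          bin_edges_um = edges_um, bin_fractions = NA_real_,
                          n_cells = 0L, empty = TRUE),
                     class = "distance_result")
    return(res)
  }
  d_px <- .nearest_positive_px(cells$cells$row, cells$cells$col, m)
  per_um <- d_px / pixel_scale
  fr <- .bin_fractions(per_um, edges_um)
  structure(list(per_cell_um = per_um, mean_um = mean(per_um),
                 bin_edges_um = edges_um, bin_fractions = fr,
                 n_cells = n, empty = FALSE),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  if (x$empty) {
    cat("<distance_result> empty cell set (distances undefined)\n")
  } else {
    cat(sprintf("<distance_result> n = %d, mean = %.3f um\n", x$n_cells, x$mean_um))
    lab <- .bin_labels(x$bin_edges_um)
    cat(paste(sprintf("  %s: %.3f", lab, x$bin_fractions), collapse = "\n"), "\n")
  }
  invisible(x)
}

# exact nearest positive-pixel-center distance for continuous points (r, c);
# containment rule: points whose containing pixel is positive get 0
.nearest_positive_px <- function(r, c, mask) {
  H <- nrow(mask); W <- ncol(mask)
  dmap <- EBImage::distmap(1 - mask)  # per-pixel distance to nearest positive
  dmap <- matrix(as.numeric(dmap), H, W)
  pos <- which(mask)
  pr <- ((pos - 1L) %% H) + 1L
  pc <- ((pos - 1L) %/% H) + 1L
  ord <- order(pr)
  pr_s <- pr[ord]; pc_s <- pc[ord]
  out <- numeric(length(r))
  for (i in seq_along(r)) {
    cr <- min(max(floor(r[i] + 0.5), 1L), H)  # containing pixel (round-half-up)
    cc <- min(max(floor(c[i] + 0.5), 1L), W)
    if (mask[cr, cc]) { out[i] <- 0; next }
    # nearest positive center is no farther than (dist to own center) + dmap;
    # the window is widened by an epsilon so boundary pixels exactly at the
    # bound are kept
    bound <- sqrt((r[i] - cr)^2 + (c[i] - cc)^2) + dmap[cr, cc]
    i1 <- findInterval(r[i] - bound - 1e-7, pr_s) + 1L
    i2 <- findInterval(r[i] + bound + 1e-7, pr_s)
    rr <- pr_s[i1:i2]; cc2 <- pc_s[i1:i2]
    sel <- abs(cc2 - c[i]) <= bound + 1e-7
    out[i] <- sqrt(min((rr[sel] - r[i])^2 + (cc2[sel] - c[i])^2))
  }
  out
}

.bin_fractions <- function(d, edges) {
  .check_edges(edges)
  edges <- c(edges[is.finite(edges)], Inf)
  counts <- tabulate(findInterval(d, edges), nbins = length(edges) - 1L)
  counts / length(d)
}

.bin_labels <- function(edges) {
  edges <- c(edges[is.finite(edges)], Inf)
  k <- length(edges) - 1L
  out <- character(k)
  for (i in seq_len(k)) {
    out[i] <- if (is.finite(edges[i + 1L])) {
      sprintf("[%g, %g) um", edges[i], edges[i + 1L])
    } else {
      sprintf(">= %g um", edges[i])
    }
  }
  out
}

.check_edges <- function(edges) {
  e <- edges[is.finite(edges)]
  if (length(e) < 1L || e[1L] != 0) stop("bin edges must start at 0")
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  invisible(TRUE)
}

#' Bin per-cell distances into fractions
#'
#' Fraction of cells falling in `[e_i, e_{i+1})` for each consecutive pair of
#' edges, with the last bin closed above at infinity. The default edges
#' `c(0, 20)` report the proportion of cells within versus beyond 20 um of
#' the structure.
#'
#' @param result a `distance_result` or a numeric vector of distances (um).
#' @param edges_um strictly increasing edges starting at 0; a trailing `Inf`
#'   is implied if absent.
#' @return Numeric vector of fractions summing to 1.
#' @export
bin_distances <- function(result, edges_um = c(0, 20)) {
  d <- if (inherits(result, "distance_result")) result$per_cell_um else result
  if (length(d) == 0L) stop("no distances to bin (empty cell set)")
  .bin_fractions(d, edges_um)
}

#' Grid (quadrat) occupancy of a cell distribution
#'
#' Tiles the field into `grid_side_px` x `grid_side_px` squares (partial
#' squares at the right/bottom edges included) and counts squares that are
#' "positive". Higher occupancy means a more homogeneous spatial
#' distribution; excluded cell populations concentrate in fewer grids.
#'
#' Positivity criteria:
#' \describe{
#'   \item{`centroid`}{the square contains at least one cell centroid
#'     (default; a cell is located in the square holding its containing
#'     pixel).}
#'   \item{`pixel_fraction`}{at least 50% of the square's pixels are
#'     mask-positive.}
#'   \item{`either`}{union of the two criteria.}
#' }
#'
#' @param cells a `cell_set`, or `NULL` when `mode = "pixel_fraction"`.
#' @param mask a [region_mask()]; required unless `mode = "centroid"`.
#' @param field_shape integer `(H, W)` in pixels; defaults to the shape
#'   recorded in `cells`.
#' @param grid_side_px square side in pixels (default 100).
#' @param mode positivity criterion, see above.
#' @param pixel_fraction fraction of square pixels that must be
#'   mask-positive in the `pixel_fraction`/`either` modes (default 0.5).
#' @return An object of class `grid_heterogeneity`: `grid_side_px`,
#'   `n_grids`, `n_positive`, `mode`, `occupancy_fraction`, `grid_dims`.
#' @export
grid_occupancy <- function(cells = NULL, mask = NULL,
                           field_shape = cells$field_shape,
                           grid_side_px = 100,
                           mode = c("centroid", "pixel_fraction", "either"),
                           pixel_fraction = 0.5) {
  mode <- match.arg(mode)
  if (grid_side_px < 1) stop("`grid_side_px` must be >= 1")
  if (mode != "pixel_fraction" && is.null(cells)) {
    stop("`cells` required in mode '", mode, "'")
  }
  if (mode != "centroid" && is.null(mask)) {
    stop("`mask` required in mode '", mode, "'")
  }
  if (is.null(field_shape)) {
    if (!is.null(mask)) field_shape <- dim(mask$mask) else
      stop("`field_shape` could not be inferred")
  }
  H <- as.integer(field_shape[1L]); W <- as.integer(field_shape[2L])
  gr <- ceiling(H / grid_side_px); gc <- ceiling(W / grid_side_px)
  n_grids <- gr * gc
  hit_centroid <- hit_pixel <- logical(n_grids)
  if (mode %in% c("centroid", "either") && nrow(cells$cells) > 0L) {
    pr <- pmin(pmax(floor(cells$cells$row + 0.5), 1L), H)
    pc <- pmin(pmax(floor(cells$cells$col + 0.5), 1L), W)
    gi <- ceiling(pr / grid_side_px)
    gj <- ceiling(pc / grid_side_px)
    hit_centroid[unique((gj - 1L) * gr + gi)] <- TRUE
  }
  if (mode %in% c("pixel_fraction", "either")) {
    m <- mask$mask
    if (!identical(dim(m), c(H, W))) stop("mask shape differs from field_shape")
    gi <- ceiling(row(m) / grid_side_px)
    gj <- ceiling(col(m) / grid_side_px)
    gidx <- (gj - 1L) * gr + gi
    npos <- tabulate(gidx[m], nbins = n_grids)
    ntot <- tabulate(gidx, nbins = n_grids)
    hit_pixel <- npos >= pixel_fraction * ntot & ntot > 0L
  }
  hit <- switch(mode,
                centroid = hit_centroid,
                pixel_fraction = hit_pixel,
                either = hit_centroid | hit_pixel)
  structure(list(grid_side_px = grid_side_px, n_grids = n_grids,
                 n_positive = sum(hit), mode = mode,
                 occupancy_fraction = sum(hit) / n_grids,
                 grid_dims = c(gr, gc)),
            class = "grid_heterogeneity")
}

#' @export
print.grid_heterogeneity <- function(x, ...) {
  cat(sprintf("<grid_heterogeneity> %d / %d grids positive (%.3f), side %g px, mode '%s'\n",
              x$n_positive, x$n_grids, x$occupancy_fraction,
              x$grid_side_px, x$mode))
  invisible(x)
}

#' Cell density in cells per square millimeter
#'
#' @param cells a `cell_set`.
#' @param field_shape `(H, W)` in pixels; defaults to the shape recorded in
#'   `cells`.
#' @param pixel_scale pixels per micrometer.
#' @return Density in cells / mm^2.
#' @export
cell_density <- function(cells, field_shape = cells$field_shape, pixel_scale) {
  stopifnot(inherits(cells, "cell_set"))
  if (pixel_scale <= 0) stop("`pixel_scale` must be positive")
  H <- field_shape[1L]; W <- field_shape[2L]
  area_mm2 <- (H * W) / pixel_scale^2 / 1e6
  if (area_mm2 <= 0) stop("zero-area field")
  nrow(cells$cells) / area_mm2
}

#' Partition fields into structure-rich and structure-poor groups
#'
#' The mean positive-area fraction across fields is the cutoff: fields with
#' fraction strictly above the mean are "rich", the rest (ties included)
#' "poor".
#'
#' @param masks list of [region_mask()] objects (>= 2), or a numeric vector
#'   of area fractions.
#' @param ids identifiers; defaults to names or indices.
#' @return List with `rich`, `poor` (identifier vectors) and `cutoff`.
#' @export
split_rich_poor <- function(masks, ids = NULL) {
  if (is.list(masks)) {
    fr <- vapply(masks, function(m) {
      stopifnot(inherits(m, "region_mask")); m$area_fraction
    }, numeric(1L))
  } else {
    fr <- as.numeric(masks)
  }
  if (length(fr) < 2L) stop("need >= 2 masks to split")
  if (is.null(ids)) {
    ids <- names(fr)
    if (is.null(ids)) ids <- seq_along(fr)
  }
  cutoff <- mean(fr)
  list(rich = ids[fr > cutoff], poor = ids[fr <= cutoff], cutoff = cutoff)
}
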