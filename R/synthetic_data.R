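#' Specification for a synthetic fluorescence field
#'
#' Describes a ground-truth-known two-channel field: a structure channel
#' (`aSMA`) rendered as ribbon-like chords crossing the field, and a cell
#' channel (`CD3`) rendered as isotropic Gaussian blobs whose centroids are
#' sampled under one of three point processes relative to the structure:
#' uniform, stroma-excluded (hard exclusion radius) or stroma-attracted
#' (acceptance probability decaying exponentially with distance).
#'
#' Intensities emulate a 16-bit camera: a constant background offset plus
#' signal plus additive Gaussian read noise, rounded to integer digital
#' numbers and clamped at 0. Cell centroids keep a hard-core minimum
#' separation (cells are solid bodies and do not interpenetrate) and a
#' border margin that keeps blobs fully inside the field.
#'
#' @param shape `(H, W)` in pixels.
#' @param pixel_scale pixels per micrometer.
#' @param n_cells number of cells to place.
#' @param placement `"uniform"`, `"excluded"` or `"attracted"`.
#' @param exclusion_radius_um hard exclusion distance from the structure
#'   (used when `placement = "excluded"`); default 20, the conventional
#'   boundary separating stroma-adjacent from stroma-distant cells.
#' @param attraction_scale_um decay length of the attraction kernel
#'   `exp(-d / scale)` (used when `placement = "attracted"`).
#' @param structure list of ribbon segments `list(p1 = c(row, col),
#'   p2 = c(row, col), width_px = ...)`, or `NULL` to sample `n_ribbons`
#'   random full-field chords.
#' @param n_ribbons,ribbon_width_px,ribbon_amplitude random-structure
#'   parameters (chords of the given width and peak intensity in DN).
#' @param blob_sigma_px Gaussian blob standard deviation in pixels.
#' @param blob_amplitude blob peak intensity above background, in DN.
#'   `blob_amplitude / noise_sd` is the peak signal-to-noise ratio.
#' @param background_offset camera offset in DN.
#' @param noise_sd additive Gaussian noise SD in DN.
#' @param min_separation_px hard-core minimum distance between centroids;
#'   default `4 * blob_sigma_px`.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(shape = c(1024, 1024), pixel_scale = 1.98,
                       n_cells = 200,
                       placement = c("uniform", "excluded", "attracted"),
                       exclusion_radius_um = 20, attraction_scale_um = 10,
                       structure = NULL, n_ribbons = 14, ribbon_width_px = 10,
                       ribbon_amplitude = 300, blob_sigma_px = 2,
                       blob_amplitude = 200, background_offset = 100,
                       noise_sd = 20, min_separation_px = 4 * blob_sigma_px,
                       seed = 1) {
  placement <- match.arg(placement)
  stopifnot(length(shape) == 2L, all(shape >= 16), pixel_scale > 0,
            n_cells >= 0, exclusion_radius_um >= 0, attraction_scale_um > 0,
            blob_sigma_px > 0, blob_amplitude > 0, noise_sd >= 0,
            background_offset >= 0, min_separation_px >= 0)
  structure(list(shape = as.integer(shape), pixel_scale = pixel_scale,
                 n_cells = as.integer(n_cells), placement = placement,
                 exclusion_radius_um = exclusion_radius_um,
                 attraction_scale_um = attraction_scale_um,
                 structure = structure, n_ribbons = n_ribbons,
                 ribbon_width_px = ribbon_width_px,
                 ribbon_amplitude = ribbon_amplitude,
                 blob_sigma_px = blob_sigma_px,
                 blob_amplitude = blob_amplitude,
                 background_offset = background_offset, noise_sd = noise_sd,
                 min_separation_px = min_separation_px,
                 seed = as.integer(seed)),
            class = "field_spec")
}

# evaluate expr under a seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# distance from points (r, c) to the nearest of a list of segments
.dist_to_segments <- function(r, c, segments) {
  d <- rep(Inf, length(r))
  for (s in segments) {
    ar <- s$p1[1L]; ac <- s$p1[2L]
    vr <- s$p2[1L] - ar; vc <- s$p2[2L] - ac
    len2 <- vr^2 + vc^2
    if (len2 == 0) {
      di <- sqrt((r - ar)^2 + (c - ac)^2)
    } else {
      t <- pmin(pmax(((r - ar) * vr + (c - ac) * vc) / len2, 0), 1)
      di <- sqrt((r - (ar + t * vr))^2 + (c - (ac + t * vc))^2)
    }
    d <- pmin(d, di)
  }
  d
}

# random full-field chords: uniform interior point + uniform orientation
.random_ribbons <- function(shape, n, width_px) {
  H <- shape[1L]; W <- shape[2L]
  half <- sqrt(H^2 + W^2)
  lapply(seq_len(n), function(i) {
    cr <- stats::runif(1, 1, H); cc <- stats::runif(1, 1, W)
    th <- stats::runif(1, 0, pi)
    list(p1 = c(cr - half * sin(th), cc - half * cos(th)),
         p2 = c(cr + half * sin(th), cc + half * cos(th)),
         width_px = width_px)
  })
}

#' Generate a synthetic fluorescence field with ground truth
#'
#' Renders the structure channel as anti-aliased ribbons and the cell
#' channel as Gaussian blobs at centroids sampled under the spec's point
#' process, then adds camera offset and Gaussian noise and rounds to integer
#' digital numbers. Returns the field together with the ground-truth cell
#' positions and structure mask, so segmentation and the spatial metrics can
#' be validated against known truth.
#'
#' @param spec a [field_spec()].
#' @return List with elements `field` (a [fluorescence_field()] with
#'   channels `CD3` and `aSMA`), `truth_cells` (a `cell_set` of true
#'   centroids), `truth_mask` (a [region_mask()] of the true ribbon
#'   footprint), and `spec`.
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  .with_seed(spec$seed, {
    H <- spec$shape[1L]; W <- spec$shape[2L]
    segments <- spec$structure
    if (is.null(segments)) {
      segments <- .random_ribbons(spec$shape, spec$n_ribbons,
                                  spec$ribbon_width_px)
    }
    pr <- rep(seq_len(H), times = W)
    pc <- rep(seq_len(W), each = H)
    dpix <- matrix(.dist_to_segments(pr, pc, segments), H, W)
    halfw <- vapply(segments, function(s) s$width_px / 2, numeric(1L))
    if (length(unique(halfw)) > 1L) {
      # per-segment widths: recompute coverage against each segment
      cover <- matrix(0, H, W)
      for (s in segments) {
        ds <- matrix(.dist_to_segments(pr, pc, list(s)), H, W)
        cover <- pmax(cover, pmin(pmax(0.5 + s$width_px / 2 - ds, 0), 1))
      }
      truth_mask_mat <- cover >= 0.5
    } else {
      cover <- pmin(pmax(0.5 + halfw[1L] - dpix, 0), 1)
      truth_mask_mat <- dpix <= halfw[1L]
    }
    centroids <- .sample_centroids(spec, segments)
    cd3 <- matrix(0, H, W)
    if (nrow(centroids)) {
      win <- ceiling(4 * spec$blob_sigma_px)
      s2 <- 2 * spec$blob_sigma_px^2
      for (i in seq_len(nrow(centroids))) {
        r0 <- centroids$row[i]; c0 <- centroids$col[i]
        rr <- max(1L, floor(r0) - win):min(H, ceiling(r0) + win)
        cc <- max(1L, floor(c0) - win):min(W, ceiling(c0) + win)
        g <- spec$blob_amplitude *
          exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) / s2)
        cd3[rr, cc] <- cd3[rr, cc] + g
      }
    }
    asma <- spec$ribbon_amplitude * cover
    quantize <- function(sig) {
      img <- spec$background_offset + sig
      if (spec$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
      m <- matrix(as.integer(pmin(pmax(round(img), 0), 65535L)), H, W)
      m
    }
    field <- fluorescence_field(
      list(CD3 = quantize(cd3), aSMA = quantize(asma)),
      pixel_scale = spec$pixel_scale,
      field_id = sprintf("synthetic_%s_seed%d", spec$placement, spec$seed))
    truth_cells <- structure(
      list(channel = "CD3",
           cells = data.frame(label_id = seq_len(nrow(centroids)),
                              row = centroids$row, col = centroids$col,
                              area_px = rep(NA_real_, nrow(centroids))),
           source_field_id = field$field_id, params = NULL,
           field_shape = c(H, W)),
      class = "cell_set")
    list(field = field,
         truth_cells = truth_cells,
         truth_mask = region_mask(truth_mask_mat, channel = "aSMA"),
         spec = spec)
  })
}

# dart-throwing sampler honoring placement rule, hard core and border margin
.sample_centroids <- function(spec, segments) {
  H <- spec$shape[1L]; W <- spec$shape[2L]
  n <- spec$n_cells
  empty <- data.frame(row = numeric(), col = numeric())
  if (n == 0L) return(empty)
  margin <- 3 * spec$blob_sigma_px + 1
  excl_px <- spec$exclusion_radius_um * spec$pixel_scale
  scale_px <- spec$attraction_scale_um * spec$pixel_scale
  # feasibility probe on a coarse lattice
  if (spec$placement == "excluded") {
    gr <- seq(margin, H - margin, length.out = 64)
    gc <- seq(margin, W - margin, length.out = 64)
    dprobe <- .dist_to_segments(rep(gr, times = 64), rep(gc, each = 64),
                                segments)
    if (!any(dprobe >= excl_px)) {
      stop("infeasible placement: exclusion radius leaves no admissible area")
    }
  }
  rows <- numeric(0); cols <- numeric(0)
  attempts <- 0L
  max_attempts <- 4000L * n
  min_sep2 <- spec$min_separation_px^2
  while (length(rows) < n && attempts < max_attempts) {
    k <- max(64L, n)
    cr <- stats::runif(k, margin, H - margin)
    cc <- stats::runif(k, margin, W - margin)
    attempts <- attempts + k
    d <- .dist_to_segments(cr, cc, segments)
    keep <- switch(spec$placement,
                   uniform = rep(TRUE, k),
                   excluded = d >= excl_px,
                   attracted = stats::runif(k) < exp(-d / scale_px))
    cr <- cr[keep]; cc <- cc[keep]
    for (i in seq_along(cr)) {
      if (length(rows) >= n) break
      if (length(rows) == 0L ||
          min((rows - cr[i])^2 + (cols - cc[i])^2) >= min_sep2) {
        rows <- c(rows, cr[i]); cols <- c(cols, cc[i])
      }
    }
  }
  if (length(rows) < n) {
    stop("infeasible placement: could not place ", n, " cells (placed ",
         length(rows), ")")
  }
  data.frame(row = rows, col = cols)
}

#' Specification for a tubular vessel phantom
#'
#' @param shape `(nx, ny, nz)` voxels.
#' @param voxel_size_um isotropic voxel edge in micrometers.
#' @param tubes list of `list(from, to, radius_um, intensity, capped)`:
#'   axis endpoints in continuous voxel coordinates (voxel centers at
#'   integers), tube radius in micrometers, intensity in arbitrary units
#'   (default 100), and `capped` (default `FALSE`): flat-ended cylinder when
#'   `FALSE`, hemispherical end caps (capsule) when `TRUE`.
#' @param background_intensity baseline intensity (default 0).
#' @param noise_sd additive Gaussian noise SD (default 0, a clean phantom).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_size_um = 50,
                         tubes = list(), background_intensity = 0,
                         noise_sd = 0, seed = 1) {
  stopifnot(length(shape) == 3L, all(shape >= 1), voxel_size_um > 0,
            noise_sd >= 0)
  tubes <- lapply(tubes, function(tb) {
    stopifnot(length(tb$from) == 3L, length(tb$to) == 3L, tb$radius_um > 0)
    if (is.null(tb$intensity)) tb$intensity <- 100
    if (is.null(tb$capped)) tb$capped <- FALSE
    tb
  })
  structure(list(shape = as.integer(shape), voxel_size_um = voxel_size_um,
                 tubes = tubes, background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a tubular vessel phantom with known analytic volume
#'
#' A voxel is tube-positive when its center lies within the tube radius of
#' the axis: for flat-ended tubes the center's axial projection must also
#' fall between the endpoints; capped tubes accept the hemispherical regions
#' beyond the ends. The analytic volume per tube is `pi r^2 L` plus
#' `4/3 pi r^3` when capped; tubes are assumed disjoint (volumes add).
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (an [angio_volume()]) and
#'   `analytic_volume_mm3`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  vox_um <- spec$voxel_size_um
  arr <- array(spec$background_intensity, dim = d)
  analytic <- 0
  if (length(spec$tubes)) {
    cx <- rep(seq_len(d[1L]), times = d[2L] * d[3L])
    cy <- rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L])
    cz <- rep(seq_len(d[3L]), each = d[1L] * d[2L])
    for (tb in spec$tubes) {
      r_vox <- tb$radius_um / vox_um
      a <- tb$from; b <- tb$to
      v <- b - a
      L_vox <- sqrt(sum(v^2))
      if (L_vox == 0) stop("tube of zero length")
      u <- v / L_vox
      # containment: capsule bounding box (exact for axis-aligned tubes)
      lo <- pmin(a, b) - r_vox * (1 - abs(u)) - (if (tb$capped) r_vox * abs(u) else 0)
      hi <- pmax(a, b) + r_vox * (1 - abs(u)) + (if (tb$capped) r_vox * abs(u) else 0)
      if (any(lo < 0.5 - 1e-9) || any(hi > d + 0.5 + 1e-9)) {
        stop("tube exits volume bounds")
      }
      wx <- cx - a[1L]; wy <- cy - a[2L]; wz <- cz - a[3L]
      t <- wx * u[1L] + wy * u[2L] + wz * u[3L]
      if (tb$capped) {
        tc <- pmin(pmax(t, 0), L_vox)
        d2 <- (wx - tc * u[1L])^2 + (wy - tc * u[2L])^2 + (wz - tc * u[3L])^2
        inside <- d2 <= r_vox^2 + 1e-12
      } else {
        d2 <- (wx - t * u[1L])^2 + (wy - t * u[2L])^2 + (wz - t * u[3L])^2
        inside <- t >= -1e-12 & t <= L_vox + 1e-12 & d2 <= r_vox^2 + 1e-12
      }
      arr[inside] <- pmax(arr[inside], tb$intensity)
      r_mm <- tb$radius_um / 1000
      L_mm <- L_vox * vox_um / 1000
      analytic <- analytic + pi * r_mm^2 * L_mm +
        (if (tb$capped) 4 / 3 * pi * r_mm^3 else 0)
    }
  }
  if (spec$noise_sd > 0) {
    arr <- .with_seed(spec$seed,
                      arr + array(stats::rnorm(length(arr), 0, spec$noise_sd),
                                  dim = d))
  }
  list(volume = angio_volume(arr, voxel_size_um = vox_um,
                             volume_id = sprintf("phantom_seed%d", spec$seed)),
       analytic_volume_mm3 = analytic)
}

#' Specification for a synthetic survival cohort
#'
#' Censored exponential survival with a cure fraction: each subject is cured
#' with probability `cure_fraction` (censored alive at the end of study);
#' otherwise its death time is exponential with the stated median, censored
#' at the end of study if it exceeds it.
#'
#' @param n_per_group subjects per group.
#' @param groups list of `list(name, median_days, cure_fraction)`.
#' @param end_of_study_day final follow-up day (default 100, a conventional
#'   rechallenge/endpoint day).
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10,
                        groups = list(
                          list(name = "control", median_days = 22,
                               cure_fraction = 0),
                          list(name = "treated", median_days = 30,
                               cure_fraction = 0.25)),
                        end_of_study_day = 100, seed = 1) {
  stopifnot(n_per_group >= 1, end_of_study_day > 0, length(groups) >= 1)
  for (g in groups) {
    stopifnot(!is.null(g$name), g$median_days > 0,
              g$cure_fraction >= 0, g$cure_fraction < 1)
  }
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 end_of_study_day = end_of_study_day, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic survival cohort
#'
#' @param spec a [cohort_spec()].
#' @return A [survival_cohort()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    recs <- lapply(spec$groups, function(g) {
      n <- spec$n_per_group
      cured <- stats::runif(n) < g$cure_fraction
      t <- stats::rexp(n, rate = log(2) / g$median_days)
      time <- ifelse(cured, spec$end_of_study_day,
                     pmin(t, spec$end_of_study_day))
      event <- ifelse(cured | t >= spec$end_of_study_day, 0L, 1L)
      data.frame(subject_id = sprintf("%s_%03d", g$name, seq_len(n)),
                 group = g$name, time_days = time, event = event)
    })
    survival_cohort(do.call(rbind, recs))
  })
}

#' Match detected cells to ground-truth cells
#'
#' Greedy nearest-first one-to-one matching of detected centroids to truth
#' centroids within a tolerance radius, as used to score segmentation
#' against generator ground truth.
#'
#' @param truth,found `cell_set` objects (or data.frames with `row`/`col`).
#' @param tol_px maximum centroid distance for a match, in pixels.
#' @return List with `n_truth`, `n_found`, `true_positive`, `precision`,
#'   `recall` and `centroid_errors_px` (per matched pair). With no truth and
#'   no detections, precision and recall are 1 (vacuously correct).
#' @export
match_cells <- function(truth, found, tol_px = 3) {
  get_df <- function(x) if (inherits(x, "cell_set")) x$cells else x
  tr <- get_df(truth); fo <- get_df(found)
  nt <- nrow(tr); nf <- nrow(fo)
  if (nt == 0L || nf == 0L) {
    return(list(n_truth = nt, n_found = nf, true_positive = 0L,
                precision = if (nf == 0L) 1 else 0,
                recall = if (nt == 0L) 1 else 0,
                centroid_errors_px = numeric()))
  }
  d2 <- outer(tr$row, fo$row, "-")^2 + outer(tr$col, fo$col, "-")^2
  used <- rep(FALSE, nf)
  errs <- numeric(0)
  tp <- 0L
  for (i in order(apply(d2, 1L, min))) {
    cand <- ifelse(used, Inf, d2[i, ])
    j <- which.min(cand)
    if (is.finite(cand[j]) && cand[j] <= tol_px^2) {
      used[j] <- TRUE
      tp <- tp + 1L
      errs <- c(errs, sqrt(cand[j]))
    }
  }
  list(n_truth = nt, n_found = nf, true_positive = tp,
       precision = tp / nf, recall = tp / nt,
       centroid_errors_px = errs)
}
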