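# Independent brute-force oracles used to validate the implementations.
# These deliberately use the slowest, most literal formulation of each
# definition and share no code with the package internals.

# exhaustive nearest-positive-pixel distance for continuous centroids;
# containment rule: 0 when the centroid's containing pixel is positive
oracle_nearest_distance <- function(rows, cols, mask) {
  H <- nrow(mask); W <- ncol(mask)
  pos <- which(mask, arr.ind = TRUE)
  out <- numeric(length(rows))
  for (i in seq_along(rows)) {
    cr <- min(max(floor(rows[i] + 0.5), 1), H)
    cc <- min(max(floor(cols[i] + 0.5), 1), W)
    if (mask[cr, cc]) {
      out[i] <- 0
    } else {
      out[i] <- sqrt(min((pos[, 1] - rows[i])^2 + (pos[, 2] - cols[i])^2))
    }
  }
  out
}

# BFS flood-fill connected components, 8-connectivity
oracle_label8 <- function(mask) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# literal double-loop grid enumeration
oracle_grid_occupancy <- function(rows, cols, mask, H, W, side, mode,
                                  pixel_fraction = 0.5) {
  gr <- ceiling(H / side); gc <- ceiling(W / side)
  n_pos <- 0L
  for (gi in seq_len(gr)) for (gj in seq_len(gc)) {
    r1 <- (gi - 1) * side + 1; r2 <- min(gi * side, H)
    c1 <- (gj - 1) * side + 1; c2 <- min(gj * side, W)
    hit_cent <- FALSE
    if (length(rows)) {
      pr <- pmin(pmax(floor(rows + 0.5), 1), H)
      pc <- pmin(pmax(floor(cols + 0.5), 1), W)
      hit_cent <- any(pr >= r1 & pr <= r2 & pc >= c1 & pc <= c2)
    }
    hit_pix <- FALSE
    if (!is.null(mask)) {
      sub <- mask[r1:r2, c1:c2, drop = FALSE]
      hit_pix <- mean(sub) >= pixel_fraction
    }
    hit <- switch(mode, centroid = hit_cent, pixel_fraction = hit_pix,
                  either = hit_cent || hit_pix)
    if (hit) n_pos <- n_pos + 1L
  }
  list(n_grids = gr * gc, n_positive = n_pos)
}

# literal product-limit estimator over explicit risk sets
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    t <- ts[i]
    n_t <- sum(time >= t)
    d_t <- sum(time == t & event == 1)
    s <- s * (1 - d_t / n_t)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# two-group log-rank by explicit O/E/V tabulation over event times
oracle_logrank_chi2 <- function(time, event, grp) {
  stopifnot(length(unique(grp)) == 2)
  g1 <- grp == unique(grp)[1]
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# textbook one-way ANOVA sums of squares
oracle_anova_F <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  k <- length(groups); n <- length(y)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# small random binary mask with at least one positive pixel
random_mask <- function(H, W, p = 0.05) {
  m <- matrix(runif(H * W) < p, H, W)
  if (!any(m)) m[sample(H * W, 1)] <- TRUE
  m
}

# wrap centroid coordinates as a minimal cell_set
as_cell_set <- function(rows, cols, shape, channel = "CD3") {
  structure(list(channel = channel,
                 cells = data.frame(label_id = seq_along(rows),
                                    row = rows, col = cols,
                                    area_px = rep(NA_real_, length(rows))),
                 source_field_id = "test", params = NULL,
                 field_shape = shape),
            class = "cell_set")
}

# flat constant-intensity field helper
const_field <- function(value, H = 32, W = 32, channel = "CD3",
                        pixel_scale = 1.98) {
  ch <- list(matrix(value, H, W))
  names(ch) <- channel
  fluorescence_field(ch, pixel_scale = pixel_scale, field_id = "const")
}
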