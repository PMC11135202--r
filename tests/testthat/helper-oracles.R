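# Independent oracles and fixture builders shared across test files.

# Brute-force maximum Feret diameter: max distance over ALL foreground
# pixel-center pairs (not just hull/boundary points).
brute_max_feret <- function(region, pitch) {
  idx <- which(region != 0, arr.ind = TRUE) * pitch
  if (nrow(idx) < 2) return(0)
  d2 <- outer(idx[, 1], idx[, 1], "-")^2 + outer(idx[, 2], idx[, 2], "-")^2
  sqrt(max(d2))
}

# Rotation-scan minimum Feret width: minimum over projection directions
# (0.5 degree steps) of the foreground pixel-center projection span.
scan_min_feret <- function(region, pitch, step_deg = 0.5) {
  idx <- which(region != 0, arr.ind = TRUE) * pitch
  if (nrow(idx) < 3) return(0)
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(th, function(a) {
    p <- idx[, 1] * cos(a) + idx[, 2] * sin(a)
    max(p) - min(p)
  }, 0.0)
  min(widths)
}

# Random connected blob on an n x n grid: a seeded random walk dilated by
# one pixel (guaranteed 4-connected).
random_blob <- function(seed, n = 30, walk = 50) {
  set.seed(seed)
  g <- matrix(0L, n, n)
  pos <- c(n %/% 2, n %/% 2)
  g[pos[1], pos[2]] <- 1L
  moves <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1), 4, 2, byrow = TRUE)
  for (i in seq_len(walk)) {
    pos <- pmin(pmax(pos + moves[sample(4, 1), ], 2), n - 1)
    g[pos[1], pos[2]] <- 1L
  }
  # plus-shaped dilation keeps 4-connectivity
  d <- g
  d[-1, ] <- pmax(d[-1, ], g[-n, ])
  d[-n, ] <- pmax(d[-n, ], g[-1, ])
  d[, -1] <- pmax(d[, -1], g[, -n])
  d[, -n] <- pmax(d[, -n], g[, -1])
  d
}

# Rasterized disc / ellipse fixtures (pixel-center inside test, slight
# center offset to avoid pixel centers exactly on the boundary).
raster_ellipse <- function(a, b, pitch, off = c(0.137, 0.211)) {
  n <- ceiling((max(a, b) + 2 * pitch) / pitch)
  ctr <- n + 1
  xy <- (seq_len(2 * n + 1) - ctr) * pitch
  fx <- outer((xy - off[1])^2 / a^2, (xy - off[2])^2 / b^2, "+")
  matrix(as.integer(fx < 1), 2 * n + 1, 2 * n + 1)
}

# Synthetic centerline trace with prescribed diameters (and areas), for
# metrics tests that do not need real tracking.
synthetic_trace <- function(diams, areas = pi * (diams / 2)^2,
                            step_mm = 1) {
  steps <- lapply(seq_along(diams), function(i) {
    list(index = i, center = c(0, 0, i * step_mm),
         frame = make_frame(c(0, 0, i * step_mm), c(0, 0, 1)),
         area = areas[i], max_diameter = diams[i],
         min_diameter = diams[i] * 0.9,
         arc_length = (i - 1) * step_mm)
  })
  structure(list(steps = steps, status = "completed",
                 config = tracking_config(), step_mm = step_mm,
                 pitch_mm = 0.5),
            class = "centerline_trace")
}

# ANOVA-decomposition ICC(2,1) oracle via stats::aov mean squares.
aov_icc_oracle <- function(auto, ref) {
  n <- length(auto)
  dat <- data.frame(y = c(auto, ref),
                    subj = factor(rep(seq_len(n), 2)),
                    rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = dat))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# Distance diagnostics of a tracked trace against analytic phantom truth,
# restricted to the truth's valid arc-length range.
trace_vs_truth <- function(trace, truth, ds = 0.25) {
  d <- profile_data_frame(trace)
  cl <- truth_centerline(truth, ds)
  ctr <- as.matrix(d[, c("center_x_mm", "center_y_mm", "center_z_mm")])
  nearest <- vapply(seq_len(nrow(ctr)), function(i) {
    d2 <- (cl$x - ctr[i, 1])^2 + (cl$y - ctr[i, 2])^2 + (cl$z - ctr[i, 3])^2
    j <- which.min(d2)
    c(sqrt(d2[j]), cl$s[j])
  }, numeric(2))
  valid <- nearest[2, ] >= truth$valid_range[1] &
    nearest[2, ] <= truth$valid_range[2]
  list(profile = d, dist = nearest[1, ], s = nearest[2, ], valid = valid,
       rmse = sqrt(mean(nearest[1, valid]^2)))
}

# Binary STL writer for fixtures (the package reader supports both forms).
write_stl_binary <- function(vertices, faces, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(faces)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(faces))) {
    v <- vertices[faces[i, ], , drop = FALSE]
    writeBin(as.numeric(c(0, 0, 0, t(v))), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}
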