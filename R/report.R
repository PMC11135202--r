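#' Render the diameter-versus-arc-length profile
#'
#' Plots the maximal diameter against cumulative arc length for every step.
#' Spike-flagged steps are drawn as open symbols, the (spike-excluded)
#' peak is annotated, and an optional cursor marks one step -- the format
#' a reviewer uses to pick measurement locations.
#'
#' @param trace a [centerline_trace][track_centerline].
#' @param path output PNG path; `NULL` draws on the current device.
#' @param cursor_step optional step index to mark.
#' @param width,height,res PNG device geometry.
#' @return `path` (or `NULL`), invisibly.
#' @export
render_profile <- function(trace, path = NULL, cursor_step = NULL,
                           width = 800, height = 500, res = 96) {
  if (length(trace$steps) == 0)
    atk_error("empty trace", "aortrack_empty_trace")
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height, res = res)
    on.exit(grDevices::dev.off())
  }
  draw_profile_panel(trace, cursor_step)
  invisible(path)
}

draw_profile_panel <- function(trace, cursor_step = NULL) {
  arc <- vapply(trace$steps, `[[`, 0.0, "arc_length")
  d <- vapply(trace$steps, `[[`, 0.0, "max_diameter")
  flags <- spike_filter(trace)
  graphics::plot(arc, d, type = "l", col = "grey40",
                 xlab = "arc length from diaphragm (mm)",
                 ylab = "maximal diameter (mm)",
                 main = sprintf("diameter profile (status: %s)", trace$status))
  graphics::points(arc[!flags], d[!flags], pch = 16, cex = 0.5, col = "grey20")
  if (any(flags))
    graphics::points(arc[flags], d[flags], pch = 1, cex = 0.8, col = "orange")
  if (!all(flags)) {
    pk <- peak_diameter(trace)
    graphics::points(pk$arc_length_mm, pk$diameter_mm, pch = 17, col = "red3")
    graphics::text(pk$arc_length_mm, pk$diameter_mm,
                   sprintf(" peak %.2f mm", pk$diameter_mm),
                   adj = c(-0.05, 0.5), col = "red3", cex = 0.9)
  }
  if (!is.null(cursor_step)) {
    graphics::abline(v = arc[cursor_step], col = "red", lty = 2)
    graphics::points(arc[cursor_step], d[cursor_step], pch = 3, col = "red",
                     cex = 1.5, lwd = 2)
  }
}

#' Render a three-panel per-step review image
#'
#' Composite PNG for auditing one tracking step: (a) an orthographic
#' silhouette of the 3D mask with the centerline and a marker at the
#' current step, (b) the diameter profile with a cursor at the step's arc
#' length, and (c) the resampled oblique plane in grayscale with the
#' measured connected cross-section tinted red. By default the binarized
#' mask itself serves as the grayscale background of panel (c); a
#' co-registered intensity volume (same grid as the mask) may be supplied
#' to show the underlying image instead.
#'
#' @param mask the tracked [aorta_mask].
#' @param trace the [centerline_trace][track_centerline].
#' @param step_index which step to render (1-based).
#' @param path output PNG path.
#' @param image optional co-registered intensity [aorta_mask]-like object
#'   or 3D array on the same grid, used as panel (c) background.
#' @param width,height,res PNG device geometry.
#' @return `path`, invisibly.
#' @export
render_step <- function(mask, trace, step_index, path, image = NULL,
                        width = 1200, height = 420, res = 96) {
  ns <- length(trace$steps)
  if (ns == 0) atk_error("empty trace", "aortrack_empty_trace")
  if (step_index < 1 || step_index > ns)
    atk_error(sprintf("step_index %d outside 1..%d", step_index, ns),
              "aortrack_index_error")
  st <- trace$steps[[step_index]]
  grDevices::png(path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)

  # (a) orthographic silhouette along the anterior-posterior axis with
  # centerline overlay
  proj_axis <- setdiff(1:3, c(mask$is_axis,
                              if (mask$is_axis == 1) 2 else 1))[1]
  sil <- apply(mask$voxels, setdiff(1:3, proj_axis), max)
  ax_keep <- setdiff(1:3, proj_axis)
  xs <- (seq_len(dim(sil)[1]) - 1)
  ys <- (seq_len(dim(sil)[2]) - 1)
  # world coordinates of the kept axes (grid is axis-aligned up to spacing)
  wx <- voxel_to_world(mask, c(0, 0, 0))[ax_keep[1]] + xs * mask$spacing[ax_keep[1]]
  wy <- voxel_to_world(mask, c(0, 0, 0))[ax_keep[2]] + ys * mask$spacing[ax_keep[2]]
  graphics::image(wx, wy, sil, col = c("white", "grey70"),
                  xlab = sprintf("axis %d (mm)", ax_keep[1]),
                  ylab = sprintf("axis %d (mm)", ax_keep[2]),
                  main = sprintf("model + step %d", step_index),
                  useRaster = TRUE, asp = 1)
  ctr <- t(vapply(trace$steps, `[[`, numeric(3), "center"))
  graphics::lines(ctr[, ax_keep[1]], ctr[, ax_keep[2]], col = "steelblue")
  graphics::points(st$center[ax_keep[1]], st$center[ax_keep[2]],
                   pch = 19, col = "blue", cex = 1.4)

  # (b) profile with cursor
  draw_profile_panel(trace, cursor_step = step_index)

  # (c) oblique plane with cross-section overlay
  pitch <- trace$pitch_mm
  hf <- (nrow_frame_fov(st, trace))
  bg_src <- if (is.null(image)) mask else {
    if (inherits(image, "aorta_mask")) image
    else aorta_mask_like(mask, image)
  }
  bg <- sample_plane(bg_src, st$frame, half_fov = hf, pitch = pitch,
                     binary = FALSE)
  reg <- tryCatch(connected_region(sample_plane(mask, st$frame,
                                                half_fov = hf, pitch = pitch)),
                  aortrack_lost_lumen = function(e) NULL)
  ext <- (nrow(bg) - 1) / 2 * pitch
  graphics::image(seq(-ext, ext, length.out = nrow(bg)),
                  seq(-ext, ext, length.out = ncol(bg)),
                  bg, col = grDevices::gray.colors(64, 0, 1),
                  zlim = c(0, max(1, max(bg))),
                  xlab = "u (mm)", ylab = "v (mm)",
                  main = sprintf("cross-section, area %.1f mm^2", st$area),
                  useRaster = TRUE, asp = 1)
  if (!is.null(reg)) {
    ov <- reg
    ov[ov == 0] <- NA
    graphics::image(seq(-ext, ext, length.out = nrow(ov)),
                    seq(-ext, ext, length.out = ncol(ov)),
                    ov, col = grDevices::adjustcolor("red", 0.35),
                    add = TRUE, useRaster = TRUE)
  }
  invisible(path)
}

# field of view used when re-rendering a recorded step: generous bound from
# the recorded diameter, clamped like the tracker's
nrow_frame_fov <- function(step, trace) {
  cfg <- trace$config
  min(max(cfg$half_fov_factor * step$max_diameter / 2,
          cfg$half_fov_floor_mm), cfg$half_fov_max_mm)
}

aorta_mask_like <- function(mask, voxels) {
  m <- mask
  m$voxels <- array(as.double(voxels), dim(mask$voxels))
  m
}

#' Render every step of a trace to numbered PNG frames
#'
#' Writes `frame_0000.png`, `frame_0001.png`, ... (zero-padded, sortable)
#' into a directory, one composite [render_step] image per step.
#'
#' @param mask the tracked [aorta_mask].
#' @param trace the [centerline_trace][track_centerline].
#' @param dir output directory (created if needed).
#' @param every render every n-th step (1 = all).
#' @param ... passed to [render_step].
#' @return character vector of written paths, invisibly.
#' @export
render_all_steps <- function(mask, trace, dir, every = 1L, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- seq(1L, length(trace$steps), by = every)
  paths <- file.path(dir, sprintf("frame_%04d.png", idx - 1L))
  for (i in seq_along(idx))
    render_step(mask, trace, idx[i], paths[i], ...)
  invisible(paths)
}

#' Forest plot of per-site agreement
#'
#' Point estimates and confidence-interval whiskers of the ICC per
#' measurement site, the standard display for multi-site agreement
#' studies.
#'
#' @param tab data frame from [agreement_table].
#' @param path output PNG path; `NULL` draws on the current device.
#' @param width,height,res PNG device geometry.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_agreement_forest <- function(tab, path = NULL, width = 700,
                                  height = 400, res = 96) {
  if (nrow(tab) == 0)
    atk_error("empty agreement table", "aortrack_degenerate_input")
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height, res = res)
    on.exit(grDevices::dev.off())
  }
  n <- nrow(tab)
  y <- rev(seq_len(n))
  xlim <- range(c(0, 1, tab$ci_low, tab$ci_high), na.rm = TRUE)
  graphics::plot(tab$icc, y, xlim = xlim, ylim = c(0.5, n + 0.5),
                 pch = 15, yaxt = "n", xlab = "ICC(2,1)", ylab = "",
                 main = "automated vs reference agreement")
  graphics::axis(2, at = y, labels = tab$site, las = 1)
  graphics::segments(tab$ci_low, y, tab$ci_high, y)
  graphics::abline(v = 1, lty = 3, col = "grey50")
  invisible(path)
}
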