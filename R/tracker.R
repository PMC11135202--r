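#' Tracking configuration
#'
#' Tunable parameters of the centerline tracker. Defaults follow the
#' measurement procedure: steps of one smallest-voxel length, a +/-30
#' degree wobble cone searched coarse-to-fine (3 degrees, then 0.5
#' degrees), and a 10 mm^2 area floor below any clinically plausible aortic
#' cross-section so that segmentation spurs are not chased.
#'
#' @param step_mm step length in mm; `NULL` (default) means the smallest
#'   voxel dimension of the tracked mask.
#' @param wobble_max_deg half-angle of the search cone around the travel
#'   direction.
#' @param wobble_coarse_deg coarse grid spacing of the two tilt angles.
#' @param wobble_fine_deg fine grid spacing for local refinement around the
#'   coarse optimum.
#' @param max_steps hard iteration cap.
#' @param min_area_mm2 connected cross-sections smaller than this terminate
#'   tracking (and are required of the two initialization slices).
#' @param stall_window number of consecutive direction reversals that
#'   terminates with status `stalled`.
#' @param pitch_mm in-plane resampling pixel size; `NULL` means half the
#'   smallest voxel dimension.
#' @param half_fov_floor_mm,half_fov_factor,half_fov_max_mm the plane field
#'   of view half-width adapts to `half_fov_factor` times the previous
#'   step's maximal radius estimate, clamped to
#'   `[half_fov_floor_mm, half_fov_max_mm]`.
#' @param lookahead_mm when the extrapolated point leaves the mask, the
#'   tracker probes this far ahead along the travel direction; finding mask
#'   there means the lumen continues past an unsegmented pocket
#'   (`lost_lumen`) rather than having genuinely ended.
#' @param snap_px seed snap radius (pixels) for connected-region growth.
#' @param progress_min_frac,move_max_frac per-step sanity band on the
#'   re-centered step, as fractions of `step_mm`: forward progress below
#'   `progress_min_frac` or total center movement above `move_max_frac`
#'   ends tracking (end-of-lumen or degenerate geometry).
#' @return object of class `tracking_config`.
#' @export
tracking_config <- function(step_mm = NULL, wobble_max_deg = 30,
                            wobble_coarse_deg = 3, wobble_fine_deg = 0.5,
                            max_steps = 2000L, min_area_mm2 = 10,
                            stall_window = 5L, pitch_mm = NULL,
                            half_fov_floor_mm = 20, half_fov_factor = 3,
                            half_fov_max_mm = 60, lookahead_mm = 30,
                            snap_px = 5L, progress_min_frac = 0.2,
                            move_max_frac = 3) {
  if (!is.null(step_mm) && step_mm <= 0)
    atk_error("step_mm must be > 0", "aortrack_config_error")
  if (!(wobble_fine_deg > 0 && wobble_fine_deg <= wobble_coarse_deg &&
        wobble_coarse_deg <= wobble_max_deg))
    atk_error("need 0 < wobble_fine_deg <= wobble_coarse_deg <= wobble_max_deg",
              "aortrack_config_error")
  structure(list(step_mm = step_mm, wobble_max_deg = wobble_max_deg,
                 wobble_coarse_deg = wobble_coarse_deg,
                 wobble_fine_deg = wobble_fine_deg,
                 max_steps = as.integer(max_steps),
                 min_area_mm2 = min_area_mm2,
                 stall_window = as.integer(stall_window),
                 pitch_mm = pitch_mm,
                 half_fov_floor_mm = half_fov_floor_mm,
                 half_fov_factor = half_fov_factor,
                 half_fov_max_mm = half_fov_max_mm,
                 lookahead_mm = lookahead_mm,
                 snap_px = as.integer(snap_px),
                 progress_min_frac = progress_min_frac,
                 move_max_frac = move_max_frac),
            class = "tracking_config")
}

#' @export
print.tracking_config <- function(x, ...) {
  cat("<tracking_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(x[[nm]])) "(from mask spacing)"
                else format(x[[nm]])))
  invisible(x)
}

# label 4-connected components of a binary matrix; returns the largest
# component's mask and pixel count
largest_component <- function(grid) {
  g <- matrix(as.integer(grid != 0), nrow(grid), ncol(grid))
  best <- NULL; best_n <- 0L
  repeat {
    idx <- which(g != 0, arr.ind = TRUE)
    if (nrow(idx) == 0) break
    res <- cpp_flood_fill(g, idx[1, 1] - 1L, idx[1, 2] - 1L, 0L)
    if (res$count > best_n) { best <- res$region; best_n <- res$count }
    g[res$region != 0] <- 0L
  }
  list(region = best, count = best_n)
}

#' Initialize tracking at the inferior end of the mask
#'
#' Scans straight-axial slices from the inferior end of the volume and
#' takes the first two adjacent slices whose largest in-slice connected
#' component has area of at least `min_area_mm2`. The component centers of
#' mass of those two slices seed the centerline and its direction of
#' travel. Assumes the vessel runs nearly vertically (parallel to the
#' inferior-superior axis) at its inferior end, which holds for the
#' descending aorta at the diaphragm.
#'
#' @param mask an [aorta_mask].
#' @param min_area_mm2 minimum qualifying in-slice area.
#' @return list with `p_inferior` and `p_superior`, two world points (mm).
#' @export
initialize_tracker <- function(mask, min_area_mm2 = 10) {
  ax <- mask$is_axis
  nk <- dim(mask$voxels)[ax]
  others <- setdiff(1:3, ax)
  pix_area <- prod(mask$spacing[others])
  order_k <- if (mask$is_dir > 0) seq_len(nk) else rev(seq_len(nk))
  slice_of <- function(k) {
    idx <- list(quote(expr =), quote(expr =), quote(expr =))
    idx[[ax]] <- k
    do.call(`[`, c(list(mask$voxels), idx, list(drop = TRUE)))
  }
  com_of <- function(k) {
    sl <- slice_of(k)
    lc <- largest_component(sl)
    if (lc$count * pix_area < min_area_mm2) return(NULL)
    idx <- which(lc$region != 0, arr.ind = TRUE)
    ijk <- numeric(3)
    ijk[others] <- colMeans(idx) - 1  # to 0-based
    ijk[ax] <- k - 1
    voxel_to_world(mask, ijk)
  }
  for (pos in seq_len(nk - 1)) {
    k1 <- order_k[pos]; k2 <- order_k[pos + 1]
    p1 <- com_of(k1)
    if (is.null(p1)) next
    p2 <- com_of(k2)
    if (is.null(p2)) next
    return(list(p_inferior = p1, p_superior = p2))
  }
  atk_error("no adjacent axial slice pair with sufficient foreground area",
            "aortrack_init_error")
}

#' Extrapolate the next centerline point
#'
#' Takes a step of `step_mm` from `p_curr` in the direction
#' `p_curr - p_prev`.
#'
#' @param p_prev,p_curr the two preceding centerline points (world mm).
#' @param step_mm step length in mm.
#' @return world point (mm).
#' @export
extrapolate_point <- function(p_prev, p_curr, step_mm) {
  d <- p_curr - p_prev
  n <- sqrt(sum(d^2))
  if (n < 1e-9)
    atk_error("coincident centerline points", "aortrack_geometry_error")
  p_curr + step_mm * d / n
}

# candidate tilt pairs within the spherical cap, ordered deterministically
tilt_grid <- function(center_a, center_b, half_range, step, max_deg) {
  a <- seq(center_a - half_range, center_a + half_range, by = step)
  b <- seq(center_b - half_range, center_b + half_range, by = step)
  g <- expand.grid(a = a, b = b)
  # total tilt of sequential rotations by a then b from the base normal
  tilt <- acos(pmin(1, abs(cos(g$a * pi / 180) * cos(g$b * pi / 180)))) * 180 / pi
  g <- g[tilt <= max_deg + 1e-9, , drop = FALSE]
  g$tilt <- tilt[tilt <= max_deg + 1e-9]
  g[order(g$tilt, g$a, g$b), , drop = FALSE]
}

#' Wobble: find the plane of minimal connected cross-sectional area
#'
#' Searches plane normals within a spherical cap of half-angle
#' `wobble_max_deg` around `base_normal` for the plane through `point`
#' whose 4-connected cross-section (seeded at `point`) has minimal area.
#' The normal is parameterized by two sequential tilts about the in-plane
#' axes of the base frame, searched on a coarse grid and then refined
#' locally on a fine grid. Ties are broken toward the smallest tilt from
#' `base_normal`, then lexicographically in the two tilt angles, making the
#' search fully deterministic.
#'
#' @param mask an [aorta_mask].
#' @param point plane origin (world mm).
#' @param base_normal direction of travel the cone is centered on.
#' @param config a [tracking_config].
#' @param half_fov,pitch plane sampling geometry (mm); defaults follow the
#'   config/mask.
#' @return list with `frame` (the minimizing [make_frame] plane),
#'   `area_mm2` (the minimized sub-pixel connected area),
#'   `pixel_area_mm2` (thresholded pixel count times `pitch^2`),
#'   `tilt_deg` (angle from `base_normal`) and the two tilt angles
#'   `a_deg`, `b_deg`.
#' @export
wobble <- function(mask, point, base_normal, config = tracking_config(),
                   half_fov = config$half_fov_floor_mm,
                   pitch = if (is.null(config$pitch_mm))
                     min(mask$spacing) / 2 else config$pitch_mm) {
  base <- make_frame(point, base_normal)
  dm <- as.integer(dim(mask$voxels))
  eval_candidate <- function(a, b, pt) {
    nrm <- rotate_about(base$normal, base$u_axis, a * pi / 180)
    nrm <- rotate_about(nrm, base$v_axis, b * pi / 180)
    fr <- make_frame(point, nrm)
    res <- cpp_plane_component_count(mask$voxels, dm, mask$invaffine,
                                     fr$origin, fr$u_axis, fr$v_axis,
                                     pt, as.integer(ceiling(half_fov / pt)),
                                     config$snap_px,
                                     max(1L, as.integer(ceiling(min(mask$spacing) / pt))))
    list(count = res[1], soft = res[2] * pt^2, frame = fr)
  }
  # the objective is the sub-pixel (interpolated) area of the connected
  # component, which varies smoothly with orientation; the thresholded
  # pixel count is too coarsely quantized to resolve sub-degree tilts
  search <- function(grid, incumbent, pt) {
    best <- incumbent
    for (i in seq_len(nrow(grid))) {
      cand <- eval_candidate(grid$a[i], grid$b[i], pt)
      if (cand$count <= 0) next
      key <- c(cand$soft, grid$tilt[i], grid$a[i], grid$b[i])
      if (is.null(best) || lex_less(key, best$key))
        best <- list(key = key, soft = cand$soft, count = cand$count,
                     frame = cand$frame, a = grid$a[i], b = grid$b[i],
                     tilt = grid$tilt[i])
    }
    best
  }
  # coarse stage at doubled pitch (multiresolution), fine stage at full
  # pitch around the coarse argmin, with the argmin re-evaluated at full
  # pitch so the two stages compare like with like
  coarse <- tilt_grid(0, 0, config$wobble_max_deg, config$wobble_coarse_deg,
                      config$wobble_max_deg)
  best <- search(coarse, NULL, 2 * pitch)
  if (is.null(best))
    atk_error("no lumen found at any wobble candidate", "aortrack_lost_lumen")
  seed <- eval_candidate(best$a, best$b, pitch)
  best <- if (seed$count > 0)
    list(key = c(seed$soft, best$tilt, best$a, best$b), soft = seed$soft,
         count = seed$count, frame = seed$frame, a = best$a, b = best$b,
         tilt = best$tilt)
  else NULL
  fine <- tilt_grid(if (is.null(best)) 0 else best$a,
                    if (is.null(best)) 0 else best$b,
                    config$wobble_coarse_deg / 2 + config$wobble_fine_deg,
                    config$wobble_fine_deg, config$wobble_max_deg)
  best <- search(fine, best, pitch)
  if (is.null(best))
    atk_error("no lumen found at any wobble candidate", "aortrack_lost_lumen")
  list(frame = best$frame, area_mm2 = best$soft,
       pixel_area_mm2 = best$count * pitch^2,
       tilt_deg = best$tilt, a_deg = best$a, b_deg = best$b)
}

# The inferior edge of a segmentation is where the imaging volume cut the
# vessel, not where the vessel ends. Oblique measurement planes near that
# open face are truncated by it, which biases the minimal-area search and
# the center of mass. Replicating the most-inferior foreground slice
# downward (a virtual continuation of the vessel through the diaphragm)
# removes the artifact; tracking starts inside the extension and steps are
# recorded only after the centerline crosses the original boundary.
extend_mask_inferior <- function(mask, extend_mm = 25) {
  ax <- mask$is_axis
  d <- dim(mask$voxels)
  K <- as.integer(ceiling(extend_mm / mask$spacing[ax]))
  idx_all <- function(k) {
    ix <- list(quote(expr =), quote(expr =), quote(expr =))
    ix[[ax]] <- k
    ix
  }
  get_slice <- function(k)
    do.call(`[`, c(list(mask$voxels), idx_all(k), list(drop = FALSE)))
  nk <- d[ax]
  order_k <- if (mask$is_dir > 0) seq_len(nk) else rev(seq_len(nk))
  k0 <- NA_integer_
  for (k in order_k) if (any(get_slice(k) != 0)) { k0 <- k; break }
  if (is.na(k0))
    atk_error("mask is empty", "aortrack_empty_mask")
  # world IS coordinate of the original inferior foreground boundary
  ijk0 <- c(0, 0, 0); ijk0[ax] <- k0 - 1
  z0 <- voxel_to_world(mask, ijk0)[3]
  nd <- d; nd[ax] <- d[ax] + K
  vox <- array(0, nd)
  # copy original volume into the superior part (is_dir > 0) or keep at
  # the low-index side (is_dir < 0)
  src <- lapply(d, seq_len)
  dst <- src
  if (mask$is_dir > 0) dst[[ax]] <- src[[ax]] + K
  vox <- do.call(`[<-`, c(list(vox), dst, list(mask$voxels)))
  sl <- get_slice(k0)
  fill_ks <- if (mask$is_dir > 0) seq_len(K + k0 - 1) else
    (d[ax] - (nk - k0)):nd[ax]
  for (k in fill_ks) {
    ix <- lapply(nd, seq_len)
    ix[[ax]] <- k
    vox <- do.call(`[<-`, c(list(vox), ix, list(sl)))
  }
  affine <- mask$affine
  if (mask$is_dir > 0)
    affine[1:3, 4] <- affine[1:3, 4] - K * affine[1:3, ax]
  list(mask = aorta_mask(vox, affine = affine, is_axis = ax,
                         is_dir = mask$is_dir),
       z0 = z0)
}

lex_less <- function(x, y) {
  for (i in seq_along(x)) {
    if (x[i] < y[i] - 1e-12) return(TRUE)
    if (x[i] > y[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' Track the vessel centerline and diameter profile
#'
#' Runs the full stepwise measurement loop: initialize at the inferior end,
#' then repeatedly extrapolate one step along the previous travel
#' direction, wobble to the minimal-area plane, restrict to the connected
#' cross-section at the current lumen, re-center on its center of mass, and
#' record area and maximal/minimal Feret diameters. Terminates with an
#' explicit status:
#' \describe{
#'   \item{completed}{the extrapolated point left the mask at a healthy
#'     lumen with no mask ahead -- the vessel ended.}
#'   \item{branch_exit_suspected}{as above, but the area profile shows a
#'     sustained collapse typical of escaping into a side branch (see
#'     [detect_branch_exit]); advisory re-labeling, no correction is
#'     attempted.}
#'   \item{exited_mask}{left the mask while the recent lumen was already
#'     below the area floor.}
#'   \item{lost_lumen}{no lumen found near the seed, or mask present ahead
#'     of the exit point (an unsegmented pocket interrupted tracking).}
#'   \item{stalled}{travel direction reversed for `stall_window`
#'     consecutive steps (typical of cavitated lumens).}
#'   \item{max_steps}{iteration cap reached.}
#' }
#' The tracker is fully deterministic: identical mask and configuration
#' yield identical traces.
#'
#' @param mask an [aorta_mask].
#' @param config a [tracking_config].
#' @param verbose print one line per step.
#' @return object of class `centerline_trace`: list with `steps` (each a
#'   list with `index`, `center`, `frame`, `area`, `max_diameter`,
#'   `min_diameter`, `arc_length`), terminal `status`, and `config`.
#' @export
track_centerline <- function(mask, config = tracking_config(),
                             verbose = FALSE) {
  step_mm <- if (is.null(config$step_mm)) min(mask$spacing) else config$step_mm
  pitch <- if (is.null(config$pitch_mm)) min(mask$spacing) / 2 else config$pitch_mm
  # initialize on the original mask (at the true inferior boundary), but
  # sample all measurement planes on the inferior-extended mask so planes
  # near the start are not truncated by the volume edge
  init <- initialize_tracker(mask, config$min_area_mm2)
  ext <- extend_mask_inferior(mask)
  z0 <- ext$z0
  mask <- ext$mask
  p_prev <- init$p_inferior
  p_curr <- init$p_superior
  recording <- FALSE
  dir_prev <- unit3(p_curr - p_prev)
  half_fov <- config$half_fov_floor_mm
  steps <- list()
  arc <- 0
  reversals <- 0L
  status <- "max_steps"

  # Distinguish the three ways forward progress can end, by probing along
  # the travel direction ahead of the extrapolated point:
  #   - lumen continues with no gap -> the tracker is stuck (stalled);
  #   - a gap followed by more mask -> an unsegmented pocket (lost_lumen);
  #   - no mask beyond the gap -> the vessel genuinely ended (completed,
  #     or exited_mask when the recent lumen was already degenerate).
  # Direction used for look-ahead probing: displacement over the last few
  # recorded centers. The instantaneous direction at a failure site can be
  # corrupted by the very event being classified (e.g. a cavity yanking
  # the center of mass sideways), while the windowed direction still
  # reflects the vessel's course.
  probe_direction <- function(dir) {
    n <- length(steps)
    if (n < 3) return(dir)
    w <- min(10L, n - 1L)
    d <- steps[[n]]$center - steps[[n - w]]$center
    if (sqrt(sum(d^2)) < 1e-9) dir else unit3(d)
  }
  classify_exit <- function(p_next, dir) {
    healthy <- length(steps) > 0 &&
      steps[[length(steps)]]$area >= config$min_area_mm2
    dir <- probe_direction(dir)
    probes <- sweep(outer(seq(0, config$lookahead_mm, by = step_mm),
                          dir), 2, p_next, "+")
    s <- mask_sample(mask, probes)
    first_out <- which(s < 0.5)[1]
    if (is.na(first_out)) return("stalled")
    if (any(s[seq_along(s) > first_out] >= 0.5)) return("lost_lumen")
    if (healthy) "completed" else "exited_mask"
  }

  for (iter in seq_len(config$max_steps)) {
    p_next <- tryCatch(extrapolate_point(p_prev, p_curr, step_mm),
                       aortrack_geometry_error = function(e) NULL)
    if (is.null(p_next)) { status <- "stalled"; break }
    dir <- unit3(p_next - p_curr)
    if (mask_sample(mask, p_next) < 0.5) {
      status <- classify_exit(p_next, dir)
      break
    }
    w <- tryCatch(wobble(mask, p_next, dir, config, half_fov, pitch),
                  aortrack_lost_lumen = function(e) NULL)
    if (is.null(w)) { status <- "lost_lumen"; break }
    if (w$area_mm2 < config$min_area_mm2) {
      status <- classify_exit(p_next, dir)
      break
    }
    grid <- sample_plane(mask, w$frame, half_fov, pitch)
    reg <- tryCatch(connected_region(grid, snap = config$snap_px),
                    aortrack_lost_lumen = function(e) NULL)
    if (is.null(reg)) { status <- "lost_lumen"; break }
    centroid <- region_centroid(reg, w$frame, pitch)
    area <- sum(reg) * pitch^2
    maxd <- max_diameter(reg, pitch)
    mind <- min_diameter(reg, pitch)

    # step-progress guard: near the open end of a lumen the minimal-area
    # plane is an obliquely truncated cut whose center of mass regresses
    # along the travel direction. When the probe shows the lumen has
    # genuinely ended (or is interrupted), terminate; when it continues,
    # tolerate a bounded run of degenerate steps -- vessel junctions
    # produce elongated cross-sections that jolt the center of mass before
    # tracking settles again (possibly into a branch, the failure mode
    # this reproduces).
    move <- centroid - p_curr
    progress <- sum(move * dir)
    degenerate <- progress < config$progress_min_frac * step_mm ||
      sqrt(sum(move^2)) > config$move_max_frac * step_mm
    if (degenerate) {
      cls <- classify_exit(p_next, dir)
      if (cls != "stalled") { status <- cls; break }
    }
    d_new <- unit3(move)
    if (degenerate || sum(d_new * dir_prev) < 0) reversals <- reversals + 1L
    else reversals <- 0L

    # steps inside the virtual inferior extension are positioning only;
    # recording starts once the center crosses the original mask boundary
    if (!recording)
      recording <- centroid[3] >= z0  # world z is superior-positive
    if (recording) {
      if (length(steps) > 0)
        arc <- arc + sqrt(sum((centroid - steps[[length(steps)]]$center)^2))
      steps[[length(steps) + 1L]] <- list(
        index = length(steps) + 1L, center = centroid, frame = w$frame,
        area = area, max_diameter = maxd, min_diameter = mind,
        arc_length = arc)
      if (verbose)
        message(sprintf("step %4d  arc %7.2f mm  area %7.2f mm^2  maxd %6.2f mm  tilt %5.1f deg",
                        length(steps), arc, area, maxd, w$tilt_deg))
    }

    if (reversals >= config$stall_window) { status <- "stalled"; break }
    p_prev <- p_curr
    p_curr <- centroid
    dir_prev <- d_new
    half_fov <- min(max(config$half_fov_factor * maxd / 2,
                        config$half_fov_floor_mm), config$half_fov_max_mm)
  }

  trace <- structure(list(steps = steps, status = status, config = config,
                          step_mm = step_mm, pitch_mm = pitch),
                     class = "centerline_trace")
  if (status %in% c("completed", "exited_mask") &&
      detect_branch_exit(trace))
    trace$status <- "branch_exit_suspected"
  trace
}

#' @export
print.centerline_trace <- function(x, ...) {
  ns <- length(x$steps)
  cat(sprintf("<centerline_trace> %d steps, status '%s'\n", ns, x$status))
  if (ns > 0) {
    arc <- x$steps[[ns]]$arc_length
    dmax <- max(vapply(x$steps, `[[`, 0.0, "max_diameter"))
    cat(sprintf("  arc length %.1f mm; peak max diameter %.2f mm\n", arc, dmax))
  }
  invisible(x)
}

#' Flag a suspected exit into a side branch
#'
#' Advisory heuristic over the recorded area series: a trace is flagged
#' when the connected cross-sectional area collapses by more than 60%
#' within a 10-step window and never recovers afterwards -- the signature
#' of the tracker escaping the arch into a smaller vessel. No correction is
#' attempted; the flag only re-labels the terminal status.
#'
#' @param trace a [centerline_trace][track_centerline].
#' @param drop_frac area fraction under which a drop counts (default 0.4,
#'   i.e. a >60% drop).
#' @param window number of steps within which the drop must occur.
#' @param recover_frac recovery threshold as a fraction of the pre-drop
#'   area.
#' @return logical flag.
#' @export
detect_branch_exit <- function(trace, drop_frac = 0.4, window = 10L,
                               recover_frac = 0.6) {
  areas <- vapply(trace$steps, `[[`, 0.0, "area")
  n <- length(areas)
  if (n < window) return(FALSE)
  for (i in seq_len(n - 1)) {
    base <- stats::median(areas[max(1, i - window + 1):i])
    jmax <- min(n, i + window)
    drops <- which(areas[(i + 1):jmax] < drop_frac * base)
    if (length(drops) == 0) next
    j <- i + drops[1]
    if (max(areas[j:n]) < recover_frac * base) return(TRUE)
  }
  FALSE
}
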