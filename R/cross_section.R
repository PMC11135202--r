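#' Build an oriented measurement plane
#'
#' Constructs a deterministic right-handed orthonormal frame from a plane
#' origin and normal. The first in-plane axis is the normalized cross
#' product of the normal with the global coordinate axis along which the
#' normal has its smallest absolute component; the second is
#' `normal x u_axis`.
#'
#' @param origin world point (mm).
#' @param normal plane normal (any nonzero length; normalized internally).
#' @return object of class `plane_frame` with fields `origin`, `normal`,
#'   `u_axis`, `v_axis`.
#' @export
make_frame <- function(origin, normal) {
  if (sqrt(sum(normal^2)) < 1e-12)
    atk_error("plane normal must be nonzero", "aortrack_geometry_error")
  n <- unit3(as.double(normal))
  e <- diag(3)[, which.min(abs(n))]
  u <- unit3(cross3(n, e))
  v <- cross3(n, u)
  structure(list(origin = as.double(origin), normal = n,
                 u_axis = u, v_axis = v),
            class = "plane_frame")
}

#' @export
print.plane_frame <- function(x, ...) {
  cat(sprintf("<plane_frame> origin (%.2f, %.2f, %.2f) mm, normal (%.3f, %.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Resample a mask on an oblique plane
#'
#' The plane is sampled on a square grid of in-plane pixels of size `pitch`
#' centered on the frame origin; pixel (i, j) lies at
#' `origin + (i - c)*pitch*u_axis + (j - c)*pitch*v_axis` where `c` is the
#' center index. The mask is interpolated trilinearly; with
#' `binary = TRUE` values are thresholded at 0.5. Points outside the volume
#' sample as 0.
#'
#' @param mask an [aorta_mask]
#' @param frame a [make_frame] plane.
#' @param half_fov half field of view in mm (grid spans `2*half_fov`).
#' @param pitch in-plane pixel size in mm; defaults to half the smallest
#'   voxel dimension, keeping discretization error below clinical reporting
#'   precision.
#' @param binary return a 0/1 integer matrix (default) or the raw
#'   interpolated values.
#' @return matrix of size `(2n+1) x (2n+1)`, `n = ceiling(half_fov/pitch)`,
#'   with attributes `pitch` and `frame`.
#' @export
sample_plane <- function(mask, frame, half_fov = 20,
                         pitch = min(mask$spacing) / 2, binary = TRUE) {
  if (pitch <= 0) atk_error("pitch must be > 0", "aortrack_geometry_error")
  if (half_fov < pitch)
    atk_error("half_fov must be at least one pitch", "aortrack_geometry_error")
  n <- as.integer(ceiling(half_fov / pitch))
  g <- cpp_sample_plane(mask$voxels, as.integer(dim(mask$voxels)),
                        mask$invaffine, frame$origin, frame$u_axis,
                        frame$v_axis, pitch, n)
  if (binary) {
    g2 <- matrix(as.integer(g >= 0.5), nrow(g), ncol(g))
    attr(g2, "pitch") <- pitch
    attr(g2, "frame") <- frame
    g2
  } else {
    attr(g, "pitch") <- pitch
    attr(g, "frame") <- frame
    g
  }
}

#' Restrict a plane grid to one connected component
#'
#' Keeps only the 4-connected foreground component containing the seed
#' pixel; all other foreground is zeroed. This guards cross-sectional
#' measurements on planes that intersect the vessel more than once (e.g.
#' planes through the arch cutting both ascending and descending limbs).
#' A seed falling on background is snapped to the nearest foreground pixel
#' within `snap` pixels.
#'
#' @param grid 0/1 matrix, e.g. from [sample_plane].
#' @param seed_pixel integer (row, col), 1-based; defaults to the grid
#'   center.
#' @param snap snap radius in pixels.
#' @return 0/1 integer matrix of the same size containing one component;
#'   attributes of `grid` are preserved.
#' @export
connected_region <- function(grid,
                             seed_pixel = c((nrow(grid) + 1) %/% 2,
                                            (ncol(grid) + 1) %/% 2),
                             snap = 5L) {
  res <- cpp_flood_fill(matrix(as.integer(grid != 0), nrow(grid), ncol(grid)),
                        as.integer(seed_pixel[1]) - 1L,
                        as.integer(seed_pixel[2]) - 1L, as.integer(snap))
  if (!res$found)
    atk_error("no foreground near seed: lumen lost in plane",
              "aortrack_lost_lumen")
  out <- res$region
  attr(out, "pitch") <- attr(grid, "pitch")
  attr(out, "frame") <- attr(grid, "frame")
  out
}

# Centers (mm, in grid row/col coordinates) of foreground pixels that touch
# background or the grid edge through a 4-neighbor.
boundary_points <- function(region, pitch) {
  fg <- region != 0
  if (!any(fg)) return(matrix(0, 0, 2))
  pad <- matrix(FALSE, nrow(fg) + 2, ncol(fg) + 2)
  pad[2:(nrow(fg) + 1), 2:(ncol(fg) + 1)] <- fg
  core <- pad[2:(nrow(fg) + 1), 2:(ncol(fg) + 1)]
  nb <- pad[1:nrow(fg), 2:(ncol(fg) + 1)] &
        pad[3:(nrow(fg) + 2), 2:(ncol(fg) + 1)] &
        pad[2:(nrow(fg) + 1), 1:ncol(fg)] &
        pad[2:(nrow(fg) + 1), 3:(ncol(fg) + 2)]
  bd <- core & !nb
  idx <- which(bd, arr.ind = TRUE)
  idx * pitch
}

#' Maximal (Feret) diameter of a 2D region
#'
#' Largest Euclidean distance between centers of any two foreground pixels,
#' in mm. Computed over the convex hull of boundary-pixel centers, which is
#' exactly the all-pairs maximum because interior pixels cannot be hull
#' vertices. Measuring between pixel centers matches an inner-edge
#' measurement convention.
#'
#' @param region 0/1 matrix (single connected component).
#' @param pitch pixel size in mm.
#' @return diameter in mm (0 for a single pixel).
#' @export
max_diameter <- function(region, pitch) {
  pts <- boundary_points(region, pitch)
  if (nrow(pts) == 0)
    atk_error("empty region", "aortrack_empty_region")
  if (nrow(pts) == 1) return(0)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  d2 <- outer(hp[, 1], hp[, 1], "-")^2 + outer(hp[, 2], hp[, 2], "-")^2
  sqrt(max(d2))
}

#' Minimal Feret width of a 2D region
#'
#' Smallest distance between two parallel supporting lines of the region's
#' boundary-pixel centers, in mm. For a convex polygon the minimum width is
#' attained with one line flush to a polygon edge, so the rotating-calipers
#' reduction over convex-hull edges is exact.
#'
#' @inheritParams max_diameter
#' @return width in mm (0 for collinear regions).
#' @export
min_diameter <- function(region, pitch) {
  pts <- boundary_points(region, pitch)
  if (nrow(pts) == 0)
    atk_error("empty region", "aortrack_empty_region")
  if (nrow(pts) <= 2) return(0)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  if (m < 3) return(0)
  widths <- vapply(seq_len(m), function(i) {
    a <- hp[i, ]
    b <- hp[i %% m + 1, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len < 1e-12) return(Inf)
    # distance of all hull vertices from the line through a, b
    max(abs((hp[, 1] - a[1]) * e[2] - (hp[, 2] - a[2]) * e[1]) / len)
  }, 0.0)
  min(widths)
}

#' Center of mass of a plane region in world coordinates
#'
#' @param region 0/1 matrix from [connected_region].
#' @param frame the [make_frame] plane the region was sampled on.
#' @param pitch pixel size in mm.
#' @return world point (mm).
#' @export
region_centroid <- function(region, frame, pitch) {
  idx <- which(region != 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    atk_error("empty region", "aortrack_empty_region")
  c0 <- (dim(region) + 1) / 2   # grid center index (origin of the frame)
  du <- (mean(idx[, 1]) - c0[1]) * pitch
  dv <- (mean(idx[, 2]) - c0[2]) * pitch
  frame$origin + du * frame$u_axis + dv * frame$v_axis
}

#' Measure one oblique cross-section of a mask
#'
#' Convenience wrapper: resample the plane, keep the connected component at
#' the plane center, and measure area (pixel count times `pitch^2`),
#' maximal and minimal Feret diameters, and the world centroid.
#'
#' @inheritParams sample_plane
#' @param snap seed snap radius in pixels for [connected_region].
#' @return object of class `cross_section` with fields `grid`, `pitch`,
#'   `frame`, `area`, `max_diameter`, `min_diameter`, `centroid_world`.
#' @export
cross_section <- function(mask, frame, half_fov = 20,
                          pitch = min(mask$spacing) / 2, snap = 5L) {
  g <- sample_plane(mask, frame, half_fov, pitch)
  reg <- connected_region(g, snap = snap)
  structure(list(grid = reg, pitch = pitch, frame = frame,
                 area = sum(reg) * pitch^2,
                 max_diameter = max_diameter(reg, pitch),
                 min_diameter = min_diameter(reg, pitch),
                 centroid_world = region_centroid(reg, frame, pitch)),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> area %.1f mm^2, max diameter %.2f mm, min %.2f mm\n",
              x$area, x$max_diameter, x$min_diameter))
  invisible(x)
}
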