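#' Specify an analytic tube phantom
#'
#' Phantoms are solids of revolution-like tubes with exactly known
#' centerlines and diameter functions, voxelized at a given spacing. They
#' stand in for clinical segmentations in tests: straight and tilted
#' cylinders probe plane resampling and the wobble search, the candy-cane
#' reproduces arch topology (vertical descending limb, half-torus arch,
#' short ascending limb), the branched variant reproduces tracking escapes
#' into an arch vessel, and the cavitated tube reproduces unsegmented
#' pockets inside the lumen.
#'
#' Shape parameters (all mm, angles in degrees) and their defaults:
#' \describe{
#'   \item{straight_cylinder}{`radius` 10, `length` 80}
#'   \item{tilted_cylinder}{`radius` 10, `length` 80, `tilt_deg` 20 (axis
#'     tilted from the inferior-superior axis in the x-z plane)}
#'   \item{elliptical_tube}{`semi_major` 15, `semi_minor` 10, `length` 80}
#'   \item{torus_arch}{`major_radius` 40, `minor_radius` 12 (half torus)}
#'   \item{candy_cane}{`radius` 12, `arch_radius` 40, `descending_length`
#'     60, `ascending_length` 30, `isthmus_radius_factor` 1 (smooth taper
#'     of the trunk radius beyond `isthmus_arc_deg` 65; 1 = no taper)}
#'   \item{candy_cane_with_branch}{candy-cane parameters plus
#'     `branch_radius_factor` 0.4 (of the nominal trunk radius),
#'     `branch_length` 45, `branch_arc_deg` 65 (take-off position along
#'     the arch), `branch_angle_deg` 0 (angle between branch axis and the
#'     local direction of travel), `branch_offset_factor` 0 (radial offset
#'     of the branch origin from the trunk centerline, in trunk radii),
#'     and `isthmus_radius_factor` 0.55: the trunk tapers into the
#'     isthmus at the ostium, the configuration of congenital aortopathy
#'     in which trackers are captured by arch vessels}
#'   \item{cavitated_tube}{`radius` 10, `length` 80, `cavity_radius` 12,
#'     `cavity_offset` c(0,0,0) (cavity center relative to the tube
#'     midpoint)}
#' }
#'
#' @param shape one of the seven shapes above.
#' @param ... shape parameters overriding the defaults.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param noise boundary jitter amplitude in voxels: the implicit-surface
#'   threshold is perturbed per voxel by seeded uniform noise, emulating
#'   rough manual segmentation; 0 disables.
#' @param seed integer seed for the jitter.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("straight_cylinder", "tilted_cylinder",
                                   "elliptical_tube", "torus_arch",
                                   "candy_cane", "candy_cane_with_branch",
                                   "cavitated_tube"),
                         ..., spacing = 1, noise = 0, seed = 1L) {
  shape <- match.arg(shape)
  sp <- as.double(spacing)
  if (length(sp) == 1L) sp <- rep(sp, 3)
  if (length(sp) != 3L || any(sp <= 0))
    atk_error("spacing must be 1 or 3 positive mm values", "aortrack_spec_error")
  defaults <- switch(shape,
    straight_cylinder = list(radius = 10, length = 80),
    tilted_cylinder = list(radius = 10, length = 80, tilt_deg = 20),
    elliptical_tube = list(semi_major = 15, semi_minor = 10, length = 80),
    torus_arch = list(major_radius = 40, minor_radius = 12),
    candy_cane = list(radius = 12, arch_radius = 40,
                      descending_length = 60, ascending_length = 30,
                      isthmus_radius_factor = 1, isthmus_arc_deg = 65),
    candy_cane_with_branch = list(radius = 12, arch_radius = 40,
                                  descending_length = 60,
                                  ascending_length = 30,
                                  branch_radius_factor = 0.4,
                                  branch_length = 45,
                                  branch_arc_deg = 65,
                                  branch_angle_deg = 0,
                                  branch_offset_factor = 0,
                                  isthmus_radius_factor = 0.55),
    cavitated_tube = list(radius = 10, length = 80, cavity_radius = 12,
                          cavity_offset = c(0, 0, 0)))
  par <- utils::modifyList(defaults, list(...))
  extra <- setdiff(names(list(...)), names(defaults))
  if (length(extra))
    atk_error(sprintf("unknown parameter(s) for %s: %s", shape,
                      paste(extra, collapse = ", ")), "aortrack_spec_error")
  tube_r <- switch(shape,
    elliptical_tube = par$semi_minor,
    torus_arch = par$minor_radius,
    candy_cane = , candy_cane_with_branch = par$radius,
    par$radius)
  if (tube_r <= 2 * max(sp))
    atk_error(sprintf(
      "tube radius %.2f mm not resolvable at spacing %.2f mm (need > 2*max spacing)",
      tube_r, max(sp)), "aortrack_spec_error")
  structure(list(shape = shape, par = par, spacing = sp,
                 noise = as.double(noise), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s; spacing %s mm; noise %.2f vox; seed %d\n",
              x$shape, paste(format(x$spacing), collapse = "x"),
              x$noise, x$seed))
  cat("  ", paste(names(x$par), vapply(x$par, function(p)
    paste(format(p), collapse = ","), ""), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# ---- signed-distance helpers (sign-exact near the boundary) --------------

sdf_capped_cylinder <- function(p, base, axis, radius, length) {
  rel <- sweep(p, 2, base)
  t <- rel %*% axis
  rad <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
  d_rad <- rad - radius
  d_ax <- abs(t - length / 2) - length / 2
  pmin(pmax(d_rad, d_ax), 0) +
    sqrt(pmax(d_rad, 0)^2 + pmax(d_ax, 0)^2)
}

sdf_sphere <- function(p, center, radius) {
  sqrt(rowSums(sweep(p, 2, center)^2)) - radius
}

# half torus in the x-z plane (y is the tube's out-of-plane axis), ring
# center `center`, keeping the z >= center_z half
sdf_half_torus <- function(p, center, major, minor) {
  dx <- p[, 1] - center[1]
  dz <- p[, 3] - center[3]
  q <- sqrt(dx^2 + dz^2) - major
  tor <- sqrt(q^2 + (p[, 2] - center[2])^2) - minor
  pmax(tor, center[3] - p[, 3])
}

sdf_elliptic_tube <- function(p, base, a, b, length) {
  rel <- sweep(p, 2, base)
  f <- (sqrt((rel[, 1] / a)^2 + (rel[, 2] / b)^2) - 1) * min(a, b)
  d_ax <- abs(rel[, 3] - length / 2) - length / 2
  pmax(f, d_ax)
}

# ---- phantom generation ---------------------------------------------------

#' Generate a phantom mask with analytic ground truth
#'
#' Voxelizes the implicit solid described by a [phantom_spec] (foreground =
#' voxel centers inside the solid, optionally after seeded boundary jitter)
#' and returns it together with the exact centerline and diameter functions
#' of the unjittered solid. Truth functions are declared valid at least two
#' tube radii away from the open tube ends, where cap effects vanish.
#'
#' @param spec a [phantom_spec].
#' @return list with components `mask` (an [aorta_mask]) and `truth`
#'   (class `phantom_truth`: `centerline(s)` arc-length-parameterized curve
#'   in mm, `total_length`, `valid_range`, `area_fn(s)` in mm^2,
#'   `maxdiam_fn(s)` in mm, plus shape metadata).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  pr <- spec$par
  pad <- 3 * sp

  geom <- switch(spec$shape,
    straight_cylinder = {
      r <- pr$radius; L <- pr$length
      list(lo = c(-r, -r, 0) - pad, hi = c(r, r, L) + pad,
           sdf = function(p) sdf_capped_cylinder(p, c(0, 0, 0), c(0, 0, 1), r, L),
           centerline = function(s) cbind(0, 0, s),
           total_length = L, valid_range = c(2 * r, L - 2 * r),
           area_fn = function(s) rep(pi * r^2, length(s)),
           maxdiam_fn = function(s) rep(2 * r, length(s)),
           axis = c(0, 0, 1), radius = r)
    },
    tilted_cylinder = {
      r <- pr$radius; L <- pr$length
      th <- pr$tilt_deg * pi / 180
      ax <- c(sin(th), 0, cos(th))
      base <- c(0, 0, 0)
      ends <- rbind(base, base + L * ax)
      lo <- pmin(ends[1, ], ends[2, ]) - r - pad
      hi <- pmax(ends[1, ], ends[2, ]) + r + pad
      list(lo = lo, hi = hi,
           sdf = function(p) sdf_capped_cylinder(p, base, ax, r, L),
           centerline = function(s) cbind(base[1] + s * ax[1],
                                          base[2] + s * ax[2],
                                          base[3] + s * ax[3]),
           total_length = L, valid_range = c(2 * r, L - 2 * r),
           area_fn = function(s) rep(pi * r^2, length(s)),
           maxdiam_fn = function(s) rep(2 * r, length(s)),
           axis = ax, radius = r)
    },
    elliptical_tube = {
      a <- pr$semi_major; b <- pr$semi_minor; L <- pr$length
      list(lo = c(-a, -b, 0) - pad, hi = c(a, b, L) + pad,
           sdf = function(p) sdf_elliptic_tube(p, c(0, 0, 0), a, b, L),
           centerline = function(s) cbind(0, 0, s),
           total_length = L, valid_range = c(2 * b, L - 2 * b),
           area_fn = function(s) rep(pi * a * b, length(s)),
           maxdiam_fn = function(s) rep(2 * a, length(s)),
           axis = c(0, 0, 1), radius = b)
    },
    torus_arch = {
      R <- pr$major_radius; r <- pr$minor_radius
      ctr <- c(0, 0, 0)
      list(lo = c(-R - r, -r, 0) - pad, hi = c(R + r, r, R + r) + pad,
           sdf = function(p) sdf_half_torus(p, ctr, R, r),
           centerline = function(s) {
             phi <- s / R
             cbind(R * cos(phi), 0, R * sin(phi))
           },
           total_length = pi * R, valid_range = c(2 * r, pi * R - 2 * r),
           area_fn = function(s) rep(pi * r^2, length(s)),
           maxdiam_fn = function(s) rep(2 * r, length(s)),
           radius = r)
    },
    candy_cane = candy_cane_geometry(pr, pad, branch = FALSE),
    candy_cane_with_branch = candy_cane_geometry(pr, pad, branch = TRUE),
    cavitated_tube = {
      r <- pr$radius; L <- pr$length
      cav_c <- c(0, 0, L / 2) + pr$cavity_offset
      cav_r <- pr$cavity_radius
      list(lo = c(-r, -r, 0) - pad, hi = c(r, r, L) + pad,
           sdf = function(p) pmax(
             sdf_capped_cylinder(p, c(0, 0, 0), c(0, 0, 1), r, L),
             -sdf_sphere(p, cav_c, cav_r)),
           centerline = function(s) cbind(0, 0, s),
           total_length = L, valid_range = c(2 * r, L - 2 * r),
           area_fn = function(s) rep(pi * r^2, length(s)),
           maxdiam_fn = function(s) rep(2 * r, length(s)),
           axis = c(0, 0, 1), radius = r)
    })

  dims <- as.integer(ceiling((geom$hi - geom$lo) / sp)) + 1L
  # offset the sampling lattice by a sub-voxel fraction so voxel centers
  # never coincide exactly with the analytic surface (integer radii on an
  # aligned lattice otherwise produce degenerate boundary counts)
  origin <- geom$lo + 0.37 * sp
  # voxel-center world coordinates, x fastest (matches R array layout)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * sp[3]
  pts <- cbind(rep(xs, times = dims[2] * dims[3]),
               rep(rep(ys, each = dims[1]), times = dims[3]),
               rep(zs, each = dims[1] * dims[2]))
  d <- geom$sdf(pts)
  if (spec$noise > 0) {
    amp <- spec$noise * mean(sp)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    d <- d + amp * stats::runif(length(d), -1, 1)
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }
  vox <- array(as.double(d < 0), dims)
  affine <- diag(c(sp, 1)); affine[1:3, 4] <- origin
  mask <- aorta_mask(vox, affine = affine, is_axis = 3L, is_dir = 1L)

  truth <- structure(list(shape = spec$shape, par = pr,
                          centerline = geom$centerline,
                          total_length = geom$total_length,
                          valid_range = geom$valid_range,
                          area_fn = geom$area_fn,
                          maxdiam_fn = geom$maxdiam_fn,
                          axis = geom$axis, radius = geom$radius,
                          branch = geom$branch),
                     class = "phantom_truth")
  list(mask = mask, truth = truth)
}

# Candy-cane: vertical descending limb (inferior end open, aligned with the
# inferior-superior axis, as the tracker's initialization assumes), half-
# torus arch over the top, short ascending limb back down. Arc length runs
# 0 (inferior descending end, the "diaphragm") to the ascending end (the
# "root"). Tracking direction is diaphragm -> root, so the "descending"
# limb is traversed first. An optional isthmus taper narrows the trunk
# beyond a given arc angle, emulating the narrowing distal to the arch
# vessels that is common in congenital aortopathy. The branched variant
# adds a smaller tube taking off along the local direction of travel at
# the taper point, mimicking an arch vessel at the isthmus -- the
# configuration in which centerline tracking is prone to escaping into
# the branch.
candy_cane_geometry <- function(pr, pad, branch = FALSE) {
  r <- pr$radius; R <- pr$arch_radius
  H <- pr$descending_length; hA <- pr$ascending_length
  tap <- if (is.null(pr$isthmus_radius_factor)) 1 else pr$isthmus_radius_factor
  phi_t <- if (branch) pr$branch_arc_deg * pi / 180
           else pr$isthmus_arc_deg * pi / 180
  r2 <- tap * r  # trunk radius beyond the taper point
  ctr <- c(0, 0, H)  # arch (half-torus) center; descending limb at x = +R
  cl <- function(s) {
    s <- pmax(0, pmin(s, H + pi * R + hA))
    out <- matrix(0, length(s), 3)
    seg1 <- s <= H
    out[seg1, ] <- cbind(R, 0, s[seg1])
    seg2 <- s > H & s <= H + pi * R
    phi <- (s[seg2] - H) / R
    out[seg2, ] <- cbind(R * cos(phi), 0, H + R * sin(phi))
    seg3 <- s > H + pi * R
    out[seg3, ] <- cbind(-R, 0, H - (s[seg3] - H - pi * R))
    out
  }
  # tube radius as a function of arch angle: smooth (smoothstep) taper
  # from r to r2 over the `taper_w` radians ending at phi_t
  taper_w <- 25 * pi / 180
  r_of_phi <- function(phi) {
    t <- pmin(pmax((phi - (phi_t - taper_w)) / taper_w, 0), 1)
    r - (r - r2) * t^2 * (3 - 2 * t)
  }
  sdf_tapered_arch <- function(p) {
    dx <- p[, 1] - ctr[1]
    dz <- p[, 3] - ctr[3]
    q <- sqrt(dx^2 + dz^2) - R
    phi <- atan2(pmax(dz, 0), dx)
    tor <- sqrt(q^2 + p[, 2]^2) - r_of_phi(phi)
    pmax(tor, ctr[3] - p[, 3])
  }
  sdf_core <- function(p) {
    arch <- if (tap == 1) sdf_half_torus(p, ctr, R, r) else sdf_tapered_arch(p)
    pmin(sdf_capped_cylinder(p, c(R, 0, 0), c(0, 0, 1), r, H),
         arch,
         sdf_capped_cylinder(p, c(-R, 0, H - hA), c(0, 0, 1), r2, hA))
  }
  total <- H + pi * R + hA
  s_t <- H + R * phi_t
  lo <- c(-R - r, -r, min(0, H - hA)) - pad
  hi <- c(R + r, r, H + R + r) + pad
  sdf <- sdf_core
  branch_info <- NULL
  if (branch) {
    # The branch mimics an arch vessel: it takes off from the outer
    # (superior) surface of the arch and continues along the local
    # direction of travel while the trunk curves away -- the configuration
    # in which a minimal-area tracker is prone to following the branch.
    phi_b <- pr$branch_arc_deg * pi / 180
    s_b <- H + R * phi_b
    p_b <- drop(cl(s_b))
    tangent <- c(-sin(phi_b), 0, cos(phi_b))
    u_out <- c(cos(phi_b), 0, sin(phi_b))  # outward radial at phi_b
    bax <- unit3(rotate_about(tangent, c(0, 1, 0),
                              pr$branch_angle_deg * pi / 180))
    borig <- p_b + pr$branch_offset_factor * r * u_out
    br <- pr$branch_radius_factor * r
    bl <- pr$branch_length
    sdf <- function(p) pmin(sdf_core(p),
                            sdf_capped_cylinder(p, borig, bax, br, bl))
    ends <- rbind(borig, borig + bl * bax)
    lo <- pmin(lo, pmin(ends[1, ], ends[2, ]) - br - pad)
    hi <- pmax(hi, pmax(ends[1, ], ends[2, ]) + br + pad)
    branch_info <- list(origin = borig, axis = bax, radius = br,
                        length = bl, arc_s = s_b)
  }
  list(lo = lo, hi = hi, sdf = sdf, centerline = cl, total_length = total,
       valid_range = c(2 * r, total - 2 * r),
       area_fn = function(s) {
         phi <- pmin(pmax((s - H) / R, 0), pi)
         rr <- if (tap == 1) rep(r, length(s)) else {
           t <- pmin(pmax((phi - (phi_t - 25 * pi / 180)) / (25 * pi / 180), 0), 1)
           r - (r - r2) * t^2 * (3 - 2 * t)
         }
         pi * rr^2
       },
       maxdiam_fn = function(s) {
         phi <- pmin(pmax((s - H) / R, 0), pi)
         rr <- if (tap == 1) rep(r, length(s)) else {
           t <- pmin(pmax((phi - (phi_t - 25 * pi / 180)) / (25 * pi / 180), 0), 1)
           r - (r - r2) * t^2 * (3 - 2 * t)
         }
         2 * rr
       },
       axis = c(0, 0, 1), radius = r, branch = branch_info)
}

#' Densely sample a phantom's analytic centerline
#'
#' @param truth a `phantom_truth` from [generate_phantom].
#' @param ds arc-length sampling interval in mm.
#' @return data frame with columns `s`, `x`, `y`, `z` (mm).
#' @export
truth_centerline <- function(truth, ds = 0.25) {
  s <- seq(0, truth$total_length, by = ds)
  p <- truth$centerline(s)
  data.frame(s = s, x = p[, 1], y = p[, 2], z = p[, 3])
}

#' Write phantom truth tables to CSV
#'
#' One row per arc-length sample: `s_mm`, analytic cross-sectional area,
#' maximal diameter, and centerline coordinates.
#'
#' @param truth a `phantom_truth`.
#' @param path output CSV path.
#' @param ds sampling interval in mm.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path, ds = 1) {
  cl <- truth_centerline(truth, ds)
  df <- data.frame(s_mm = cl$s,
                   area_mm2 = truth$area_fn(cl$s),
                   max_diameter_mm = truth$maxdiam_fn(cl$s),
                   center_x_mm = cl$x, center_y_mm = cl$y,
                   center_z_mm = cl$z)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
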