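#' Binary aortic segmentation mask
#'
#' Container for a 3D binary voxel mask together with its geometry: voxel
#' spacing in mm (possibly anisotropic) and a 4x4 homogeneous affine mapping
#' 0-based voxel indices to world coordinates in mm. The voxel-center
#' convention is used throughout: index (0,0,0) maps to the center of the
#' first voxel. The array axis corresponding to the anatomical
#' inferior-superior direction must be identifiable, because centerline
#' tracking is initialized at the inferior end of the vessel.
#'
#' @param voxels 3D array of 0/1 (logical or numeric); at least one voxel
#'   must be foreground.
#' @param spacing numeric length-3, voxel edge lengths in mm. When `affine`
#'   is supplied, `spacing` may be omitted and is derived from its column
#'   norms; if both are given they must agree to 1e-6 mm.
#' @param affine 4x4 voxel-to-world transform; defaults to
#'   `diag(c(spacing, 1))`.
#' @param is_axis integer 1-3, the array axis running inferior-superior.
#'   Defaults to the axis whose world direction has the largest
#'   superior (third world coordinate) component.
#' @param is_dir +1 when increasing index moves superior, -1 otherwise.
#'   Inferred from the affine by default.
#' @return An object of class `aorta_mask`.
#' @export
aorta_mask <- function(voxels, spacing = NULL, affine = NULL,
                       is_axis = NULL, is_dir = NULL) {
  if (length(dim(voxels)) != 3L)
    atk_error("voxels must be a 3D array", "aortrack_format_error")
  v <- array(as.double(voxels != 0), dim(voxels))
  if (!all(voxels == 0 | voxels == 1))
    atk_error("voxels must contain only 0/1", "aortrack_format_error")
  if (sum(v) == 0)
    atk_error("mask is empty: no foreground voxels", "aortrack_empty_mask")
  if (is.null(affine)) {
    if (is.null(spacing))
      atk_error("one of spacing or affine is required", "aortrack_format_error")
    affine <- diag(c(spacing, 1))
  }
  affine <- unname(matrix(as.double(affine), 4, 4))
  colnorm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (is.null(spacing)) spacing <- colnorm
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    atk_error("spacing must be 3 positive lengths in mm", "aortrack_format_error")
  if (max(abs(spacing - colnorm)) > 1e-6)
    atk_error("spacing inconsistent with affine column norms",
              "aortrack_format_error")
  if (is.null(is_axis)) {
    sup <- abs(affine[3, 1:3]) / colnorm
    is_axis <- which.max(sup)
  }
  is_axis <- as.integer(is_axis)
  if (!is_axis %in% 1:3)
    atk_error("is_axis must be 1, 2 or 3", "aortrack_format_error")
  if (is.null(is_dir)) {
    is_dir <- if (affine[3, is_axis] >= 0) 1L else -1L
  }
  structure(list(voxels = v, spacing = spacing, affine = affine,
                 invaffine = solve(affine), is_axis = is_axis,
                 is_dir = as.integer(is_dir)),
            class = "aorta_mask")
}

#' @export
print.aorta_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<aorta_mask> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  foreground: %d voxels (%.1f mL); inferior-superior axis: %d (%s)\n",
              sum(x$voxels), sum(x$voxels) * prod(x$spacing) / 1000,
              x$is_axis, if (x$is_dir > 0) "+index superior" else "-index superior"))
  invisible(x)
}

#' Map 0-based voxel indices to world mm
#'
#' @param mask an [aorta_mask]
#' @param ijk numeric vector of length 3 or an n x 3 matrix of 0-based
#'   (possibly fractional) voxel indices.
#' @return world coordinates in mm, same shape as the input.
#' @export
voxel_to_world <- function(mask, ijk) {
  if (is.null(dim(ijk))) {
    drop(mask$affine %*% c(ijk, 1))[1:3]
  } else {
    h <- cbind(ijk, 1) %*% t(mask$affine)
    h[, 1:3, drop = FALSE]
  }
}

#' Sample a mask at world points by trilinear interpolation
#'
#' Values are in `[0, 1]`; points outside the volume sample as 0.
#'
#' @param mask an [aorta_mask]
#' @param points length-3 vector or n x 3 matrix of world mm coordinates.
#' @return numeric vector of interpolated mask values.
#' @export
mask_sample <- function(mask, points) {
  dm <- as.integer(dim(mask$voxels))
  if (is.null(dim(points))) points <- matrix(points, 1)
  vapply(seq_len(nrow(points)), function(i)
    cpp_sample_point(mask$voxels, dm, mask$invaffine,
                     as.double(points[i, ])), 0.0)
}

#' Read a binary mask from a NIfTI volume
#'
#' Voxels with intensity strictly above `threshold` become foreground. The
#' affine and spacing are taken from the NIfTI header (sform/qform), and the
#' inferior-superior array axis is inferred from the header orientation.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param threshold intensity cutoff; the default 0.5 is robust for masks
#'   stored as 0/1 floats.
#' @param is_axis optional override of the inferior-superior array axis
#'   (1-3, negative to flip direction) for headerless or mislabeled data.
#' @return an [aorta_mask]
#' @export
load_mask <- function(path, threshold = 0.5, is_axis = NULL) {
  if (!file.exists(path))
    atk_error(sprintf("cannot read '%s'", path), "aortrack_format_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    atk_error(sprintf("not a readable NIfTI volume: %s",
                                      conditionMessage(e)),
                              "aortrack_format_error"))
  a <- as.array(img)
  if (length(dim(a)) > 3L) {
    if (prod(dim(a)[-(1:3)]) != 1L)
      atk_error("volume has more than 3 non-singleton dimensions",
                "aortrack_format_error")
    a <- array(a, dim(a)[1:3])
  }
  vox <- array(as.double(a > threshold), dim(a))
  if (sum(vox) == 0)
    atk_error("mask is empty after thresholding", "aortrack_empty_mask")
  affine <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  attr(affine, "imagedim") <- NULL
  attr(affine, "code") <- NULL
  dir <- NULL
  if (!is.null(is_axis)) {
    dir <- if (is_axis < 0) -1L else 1L
    is_axis <- abs(is_axis)
  }
  aorta_mask(vox, affine = affine, is_axis = is_axis, is_dir = dir)
}

#' Write a mask to NIfTI
#'
#' The voxel array is written as 0/1 with the mask's affine stored in both
#' sform and qform, so that [load_mask] round-trips voxels exactly and
#' geometry to better than 1e-6 mm.
#'
#' @param mask an [aorta_mask]
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$spacing
  img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(mask$affine, code = 2L))
  tryCatch(RNifti::writeNifti(img, path, datatype = "uint8"),
           error = function(e)
             atk_error(sprintf("cannot write '%s': %s", path,
                               conditionMessage(e)), "aortrack_io_error"))
  invisible(path)
}

#' Voxelize a watertight STL surface into a binary mask
#'
#' Foreground is the set of voxel centers lying inside the closed surface
#' (parity ray casting), matching an inner-edge segmentation convention.
#' The sampling grid covers the mesh bounding box padded by at least two
#' voxels on every side.
#'
#' @param path STL file (binary or ASCII).
#' @param target_spacing voxel size in mm (scalar or length-3). The default
#'   1.35 mm isotropic sits in the middle of the typical 3D SSFP
#'   acquisition range (1.2-1.5 mm).
#' @param is_axis array axis (of the resulting grid) running
#'   inferior-superior; STL files carry no orientation metadata, so the
#'   default assumes the mesh z axis is superior.
#' @return an [aorta_mask]
#' @export
voxelize_stl <- function(path, target_spacing = 1.35, is_axis = 3L) {
  mesh <- read_stl(path)
  open_edges <- count_open_edges(mesh)
  if (open_edges > 0)
    atk_error(sprintf("mesh is not watertight: %d open edge(s)", open_edges),
              "aortrack_voxelize_error")
  sp <- as.double(target_spacing)
  if (length(sp) == 1L) sp <- rep(sp, 3)
  if (length(sp) != 3L || any(sp <= 0))
    atk_error("target_spacing must be 1 or 3 positive mm values",
              "aortrack_format_error")
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  origin <- lo - 2 * sp
  dims <- as.integer(ceiling((hi - origin) / sp)) + 3L
  vox <- cpp_voxelize(mesh$vertices, mesh$faces - 1L,
                      as.double(origin), sp, dims)
  if (!any(vox))
    atk_error("voxelization produced an empty mask (spacing too coarse?)",
              "aortrack_empty_mask")
  affine <- diag(c(sp, 1))
  affine[1:3, 4] <- origin
  aorta_mask(array(as.double(vox), dims), affine = affine,
             is_axis = abs(is_axis), is_dir = if (is_axis < 0) -1L else 1L)
}

#' Write a centerline trace profile to CSV
#'
#' One row per tracking step: step index, cumulative arc length, center
#' point, plane normal, cross-sectional area and max/min diameters. Rows are
#' ordered by step index; RFC-4180 CSV with '.' decimal separator.
#'
#' @param trace a [centerline_trace][track_centerline]
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(trace, path) {
  df <- profile_data_frame(trace)
  if (nrow(df) == 0)
    atk_error("trace has no steps; refusing to write an empty profile",
              "aortrack_empty_trace")
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    atk_error(sprintf("cannot write '%s'", path), "aortrack_io_error")
  invisible(path)
}

#' Read a profile CSV written by [write_profile_csv]
#'
#' @param path CSV path.
#' @return a data frame with one row per step.
#' @export
read_profile_csv <- function(path) {
  utils::read.csv(path)
}

#' Flatten a centerline trace to a data frame
#'
#' @param trace a [centerline_trace][track_centerline]
#' @return data frame with columns step, arc_length_mm, center/normal
#'   coordinates, area_mm2, max_diameter_mm, min_diameter_mm.
#' @export
profile_data_frame <- function(trace) {
  st <- trace$steps
  data.frame(
    step = vapply(st, `[[`, 0L, "index"),
    arc_length_mm = vapply(st, `[[`, 0.0, "arc_length"),
    center_x_mm = vapply(st, function(s) s$center[1], 0.0),
    center_y_mm = vapply(st, function(s) s$center[2], 0.0),
    center_z_mm = vapply(st, function(s) s$center[3], 0.0),
    normal_x = vapply(st, function(s) s$frame$normal[1], 0.0),
    normal_y = vapply(st, function(s) s$frame$normal[2], 0.0),
    normal_z = vapply(st, function(s) s$frame$normal[3], 0.0),
    area_mm2 = vapply(st, `[[`, 0.0, "area"),
    max_diameter_mm = vapply(st, `[[`, 0.0, "max_diameter"),
    min_diameter_mm = vapply(st, `[[`, 0.0, "min_diameter"))
}
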