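#' Read a triangulated surface from an STL file
#'
#' Supports both binary and ASCII STL. Duplicate vertices are merged exactly
#' (STL repeats vertex coordinates per facet), yielding an indexed mesh.
#'
#' @param path STL file path.
#' @return list with `vertices` (n x 3 numeric, mm) and `faces`
#'   (m x 3 integer, 1-based vertex indices).
#' @export
read_stl <- function(path) {
  if (!file.exists(path))
    atk_error(sprintf("cannot read '%s'", path), "aortrack_format_error")
  tri <- if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
  if (nrow(tri) == 0 || nrow(tri) %% 3 != 0)
    atk_error("STL contains no complete triangles", "aortrack_format_error")
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = unname(verts), faces = faces)
}

# Binary STL: 80-byte header, uint32 triangle count, then 50 bytes/triangle.
# ASCII files also often start with "solid", so the size check decides.
is_binary_stl <- function(path) {
  size <- file.size(path)
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  identical(size, 84 + 50 * as.numeric(ntri))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  tri <- matrix(0, ntri * 3, 3)
  for (i in seq_len(ntri)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)  # attribute byte count
    tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  tri
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0)
    atk_error("no vertices found in ASCII STL", "aortrack_format_error")
  parts <- strsplit(trimws(vl), "\\s+")
  tri <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  tri
}

# Number of mesh edges not shared by exactly two triangles; 0 for a closed
# (watertight) surface.
count_open_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sum(table(key) != 2)
}

# ASCII STL writer used for fixtures and the phantom CLI; vertices in mm.
write_stl_ascii <- function(vertices, faces, path, name = "aortrack") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(faces))) {
    v <- vertices[faces[i, ], , drop = FALSE]
    n <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
                 "  endloop",
                 "endfacet"), con)
  }
  writeLines("endsolid", con)
  invisible(path)
}

# Triangulated axis-aligned cuboid [lo, hi]; 12 triangles with outward
# orientation (orientation is irrelevant to parity voxelization).
cuboid_mesh <- function(lo, hi) {
  v <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                             c(lo[3], hi[3])))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = lo
    c(5, 6, 7), c(6, 8, 7),  # z = hi
    c(1, 2, 5), c(2, 6, 5),  # y = lo
    c(3, 7, 4), c(4, 7, 8),  # y = hi
    c(1, 5, 3), c(3, 5, 7),  # x = lo
    c(2, 4, 6), c(4, 8, 6))  # x = hi
  list(vertices = v, faces = f)
}

# UV-sphere triangulation: nseg longitudes x nring latitudes.
sphere_mesh <- function(center = c(0, 0, 0), radius = 10,
                       nseg = 48, nring = 24) {
  theta <- seq(0, pi, length.out = nring + 1)        # polar
  phi <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
  verts <- list(center + c(0, 0, radius))            # north pole
  ring_start <- integer(nring - 1)
  for (r in seq_len(nring - 1)) {
    ring_start[r] <- length(verts) + 1L
    for (p in seq_len(nseg))
      verts[[length(verts) + 1L]] <- center +
        radius * c(sin(theta[r + 1]) * cos(phi[p]),
                   sin(theta[r + 1]) * sin(phi[p]),
                   cos(theta[r + 1]))
  }
  south <- length(verts) + 1L
  verts[[south]] <- center + c(0, 0, -radius)
  V <- do.call(rbind, verts)
  F <- list()
  for (p in seq_len(nseg)) {                          # polar caps
    pn <- p %% nseg + 1L
    F[[length(F) + 1L]] <- c(1L, ring_start[1] + p - 1L, ring_start[1] + pn - 1L)
    F[[length(F) + 1L]] <- c(south, ring_start[nring - 1] + pn - 1L,
                             ring_start[nring - 1] + p - 1L)
  }
  for (r in seq_len(nring - 2)) {                     # quad strips
    for (p in seq_len(nseg)) {
      pn <- p %% nseg + 1L
      a <- ring_start[r] + p - 1L;  b <- ring_start[r] + pn - 1L
      c_ <- ring_start[r + 1] + p - 1L; d <- ring_start[r + 1] + pn - 1L
      F[[length(F) + 1L]] <- c(a, c_, b)
      F[[length(F) + 1L]] <- c(b, c_, d)
    }
  }
  list(vertices = V, faces = do.call(rbind, F))
}
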