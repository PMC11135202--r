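# shared fixture: one voxelized cylinder used across several blocks
cyl10 <- generate_phantom(phantom_spec("straight_cylinder", radius = 10,
                                       length = 60))

test_that("make_frame builds deterministic right-handed orthonormal triads", {
  set.seed(3)
  for (i in 1:25) {
    n <- stats::rnorm(3)
    fr <- make_frame(c(0, 0, 0), n)
    expect_lt(abs(sum(fr$u_axis * fr$v_axis)), 1e-9)
    expect_lt(abs(sum(fr$u_axis * fr$normal)), 1e-9)
    expect_lt(abs(sum(fr$v_axis * fr$normal)), 1e-9)
    expect_equal(sqrt(sum(fr$u_axis^2)), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum(fr$v_axis^2)), 1, tolerance = 1e-9)
    # right-handed: u x v = normal
    uxv <- c(fr$u_axis[2] * fr$v_axis[3] - fr$u_axis[3] * fr$v_axis[2],
             fr$u_axis[3] * fr$v_axis[1] - fr$u_axis[1] * fr$v_axis[3],
             fr$u_axis[1] * fr$v_axis[2] - fr$u_axis[2] * fr$v_axis[1])
    expect_equal(uxv, fr$normal, tolerance = 1e-9)
  }
  expect_identical(make_frame(c(1, 2, 3), c(0, 0, 1)),
                   make_frame(c(1, 2, 3), c(0, 0, 1)))
  expect_equal(make_frame(c(0, 0, 0), c(0, 0, 2)),
               make_frame(c(0, 0, 0), c(0, 0, 1)))
  expect_error(make_frame(c(0, 0, 0), c(0, 0, 0)),
               class = "aortrack_geometry_error")
})

test_that("sample_plane recovers analytic section areas", {
  m <- cyl10$mask
  ax <- sample_plane(m, make_frame(c(0, 0, 30), c(0, 0, 1)),
                     half_fov = 15, pitch = 0.5)
  expect_lt(abs(sum(ax) * 0.25 - pi * 100) / (pi * 100), 0.02)

  th <- 20 * pi / 180
  ob <- sample_plane(m, make_frame(c(0, 0, 30), c(sin(th), 0, cos(th))),
                     half_fov = 18, pitch = 0.5)
  want <- pi * 100 / cos(th)
  expect_lt(abs(sum(ob) * 0.25 - want) / want, 0.03)

  far <- sample_plane(m, make_frame(c(200, 200, 200), c(0, 0, 1)),
                      half_fov = 10, pitch = 0.5)
  expect_true(all(far == 0))
})

test_that("connected_region keeps exactly the seeded component", {
  g <- matrix(0L, 40, 40)
  g[5:15, 5:15] <- 1L
  g[25:35, 25:35] <- 1L
  a <- connected_region(g, seed_pixel = c(10, 10))
  expect_equal(sum(a), 11 * 11)
  expect_true(all(a[25:35, 25:35] == 0))

  single <- connected_region(g, seed_pixel = c(30, 30))
  expect_equal(sum(single), 11 * 11)

  # seed on background snaps to nearby foreground within 5 pixels
  b <- connected_region(g, seed_pixel = c(18, 10))
  expect_equal(sum(b), 11 * 11)
  expect_error(connected_region(matrix(0L, 10, 10)),
               class = "aortrack_lost_lumen")
  expect_error(connected_region(g, seed_pixel = c(20, 40)),
               class = "aortrack_lost_lumen")
})

test_that("Feret diameters match analytic shapes", {
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_equal(max_diameter(one, 1), 0)

  disc <- raster_ellipse(10, 10, 0.25)
  expect_lt(abs(max_diameter(disc, 0.25) - 20), 2 * 0.25)
  expect_lt(abs(min_diameter(disc, 0.25) - max_diameter(disc, 0.25)),
            2 * 0.25)

  ell <- raster_ellipse(15, 10, 0.25)
  expect_lt(abs(max_diameter(ell, 0.25) - 30), 2 * 0.25)
  expect_lt(abs(min_diameter(ell, 0.25) - 20), 2 * 0.25)

  expect_error(max_diameter(matrix(0L, 4, 4), 1),
               class = "aortrack_empty_region")
  expect_error(min_diameter(matrix(0L, 4, 4), 1),
               class = "aortrack_empty_region")
})

test_that("Feret diameters agree with brute-force oracles on random blobs", {
  for (seed in 1:60) {
    blob <- random_blob(seed)
    expect_equal(max_diameter(blob, 0.7), brute_max_feret(blob, 0.7),
                 tolerance = 1e-12)
    mn <- min_diameter(blob, 0.7)
    or <- scan_min_feret(blob, 0.7)
    expect_lt(abs(mn - or), 0.01 * max(or, 0.7))
  }
})

test_that("region_centroid maps pixel means to world coordinates", {
  m <- cyl10$mask
  fr <- make_frame(c(0, 0, 30), c(0, 0, 1))
  g <- connected_region(sample_plane(m, fr, half_fov = 15, pitch = 0.5))
  cen <- region_centroid(g, fr, 0.5)
  expect_lt(sqrt(sum((cen - c(0, 0, 30))^2)), 0.5)

  # two-pixel region: centroid at the midpoint
  g2 <- matrix(0L, 11, 11)
  g2[6, 5] <- 1L; g2[6, 7] <- 1L
  fr2 <- make_frame(c(0, 0, 0), c(0, 0, 1))
  cen2 <- region_centroid(g2, fr2, 1)
  expect_equal(cen2, fr2$origin, tolerance = 1e-9)

  # disc displaced by a known in-plane offset
  g3 <- matrix(0L, 41, 41)
  g3[26:34, 16:24] <- 1L   # center (30, 20) vs grid center (21, 21)
  cen3 <- region_centroid(g3, fr2, 0.5)
  want <- fr2$origin + 9 * 0.5 * fr2$u_axis - 1 * 0.5 * fr2$v_axis
  expect_equal(cen3, want, tolerance = 1e-9)

  expect_error(region_centroid(matrix(0L, 4, 4), fr2, 1),
               class = "aortrack_empty_region")
})

test_that("sections are rotation invariant up to discretization", {
  m <- cyl10$mask
  fr <- make_frame(c(0, 0, 30), c(0, 0, 1))
  cs <- cross_section(m, fr, half_fov = 15, pitch = 0.5)
  # rotate the voxel grid 90 degrees about the tube axis
  rot <- aorta_mask(aperm(m$voxels, c(2, 1, 3)),
                    spacing = m$spacing[c(2, 1, 3)],
                    affine = m$affine[, c(2, 1, 3, 4)][c(2, 1, 3, 4), ],
                    is_axis = 3L)
  cs2 <- cross_section(rot, make_frame(c(0, 0, 30), c(0, 0, 1)),
                       half_fov = 15, pitch = 0.5)
  expect_lt(abs(cs$max_diameter - cs2$max_diameter), 2 * 0.5)
  expect_lt(abs(cs$area - cs2$area) / cs$area, 0.02)
})

test_that("section area is minimal perpendicular to a straight tube", {
  m <- cyl10$mask
  a0 <- cross_section(m, make_frame(c(0, 0, 30), c(0, 0, 1)),
                      half_fov = 18, pitch = 0.5)$area
  for (th in seq(5, 30, by = 5)) {
    fr <- make_frame(c(0, 0, 30),
                     c(sin(th * pi / 180), 0, cos(th * pi / 180)))
    at <- cross_section(m, fr, half_fov = 18, pitch = 0.5)$area
    expect_gte(at, a0 * 0.995)  # tilted never smaller (up to pixel noise)
  }
})

test_that("cross_section invariants hold on a measured section", {
  cs <- cross_section(cyl10$mask, make_frame(c(0, 0, 30), c(0, 0, 1)),
                      half_fov = 15, pitch = 0.5)
  expect_equal(cs$area, sum(cs$grid) * cs$pitch^2)
  expect_gte(cs$max_diameter, cs$min_diameter)
  expect_gte(cs$max_diameter, 2 * sqrt(cs$area / pi) - 2 * cs$pitch)
})
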