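test_that("phantom generation is deterministic for a given spec and seed", {
  s <- phantom_spec("straight_cylinder", radius = 8, length = 30,
                    noise = 0.5, seed = 11)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$mask$voxels, b$mask$voxels)
  c <- generate_phantom(phantom_spec("straight_cylinder", radius = 8,
                                     length = 30, noise = 0.5, seed = 12))
  expect_false(identical(a$mask$voxels, c$mask$voxels))
})

test_that("foreground volume matches the analytic solid within 5%", {
  cases <- list(
    list(spec = phantom_spec("straight_cylinder", radius = 10, length = 80),
         vol = pi * 100 * 80),
    list(spec = phantom_spec("elliptical_tube"),
         vol = pi * 15 * 10 * 80),
    # tube volume = cross-section area x centerline length (Pappus)
    list(spec = phantom_spec("candy_cane"),
         vol = pi * 144 * (60 + pi * 40 + 30)))
  for (cs in cases) {
    m <- generate_phantom(cs$spec)$mask
    got <- sum(m$voxels) * prod(m$spacing)
    expect_lt(abs(got - cs$vol) / cs$vol, 0.05)
  }
})

test_that("mid-tube axial slices of a cylinder have the analytic area", {
  ph <- generate_phantom(phantom_spec("straight_cylinder", radius = 10,
                                      length = 80))
  m <- ph$mask
  zs <- (seq_len(dim(m$voxels)[3]) - 1) * m$spacing[3] + m$affine[3, 4]
  mid <- which(zs > 20 & zs < 60)
  for (k in mid[seq(1, length(mid), by = 8)]) {
    area <- sum(m$voxels[, , k]) * prod(m$spacing[1:2])
    expect_lt(abs(area - pi * 100) / (pi * 100), 0.03)
  }
})

test_that("truth functions report the analytic diameters", {
  e <- generate_phantom(phantom_spec("elliptical_tube"))$truth
  expect_equal(e$maxdiam_fn(c(25, 40, 55)), rep(30, 3))
  expect_equal(e$area_fn(40), pi * 150)
  cc <- generate_phantom(phantom_spec("candy_cane"))$truth
  s <- seq(cc$valid_range[1], cc$valid_range[2], length.out = 7)
  expect_equal(cc$maxdiam_fn(s), rep(24, 7))
  # tapered arch narrows beyond the isthmus angle
  ct <- generate_phantom(phantom_spec("candy_cane",
                                      isthmus_radius_factor = 0.55))$truth
  expect_equal(ct$maxdiam_fn(10), 24)
  expect_equal(ct$maxdiam_fn(ct$total_length - 10), 24 * 0.55)
})

test_that("a fully interior cavity is one enclosed background pocket", {
  ph <- generate_phantom(phantom_spec("cavitated_tube", cavity_radius = 4))
  v <- ph$mask$voxels
  d <- dim(v)
  # propagate 'outside' labels inward from the volume border through
  # background voxels (6-connectivity, iterated to fixpoint)
  bg <- v == 0
  out <- array(FALSE, d)
  out[1, , ] <- bg[1, , ]; out[d[1], , ] <- bg[d[1], , ]
  out[, 1, ] <- out[, 1, ] | bg[, 1, ]; out[, d[2], ] <- out[, d[2], ] | bg[, d[2], ]
  out[, , 1] <- out[, , 1] | bg[, , 1]; out[, , d[3]] <- out[, , d[3]] | bg[, , d[3]]
  repeat {
    grown <- out
    grown[-1, , ] <- grown[-1, , ] | out[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | out[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | out[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | out[, -1, ]
    grown[, , -1] <- grown[, , -1] | out[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | out[, , -1]
    grown <- grown & bg
    if (identical(grown, out)) break
    out <- grown
  }
  pocket <- bg & !out
  expect_gt(sum(pocket), 0)
  # the pocket is a single connected component: BFS from one seed voxel
  seed <- which(pocket, arr.ind = TRUE)[1, ]
  seen <- array(FALSE, d)
  seen[seed[1], seed[2], seed[3]] <- TRUE
  queue <- list(seed)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (k in 1:6) {
      q <- p + nb[k, ]
      if (any(q < 1) || any(q > d)) next
      if (pocket[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]]) {
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  expect_equal(sum(seen), sum(pocket))
  # pocket volume close to the analytic sphere
  expect_lt(abs(sum(pocket) - 4 / 3 * pi * 64) / (4 / 3 * pi * 64), 0.25)
})

test_that("branched candy cane equals the plain one outside the branch", {
  pb <- generate_phantom(phantom_spec("candy_cane_with_branch"))
  pc <- generate_phantom(phantom_spec("candy_cane",
                                      isthmus_radius_factor = 0.55,
                                      isthmus_arc_deg = 65))
  br <- pb$truth$branch
  expect_false(is.null(br))
  # voxel bounding box of the branch tube (with one-voxel margin)
  ends <- rbind(br$origin, br$origin + br$length * br$axis)
  lo_w <- pmin(ends[1, ], ends[2, ]) - br$radius - 1
  hi_w <- pmax(ends[1, ], ends[2, ]) + br$radius + 1
  mb <- pb$mask
  # compare on the common voxel lattice via world coordinates
  dims <- dim(mb$voxels)
  coord <- function(m, axis) m$affine[axis, 4] +
    (seq_len(dim(m$voxels)[axis]) - 1) * m$spacing[axis]
  keep <- list()
  for (ax in 1:3) {
    w <- coord(mb, ax)
    keep[[ax]] <- w < lo_w[ax] | w > hi_w[ax]
  }
  # voxels of the branched mask outside the branch bbox must match the
  # plain candy cane at the same world coordinates
  wc <- lapply(1:3, function(ax) coord(pc$mask, ax))
  wb <- lapply(1:3, function(ax) coord(mb, ax))
  idx_map <- lapply(1:3, function(ax)
    match(round(wb[[ax]], 6), round(wc[[ax]], 6)))
  # the two grids share an origin, so most indices must line up
  expect_gt(sum(!is.na(idx_map[[3]])), 0.8 * length(wc[[3]]))
  mismatches <- 0
  for (k in seq_len(dims[3])) {
    kk <- idx_map[[3]][k]
    if (is.na(kk)) next
    sl_b <- mb$voxels[, , k]
    sl_c <- pc$mask$voxels[idx_map[[1]], idx_map[[2]], kk]
    ok <- outer(keep[[1]], keep[[2]], "|") | keep[[3]][k]
    valid <- !is.na(sl_c)
    mismatches <- mismatches + sum(sl_b[ok & valid] != sl_c[ok & valid])
  }
  expect_equal(mismatches, 0)
})

test_that("unresolvable or malformed specs are rejected", {
  expect_error(phantom_spec("straight_cylinder", radius = 1.5),
               class = "aortrack_spec_error")
  expect_error(phantom_spec("straight_cylinder", bogus = 1),
               class = "aortrack_spec_error")
  expect_error(phantom_spec("candy_cane", spacing = c(1, -1, 1)),
               class = "aortrack_spec_error")
})
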