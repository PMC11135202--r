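# small, fast phantoms shared by the tracking tests
cyl8 <- generate_phantom(phantom_spec("straight_cylinder", radius = 8,
                                      length = 40))

test_that("extrapolation follows the closed form and rejects degeneracy", {
  expect_equal(extrapolate_point(c(0, 0, 0), c(0, 0, 1), 1), c(0, 0, 2))
  expect_equal(extrapolate_point(c(0, 0, 0), c(0, 1, 1), sqrt(2)),
               c(0, 2, 2))
  expect_equal(extrapolate_point(c(1, 1, 1), c(1, 1, 1.5), 0.25),
               c(1, 1, 1.75))
  expect_error(extrapolate_point(c(1, 2, 3), c(1, 2, 3), 1),
               class = "aortrack_geometry_error")
})

test_that("initialization seeds at the inferior slice centers of mass", {
  init <- initialize_tracker(cyl8$mask)
  expect_lt(sqrt(sum((init$p_inferior[1:2])^2)), 1)   # axis at (0, 0)
  expect_lt(sqrt(sum((init$p_superior[1:2])^2)), 1)
  expect_lt(init$p_inferior[3], init$p_superior[3])   # ordered inferiorly

  cc <- generate_phantom(phantom_spec("candy_cane"))
  ic <- initialize_tracker(cc$mask)
  d <- ic$p_superior - ic$p_inferior
  ang <- acos(sum(d * c(0, 0, 1)) / sqrt(sum(d^2))) * 180 / pi
  expect_lt(ang, 5)

  tiny <- array(0, c(8, 8, 8)); tiny[4, 4, 4] <- 1
  expect_error(initialize_tracker(aorta_mask(tiny, spacing = c(1, 1, 1))),
               class = "aortrack_init_error")
})

test_that("wobble recovers the tube-perpendicular plane", {
  m <- cyl8$mask
  cfg <- tracking_config()
  w <- wobble(m, c(0, 0, 20), c(sin(10 * pi / 180), 0, cos(10 * pi / 180)),
              cfg)
  ang <- acos(min(1, abs(sum(w$frame$normal * c(0, 0, 1))))) * 180 / pi
  expect_lte(ang, cfg$wobble_fine_deg + 1e-6)
  expect_lt(abs(w$area_mm2 - pi * 64) / (pi * 64), 0.02)

  # an already-optimal base normal is kept (tie-break toward zero tilt)
  w2 <- wobble(m, c(0, 0, 20), c(0, 0, 1), cfg)
  expect_lte(w2$tilt_deg, cfg$wobble_fine_deg + 1e-6)

  # locally circular section of a curved tube
  ta <- generate_phantom(phantom_spec("torus_arch"))
  mid <- as.numeric(ta$truth$centerline(pi * 40 / 2))
  w3 <- wobble(ta$mask, mid, c(-1, 0, 0.1), tracking_config())
  expect_lt(abs(w3$area_mm2 - pi * 144) / (pi * 144), 0.03)

  # a point far outside the mask has no lumen to find
  expect_error(wobble(m, c(100, 100, 100), c(0, 0, 1), cfg),
               class = "aortrack_lost_lumen")
})

test_that("tracking a straight tube is complete, regular and accurate", {
  tr <- track_centerline(cyl8$mask)
  expect_equal(tr$status, "completed")
  d <- profile_data_frame(tr)
  expect_gt(nrow(d), 32)          # ~40 mm at 1 mm steps, minus end effects
  expect_lt(nrow(d), 48)
  expect_lt(abs(max(d$arc_length_mm) - 40) / 40, 0.12)

  # arc length strictly increasing, step lengths within [0.2, 3] steps
  expect_true(all(diff(d$arc_length_mm) > 0))
  ctr <- as.matrix(d[, c("center_x_mm", "center_y_mm", "center_z_mm")])
  hops <- sqrt(rowSums(diff(ctr)^2))
  expect_true(all(hops >= 0.2 * tr$step_mm & hops <= 3 * tr$step_mm))

  # diameter recovery in the valid region
  tv <- trace_vs_truth(tr, cyl8$truth)
  expect_lt(abs(stats::median(d$max_diameter_mm[tv$valid]) - 16),
            max(2 * tr$pitch_mm, 0.02 * 16))
  expect_lt(tv$rmse, 1)           # < 1 voxel
})

test_that("the chosen wobble normal is a local area minimum", {
  m <- cyl8$mask
  cfg <- tracking_config()
  tr <- track_centerline(m)
  dm <- as.integer(dim(m$voxels))
  picks <- tr$steps[as.integer(seq(8, length(tr$steps) - 8, length.out = 4))]
  for (st in picks) {
    base <- st$frame
    n_px <- as.integer(ceiling(cfg$half_fov_floor_mm / tr$pitch_mm))
    area_of <- function(nrm) {
      fr <- make_frame(st$frame$origin, nrm)
      res <- aortrack:::cpp_plane_component_count(
        m$voxels, dm, m$invaffine, fr$origin, fr$u_axis, fr$v_axis,
        tr$pitch_mm, n_px, 5L, 2L)
      res[2] * tr$pitch_mm^2
    }
    a0 <- area_of(base$normal)
    for (axis in list(base$u_axis, base$v_axis))
      for (sgn in c(-1, 1)) {
        nrm <- aortrack:::rotate_about(base$normal, axis,
                                       sgn * 2 * cfg$wobble_fine_deg * pi / 180)
        expect_gt(area_of(nrm), a0 * 0.99)
      }
  }
})

test_that("tracking is deterministic", {
  t1 <- track_centerline(cyl8$mask)
  t2 <- track_centerline(cyl8$mask)
  expect_identical(profile_data_frame(t1), profile_data_frame(t2))
  expect_identical(t1$status, t2$status)
})

test_that("branch-exit flagging follows the sustained area collapse rule", {
  # too short for the window
  expect_false(detect_branch_exit(synthetic_trace(rep(20, 5))))
  # clean tube
  expect_false(detect_branch_exit(synthetic_trace(rep(20, 60))))
  # sustained collapse to a fraction of the trunk area
  d <- c(rep(20, 40), rep(8, 40))
  expect_true(detect_branch_exit(synthetic_trace(d)))
  # a transient dip that recovers is not a branch exit
  d2 <- c(rep(20, 30), rep(8, 5), rep(20, 30))
  expect_false(detect_branch_exit(synthetic_trace(d2)))
})
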