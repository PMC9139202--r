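# Synthetic geometry generators and mask operations.

test_that("straight vessel masks hit the analytic fluid fractions", {
  p <- aneurysm_params(vessel_length = 16e-3)
  m <- make_straight_vessel(p, 1e-4, 2L, domain_height = 8e-3)
  # channel of 4 mm in an 8 mm box: half the area, within one cell layer
  one_layer <- 1 / ncol(m$indicator)
  expect_lte(abs(fluid_fraction(m) - 0.5), one_layer + 1e-12)
  expect_true(all(m$indicator %in% c(0L, 1L)))

  m3 <- make_straight_vessel(p, 1e-4, 3L, domain_height = 8e-3)
  expect_lt(abs(fluid_fraction(m3) / (pi / 16) - 1), 0.02)
})

test_that("too coarse a spacing is a resolution error", {
  p <- aneurysm_params()
  expect_error(make_straight_vessel(p, 1e-3), class = "aneuflow_resolution_error")
  # 8 cells across is the documented minimum
  expect_s3_class(make_straight_vessel(p, 0.5e-3), "voxel_mask")
})

test_that("sidewall aneurysm area matches channel plus circular-segment value", {
  p <- aneurysm_params(sac_radius = 2e-3, neck_width = 1.6e-3,
                       vessel_length = 16e-3)
  m <- make_sidewall_aneurysm(p, 0.5e-4)
  r <- p$sac_radius
  b <- sqrt(r^2 - (p$neck_width / 2)^2)
  minor_segment <- r^2 * acos(b / r) - b * sqrt(r^2 - b^2)
  sac_part <- pi * r^2 - minor_segment      # disk portion beyond the wall
  analytic <- p$vessel_length * m$meta$diameter + sac_part
  area <- sum(m$indicator == 0L) * m$spacing^2
  expect_lt(abs(area / analytic - 1), 0.03)
})

test_that("every generated mask satisfies the class invariants", {
  for (spacing in c(1e-4, 2e-4)) {
    for (neck in c(1.2e-3, 2e-3)) {
      for (side in c("top", "bottom")) {
        m <- make_sidewall_aneurysm(
          aneurysm_params(neck_width = neck, sac_side = side), spacing)
        expect_silent(validate_voxel_mask(m))
        expect_true(all(m$indicator %in% c(0L, 1L)))
      }
    }
  }
})

test_that("degenerate necks leave the sac disconnected and error", {
  expect_error(make_sidewall_aneurysm(aneurysm_params(neck_width = 0), 1e-4),
               class = "aneuflow_geometry_error")
  expect_error(aneurysm_params(neck_width = 5e-3, sac_radius = 2e-3),
               class = "aneuflow_domain_error")
})

test_that("refine_mask replicates blocks, preserves fractions and composes", {
  m <- make_sidewall_aneurysm(aneurysm_params(), 2e-4)
  expect_identical(refine_mask(m, 1), m)
  r2 <- refine_mask(m, 2)
  expect_equal(r2$spacing, m$spacing / 2)
  expect_identical(dim(r2$indicator), dim(m$indicator) * 2L)
  expect_equal(fluid_fraction(r2), fluid_fraction(m))
  # composition: refine by a*b equals refine by a then b
  expect_identical(refine_mask(m, 6)$indicator,
                   refine_mask(refine_mask(m, 2), 3)$indicator)
  # 2 px/mm imagery refined 16x reaches 32 cells/mm
  px2 <- make_straight_vessel(aneurysm_params(), 0.5e-3)
  r16 <- refine_mask(px2, 16)
  cells_per_mm <- 1e-3 / r16$spacing
  expect_gte(cells_per_mm, 30); expect_lte(cells_per_mm, 40)
})

test_that("smoothing removes specks, is identity at radius 0 and keeps invariants", {
  m <- make_straight_vessel(aneurysm_params(vessel_length = 8e-3), 1e-4)
  expect_identical(smooth_mask(m, 0), m)
  speck <- m
  mid <- round(dim(m$indicator) / 2)
  speck$indicator[mid[1], mid[2]] <- 1L
  sm <- smooth_mask(speck, 1)
  expect_identical(sm$indicator[mid[1], mid[2]], 0L)
  expect_true(all(sm$indicator %in% c(0L, 1L)))
  expect_silent(validate_voxel_mask(sm))
})
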