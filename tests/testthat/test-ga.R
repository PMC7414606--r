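test_that("automatic GA segmentation recovers the synthetic lesion", {
  sc <- make_eye_scene(small_params(21), growth_law())
  les <- segment_ga(sc$pair$baseline$sub_rpe, geometry = small_geometry())
  tr <- sc$truth$ga_baseline
  dice <- 2 * sum(les$mask & tr) / (sum(les$mask) + sum(tr))
  expect_gte(dice, 0.95)
})

test_that("override masks are used verbatim and uniform images give empty lesions", {
  g <- small_geometry(32)
  ov <- disk_mask(32, 5)
  les <- segment_ga(matrix(0, 32, 32), override_mask = ov, geometry = g)
  expect_identical(les$mask, ov)
  expect_warning(les0 <- segment_ga(matrix(7, 32, 32), geometry = g),
                 "uniform|empty")
  expect_false(any(les0$mask))
  expect_equal(les0$area_mm2, 0)
})

test_that("lesion area, focus count and border flag are computed from the mask", {
  g <- scan_geometry()  # 12 um/px
  m <- disk_mask(100, 10) | disk_mask(100, 6, 80, 80)
  les <- ga_lesion(m, g)
  expect_equal(les$area_mm2, sum(m) * (0.012)^2)
  expect_equal(les$n_foci, 2L)
  expect_false(les$border_flag)
  # area is additive over foci
  a1 <- ga_lesion(disk_mask(100, 10), g)$area_mm2
  a2 <- ga_lesion(disk_mask(100, 6, 80, 80), g)$area_mm2
  expect_equal(les$area_mm2, a1 + a2)
  m2 <- m; m2[1, 50] <- TRUE
  expect_true(ga_lesion(m2, g)$border_flag)
})

test_that("vessel-landmark registration recovers constructed shifts", {
  sc <- make_eye_scene(small_params(31, n = 128), growth_law(),
                       true_shift = c(3, -5))
  reg <- register_pair(sc$pair$baseline, sc$pair$followup)
  expect_identical(c(reg$dy, reg$dx), c(3L, -5L))
  expect_true(reg$reliable)
  # identical images: zero shift
  reg0 <- register_pair(sc$pair$baseline, sc$pair$baseline)
  expect_identical(c(reg0$dy, reg0$dx), c(0L, 0L))
  # aligning undoes the constructed shift on the truth mask
  aligned <- shift_visit(sc$pair$followup, -reg$dy, -reg$dx)
  les <- segment_ga(aligned$sub_rpe, geometry = small_geometry(128))
  expect_gt(2 * sum(les$mask & sc$truth$ga_followup) /
              (sum(les$mask) + sum(sc$truth$ga_followup)), 0.6)
})

test_that("registration degrades gracefully on noise and missing layers", {
  g <- small_geometry(64)
  set.seed(10)
  mk <- function() eye_visit("p", "right",
                             matrix(runif(64^2, 0, 100), 64, 64),
                             matrix(runif(64^2, 0, 100), 64, 64),
                             inner_retina_octa = matrix(runif(64^2), 64, 64),
                             geometry = g)
  expect_warning(reg <- register_pair(mk(), mk()), "indistinct|flat")
  expect_identical(c(reg$dy, reg$dx), c(0L, 0L))
  v <- mk(); v$inner_retina_octa <- NULL
  expect_warning(reg2 <- register_pair(v, mk()), "missing")
  expect_false(reg2$reliable)
})

test_that("growth rate implements the square-root-area formula", {
  g <- scan_geometry(grid_size_px = 8)
  m <- matrix(0, 8, 8)
  b <- eye_visit("p", "right", m, m, geometry = g)
  pair <- visit_pair(b, b, months_elapsed = 10)
  mk_lesion <- function(area_mm2) {
    l <- ga_lesion(matrix(TRUE, 8, 8)[, , drop = FALSE], g)
    l$area_mm2 <- area_mm2
    l
  }
  gr <- growth_rate(pair, mk_lesion(1), mk_lesion(4))
  expect_equal(gr$growth_rate_um_per_month, (2000 - 1000) / 10)
  expect_equal(growth_rate(pair, mk_lesion(2), mk_lesion(2))$growth_rate_um_per_month, 0)
  expect_warning(growth_rate(pair, ga_lesion(matrix(TRUE, 8, 8), g),
                             ga_lesion(matrix(FALSE, 8, 8), g)),
                 "superset")
})

test_that("sqrt-area growth rate is independent of baseline radius for constant radial speed", {
  g <- scan_geometry()  # 12 um/px
  months <- 12
  v_um_mo <- 10
  expected <- v_um_mo * sqrt(pi)  # 17.72 um/month
  for (r0_px in c(25, 40, 60)) {
    n <- 220
    r1_px <- r0_px + v_um_mo * months / g$pixel_size_um
    l0 <- ga_lesion(disk_mask(n, r0_px), g)
    l1 <- ga_lesion(disk_mask(n, r1_px), g)
    m <- matrix(0, n, n)
    geom_n <- scan_geometry(grid_size_px = n, field_of_view_mm = n * 12 / 1000)
    b <- eye_visit("p", "right", m, m, geometry = geom_n)
    pair <- visit_pair(b, b, months_elapsed = months)
    rate <- growth_rate(pair, l0, l1)$growth_rate_um_per_month
    expect_equal(rate, expected, tolerance = 0.02)
  }
})

test_that("distance map equals the brute-force oracle on small grids", {
  set.seed(11)
  for (rep in 1:3) {
    ga <- matrix(runif(32 * 32) < 0.08, 32, 32)
    if (!any(ga)) ga[16, 16] <- TRUE
    d <- distance_map(ga)
    expect_equal(d, brute_distance_map(ga))
  }
  # diagonal neighbour is at sqrt(2)
  ga <- matrix(FALSE, 16, 16); ga[8, 8] <- TRUE
  d <- distance_map(ga)
  expect_equal(d[9, 9], sqrt(2))
  expect_equal(d[8, 9], 1)
  expect_error(distance_map(matrix(FALSE, 8, 8)), "empty")
})

test_that("ring ROIs nest and respect exclusions", {
  ga <- disk_mask(200, 30)
  d <- distance_map(ga)
  r40 <- ring_roi(d, 40)
  r60 <- ring_roi(d, 60)
  r80 <- ring_roi(d, 80)
  expect_true(all(r40 <= r60) && all(r60 <= r80))
  expect_false(any(r40 & ga))
  # annulus geometry: every ring pixel within the distance bound
  expect_true(all(d[r40] > 0 & d[r40] <= 40))
  # full exclusion empties the ring
  expect_error(ring_roi(d, 40, list(matrix(TRUE, 200, 200))), "empty")
})

test_that("the 40 px ring spans 480 um at default geometry", {
  expect_equal(pixels_to_um(40, scan_geometry()), 480)
})
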