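test_that("compensation is a clipped structural-ratio gain", {
  set.seed(1)
  cc <- matrix(runif(64 * 64, 50, 150), 64, 64)
  # uniform structure: output exactly proportional (gain constant, = 1 here)
  uni <- matrix(1000, 64, 64)
  expect_equal(compensate(cc, uni), cc)
  # a shadowed patch at half the structural level doubles the OCTA signal
  st <- matrix(1000, 64, 64)
  st[20:40, 20:40] <- 500
  out <- compensate(cc, st, reference = 1000)
  expect_equal(out[30, 30] / cc[30, 30], 2, tolerance = 0.02)
  expect_equal(out[5, 5] / cc[5, 5], 1, tolerance = 0.02)
  # deep shadow: gain capped at the clip bound
  st2 <- matrix(1000, 64, 64); st2[30:34, 30:34] <- 100
  out2 <- compensate(cc, st2, clip = c(0.5, 2), reference = 1000)
  expect_equal(out2[32, 32] / cc[32, 32], 2, tolerance = 1e-6)
  expect_error(compensate(cc, matrix(0, 64, 64)), "all-zero")
  expect_error(compensate(cc, matrix(1, 10, 10)), "dimensions")
})

test_that("the FV threshold is mean minus k SDs of the normative intensity", {
  expect_equal(fv_threshold(normative_stats(100, 20)), 80)
  expect_equal(fv_threshold(normative_stats(100, 20), k_sd = 0), 100)
  expect_equal(fv_threshold(normative_stats(150, 50)), 100)
})

test_that("binarization is strictly below threshold and counts exactly", {
  img <- matrix(80, 20, 20)
  expect_equal(sum(binarize_fv(img, 80)), 0)  # ties are not FV
  set.seed(4)
  img2 <- matrix(runif(500 * 500, 0, 100), 500, 500)
  thr <- 37.5
  expect_equal(sum(binarize_fv(img2, thr)), sum(img2 < thr))
  expect_equal(sum(binarize_fv(img2, -Inf)), 0)
})

test_that("drusen exclusion applies the equivalent-diameter rule", {
  g <- scan_geometry()  # 12 um/px
  mk_bump <- function(area_px) {
    elev <- matrix(0, 50, 50)
    idx <- which(disk_mask(50, sqrt(area_px / pi) + 0.1), arr.ind = TRUE)
    idx <- idx[seq_len(min(area_px, nrow(idx))), , drop = FALSE]
    elev[idx] <- 30
    elev
  }
  # equivalent diameter 2*sqrt(a/pi)*12 um; area 3 px -> 23.4 um: kept out
  expect_false(any(drusen_exclusion(mk_bump(3), 15, geometry = g)))
  # area 9 px -> 40.6 um: excluded, fully
  ex <- drusen_exclusion(mk_bump(9), 15, geometry = g)
  expect_equal(sum(ex), 9)
  expect_false(any(drusen_exclusion(matrix(0, 50, 50), 15, geometry = g)))
  expect_error(drusen_exclusion(matrix(-1, 5, 5)), "non-negative")
})

test_that("drusen components are labelled with 8-connectivity", {
  elev <- matrix(0, 30, 30)
  # staircase of diagonal pixels: one 8-connected component of area 12
  for (i in 1:12) elev[10 + i, 10 + i] <- 30
  ex <- drusen_exclusion(elev, 15, min_diameter_um = 25,
                         geometry = scan_geometry())
  # equivalent diameter 2*sqrt(12/pi)*12 = 46.9 um -> excluded as one blob
  expect_equal(sum(ex), 12)
})

test_that("projection exclusion covers vessels plus a one-pixel halo", {
  inner <- matrix(0, 64, 64)
  inner[30:32, 10:54] <- 1000  # 3-px-wide vessel line
  ex <- projection_exclusion(inner)
  expect_true(all(ex[29:33, 11:53]))   # line + halo
  expect_false(any(ex[c(1:27, 35:64), ]))
  expect_false(any(projection_exclusion(matrix(5, 32, 32))))  # blank
  expect_warning(ex0 <- projection_exclusion(NULL, scan_geometry(grid_size_px = 16)),
                 "missing")
  expect_equal(dim(ex0), c(16, 16))
})

test_that("FV percentage equals the brute-force pixel ratio", {
  set.seed(5)
  n <- 40
  fv <- matrix(runif(n^2) < 0.3, n, n)
  roi <- matrix(runif(n^2) < 0.7, n, n)
  excl <- list(matrix(runif(n^2) < 0.1, n, n))
  roi_eff <- roi & !excl[[1]]
  expect_equal(fv_percentage(fv, roi, excl),
               100 * sum(fv & roi_eff) / sum(roi_eff))
  # exact fixture: 37 FV pixels in a 200-pixel ROI
  roi2 <- matrix(FALSE, n, n); roi2[1:10, 1:20] <- TRUE
  fv2 <- matrix(FALSE, n, n); fv2[1:10, 1:20][sample(200, 37)] <- TRUE
  expect_equal(fv_percentage(fv2, roi2), 18.5)
  expect_equal(fv_percentage(roi2, roi2), 100)
  expect_equal(fv_percentage(!roi2, roi2), 0)
  expect_error(fv_percentage(fv, matrix(FALSE, n, n)), "empty")
})

test_that("FV percentage is monotone nondecreasing in the threshold", {
  set.seed(6)
  img <- matrix(rnorm(64^2, 100, 20), 64, 64)
  roi <- matrix(TRUE, 64, 64)
  pct <- vapply(seq(40, 160, 10), function(t)
    fv_percentage(binarize_fv(img, t), roi), numeric(1))
  expect_true(all(diff(pct) >= 0))
  expect_true(all(pct >= 0 & pct <= 100))
})

test_that("FV percentage ignores intensities inside exclusion masks", {
  set.seed(7)
  n <- 64
  img <- matrix(rnorm(n^2, 100, 20), n, n)
  excl <- matrix(FALSE, n, n); excl[10:30, 10:30] <- TRUE
  roi <- matrix(TRUE, n, n)
  pct <- function(im) fv_percentage(binarize_fv(im, 80), roi, list(excl))
  img2 <- img
  img2[excl] <- runif(sum(excl), -1000, 1000)  # arbitrary perturbation
  expect_identical(pct(img), pct(img2))
})

test_that("2-degree band matches the brute-force distance rule", {
  g <- scan_geometry(grid_size_px = 48, field_of_view_mm = 48 * 12 / 1000)
  ga <- matrix(FALSE, 48, 48); ga[24, 24] <- TRUE
  band <- band_2deg(ga, g)
  width_px <- round(degrees_to_um(2, g) / g$pixel_size_um)  # 48
  bf <- brute_distance_map(ga)
  expect_identical(band, !ga & !is.na(bf) & bf > 0 & bf <= width_px)
  # multi-pixel lesion on a small grid
  g2 <- scan_geometry(grid_size_px = 64, field_of_view_mm = 64 * 12 / 1000)
  set.seed(8)
  ga2 <- disk_mask(64, 6, 20, 44)
  band2 <- band_2deg(ga2, g2)
  bf2 <- brute_distance_map(ga2)
  expect_identical(band2, !ga2 & !is.na(bf2) & bf2 > 0 & bf2 <= 48)
  expect_error(band_2deg(matrix(FALSE, 8, 8), g), "empty")
})

test_that("band width at default geometry is 48 px (about 571 um)", {
  g <- scan_geometry()
  width_px <- round(degrees_to_um(2, g) / g$pixel_size_um)
  expect_identical(width_px, 48)
  expect_equal(pixels_to_um(width_px, g), 576)
  expect_equal(round(degrees_to_um(2, g), 2), 571.43)
})

test_that("Gaussian FV blur preserves mass and range", {
  set.seed(9)
  fv <- matrix(runif(128^2) < 0.2, 128, 128)
  bl <- blur_fv(fv, 9)
  expect_true(all(bl >= 0 & bl <= 1))
  expect_equal(sum(bl), sum(fv), tolerance = 1e-6)  # normalized kernel
  # blur of a constant map is the constant
  expect_equal(blur_fv(matrix(TRUE, 32, 32), 5), matrix(1, 32, 32))
  expect_equal(blur_fv(matrix(FALSE, 32, 32), 5), matrix(0, 32, 32))
})

test_that("mask sets validate dimensions and nest the band in the ROI", {
  n <- 64
  g <- scan_geometry(grid_size_px = n, field_of_view_mm = n * 12 / 1000)
  ga <- disk_mask(n, 8)
  ms <- mask_set(fv = matrix(FALSE, n, n),
                 drusen_excl = matrix(FALSE, n, n),
                 projection_excl = matrix(FALSE, n, n),
                 baseline_ga = ga, geometry = g)
  expect_true(all(ms$roi_band2deg <= ms$roi_all))
  expect_false(any(ms$roi_all & ga))
  expect_error(mask_set(matrix(FALSE, n, n), matrix(FALSE, 2, 2),
                        matrix(FALSE, n, n), ga, g), "drusen_excl")
})
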