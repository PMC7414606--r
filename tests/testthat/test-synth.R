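test_that("normative database recovers the programmed intensity statistics", {
  p <- small_params(seed = 42)
  norm <- make_normative_db(20, p)
  n_pool <- 20 * 96^2
  # CLT bound on the pooled mean (3 sigma)
  expect_lt(abs(norm$mean - 100), 3 * 20 / sqrt(n_pool))
  expect_lt(abs(norm$sd - 20), 1)
  # near-degenerate noise: SD estimate collapses towards zero
  tiny <- make_normative_db(5, small_params(seed = 1, normal_sd = 1e-4))
  expect_lt(tiny$sd, 1e-3)
  # different seeds give different but compatible statistics
  n2 <- make_normative_db(20, small_params(seed = 43))
  expect_false(identical(norm$mean, n2$mean))
  se_mean <- 20 / sqrt(n_pool)
  expect_lt(abs(norm$mean - n2$mean), 6 * se_mean)
})

test_that("degenerate normative SD is reported as an error", {
  expect_error(normative_stats(100, 0), "degenerate")
  expect_error(make_normative_db(5, small_params(seed = 1, normal_sd = 0)),
               "degenerate")
})

test_that("atrophy is irreversible: follow-up GA contains baseline GA", {
  for (seed in 1:5) {
    sc <- make_eye_scene(small_params(seed), growth_law(), render = FALSE)
    expect_true(all(sc$truth$ga_followup[sc$truth$ga_baseline]))
  }
})

test_that("conversion table and rendered follow-up mask agree pixel-for-pixel", {
  sc <- make_eye_scene(small_params(7), growth_law(), render = FALSE)
  conv <- sc$truth$conversion
  idx <- cbind(conv$row, conv$col)
  expect_identical(as.integer(sc$truth$ga_followup[idx]), conv$converted)
  # pixels outside ring and baseline unchanged
  outside <- !sc$truth$ga_baseline
  outside[idx] <- FALSE
  expect_false(any(sc$truth$ga_followup[outside]))
})

test_that("a negligible conversion intercept freezes the lesion", {
  sc <- make_eye_scene(small_params(3), growth_law(beta0 = -30),
                       render = FALSE)
  expect_identical(sc$truth$ga_followup, sc$truth$ga_baseline)
})

test_that("with no FV effect, conversion is independent of FV", {
  sc <- make_eye_scene(recovery_params(11), growth_law(beta3 = 0),
                       render = FALSE)
  conv <- sc$truth$conversion
  # condition on distance via strata to remove the distance confound
  strata <- cut(conv$distance_px, c(0, 5, 10, 20, 40))
  p <- suppressWarnings(
    stats::mantelhaen.test(table(conv$fv, conv$converted, strata))$p.value)
  expect_gt(p, 0.001)
})

test_that("programmed conversion odds ratio is recovered from the truth table", {
  or_true <- 1.33
  # pool near-margin pixels of several scenes; 2x2 table at matched distance
  logors <- c()
  for (seed in 1:6) {
    sc <- make_eye_scene(recovery_params(seed), growth_law(beta3 = log(or_true)),
                         render = FALSE)
    conv <- sc$truth$conversion
    sel <- conv$distance_px > 2 & conv$distance_px <= 6  # narrow stratum
    t22 <- table(factor(conv$fv[sel], 0:1), factor(conv$converted[sel], 0:1))
    t22 <- t22 + 0.5  # Haldane-Anscombe correction for sparse cells
    logors <- c(logors, log((t22[2, 2] * t22[1, 1]) / (t22[2, 1] * t22[1, 2])))
  }
  se <- sd(logors) / sqrt(length(logors))
  expect_lt(abs(mean(logors) - log(or_true)), 3 * se + 0.05)
})

test_that("cohort layout matches the paired-eye study design", {
  coh <- make_cohort(seed = 5, params = small_params(), render = FALSE)
  expect_equal(nrow(coh$manifest), 12)
  expect_equal(length(unique(coh$manifest$patient_id)), 7)
  expect_true(all(coh$manifest$months_elapsed >= 7 &
                    coh$manifest$months_elapsed <= 16))
  expect_equal(sum(table(coh$manifest$patient_id) == 2), 5)
  expect_equal(sum(table(coh$manifest$patient_id) == 1), 2)
})

test_that("cohort generation is deterministic under a fixed seed", {
  c1 <- make_cohort(seed = 9, params = small_params(), render = FALSE)
  c2 <- make_cohort(seed = 9, params = small_params(), render = FALSE)
  expect_identical(c1$scenes[["P01_OD"]]$truth$conversion,
                   c2$scenes[["P01_OD"]]$truth$conversion)
  expect_identical(c1$manifest, c2$manifest)
  c3 <- make_cohort(seed = 10, params = small_params(), render = FALSE)
  expect_false(identical(c1$manifest$months_elapsed,
                         c3$manifest$months_elapsed))
})

test_that("between-patient severity induces within-patient correlation of FV", {
  dens <- function(coh) {
    m <- coh$manifest
    d <- vapply(coh$scenes, function(s) s$params$fv_patch_density, numeric(1))
    two_eye <- names(which(table(m$patient_id) == 2))
    sapply(two_eye, function(p) {
      ids <- m$eye_id[m$patient_id == p]
      d[ids]
    })
  }
  cors <- vapply(1:20, function(s) {
    coh <- make_cohort(n_patients = 8, eyes_per_patient = rep(2L, 8),
                       params = small_params(), between_sd = 1,
                       within_sd = 0.2, seed = 1000 + s, render = FALSE)
    d <- dens(coh)
    cor(d[1, ], d[2, ])
  }, numeric(1))
  expect_gt(mean(cors), 0.5)   # strong clustering when between >> within
})

test_that("GA touching the scan border is flagged", {
  p <- small_params(seed = 2, n = 64)
  p$ga_radius_px <- 45  # lesion overflows the 64 px grid
  sc <- make_eye_scene(p, growth_law(), render = FALSE)
  expect_true(sc$truth$border_flag)
  expect_false(make_eye_scene(small_params(1), growth_law(),
                              render = FALSE)$truth$border_flag)
})

test_that("written cohorts round-trip through the disk layout", {
  d <- withr::local_tempdir()
  coh <- make_cohort(n_patients = 2, eyes_per_patient = c(1L, 1L),
                     params = small_params(), seed = 3, render = TRUE,
                     dir = d)
  expect_true(file.exists(file.path(d, "manifest.yaml")))
  eye <- coh$manifest$eye_id[1]
  expect_true(file.exists(file.path(d, eye, "baseline", "cc_octa.tif")))
  gt <- read_csv_table(file.path(d, eye, "truth", "ground_truth.csv"))
  conv <- coh$scenes[[eye]]$truth$conversion
  expect_equal(nrow(gt), nrow(conv))
  expect_equal(gt$row, conv$row - 1L)  # 0-based on disk
  mask <- read_mask(file.path(d, eye, "truth", "ga_baseline.png"))
  expect_identical(mask, coh$scenes[[eye]]$truth$ga_baseline)
})
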