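#' Parameters of a synthetic en face scene
#'
#' Describes one synthetic eye: the normative choriocapillaris intensity
#' distribution, flow-void (FV) patch density and depth, geographic atrophy
#' (GA) focus count and size, drusen, and retinal vessels.  Intensities are
#' in arbitrary greyscale units (stored as 16-bit on disk).
#'
#' @param geometry A [scan_geometry()].
#' @param normal_mean,normal_sd Mean and SD of normal CC OCTA intensity.
#' @param fv_patch_density Fraction of pixels belonging to FV patches;
#'   either a single number in `[0, 1]` or a function of distance to the GA
#'   margin (px) returning such fractions, to emulate margin-dependent FV.
#' @param fv_depth Intensity drop inside FV patches, in units of
#'   `normal_sd`.
#' @param ga_foci Number of GA foci (1 = unifocal, >1 = multifocal).
#' @param ga_radius_px Mean radius of each GA focus, in pixels.
#' @param drusen_count Number of drusen bumps.
#' @param drusen_height_um Typical drusen peak elevation, um.
#' @param vessel_density Controls the number of rendered retinal vessel
#'   branches (fraction-like scale; default 0.04 gives about ten branches
#'   on a 500-px grid).
#' @param rng_seed Integer seed driving all randomness of the scene.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(geometry = scan_geometry(),
                         normal_mean = 100, normal_sd = 20,
                         fv_patch_density = 0.15, fv_depth = 2,
                         ga_foci = 2L, ga_radius_px = 60,
                         drusen_count = 12L, drusen_height_um = 40,
                         vessel_density = 0.04,
                         rng_seed = 1L) {
  stopifnot(is_scan_geometry(geometry))
  if (!is.function(fv_patch_density) &&
      (fv_patch_density < 0 || fv_patch_density > 1))
    stop("'fv_patch_density' must be in [0, 1] or a function of distance")
  if (normal_sd < 0) stop("'normal_sd' must be non-negative")
  if (ga_radius_px < 1) stop("'ga_radius_px' must be at least 1")
  if (vessel_density < 0 || vessel_density > 1)
    stop("'vessel_density' must be in [0, 1]")
  structure(list(geometry = geometry,
                 normal_mean = normal_mean, normal_sd = normal_sd,
                 fv_patch_density = fv_patch_density, fv_depth = fv_depth,
                 ga_foci = as.integer(ga_foci), ga_radius_px = ga_radius_px,
                 drusen_count = as.integer(drusen_count),
                 drusen_height_um = drusen_height_um,
                 vessel_density = vessel_density,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_params")
}

#' Logistic conversion law for GA growth
#'
#' Forward model of atrophy conversion: over one baseline-to-follow-up
#' interval, every non-atrophic pixel within `max_ring_px` of the GA margin
#' converts independently with probability
#' `plogis(beta0 + beta1 * d + beta2 * d^2 + beta3 * f)`, where `d` is the
#' distance to the margin in pixels and `f` the FV indicator at that pixel.
#' `exp(beta3)` is the ground-truth odds ratio of conversion for FV versus
#' non-FV pixels at equal distance.
#'
#' The default coefficients give a conversion probability declining from
#' about 0.9 at the margin to below 0.01 at 40 px, which at the default
#' scene size produces square-root-area growth rates around 21 um/month
#' over a typical one-year interval.
#'
#' @param beta0 Intercept (log-odds at the margin, non-FV).
#' @param beta1 Linear distance coefficient, per pixel.
#' @param beta2 Quadratic distance coefficient, per pixel squared.
#' @param beta3 Log odds ratio for the FV indicator.
#' @param max_ring_px Maximum distance (px) at which conversion can occur.
#' @return An object of class `growth_law`; `$odds_ratio` records
#'   `exp(beta3)`.
#' @export
growth_law <- function(beta0 = 2.0, beta1 = -0.25, beta2 = 0.0015,
                       beta3 = log(1.33), max_ring_px = 40) {
  stopifnot(max_ring_px >= 1)
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 max_ring_px = max_ring_px, odds_ratio = exp(beta3)),
            class = "growth_law")
}

conversion_probability <- function(law, d, f) {
  stats::plogis(law$beta0 + law$beta1 * d + law$beta2 * d^2 + law$beta3 * f)
}

#' Normative statistics of normal CC OCTA intensity
#'
#' @param mean,sd Mean and SD of normal CC OCTA intensity.
#' @param n_subjects Number of normal subjects pooled.
#' @return An object of class `normative_stats`.
#' @export
normative_stats <- function(mean, sd, n_subjects = NA_integer_) {
  if (!is.finite(sd) || sd <= 0) stop("degenerate SD (<= 0) in normative stats")
  structure(list(mean = mean, sd = sd, n_subjects = n_subjects),
            class = "normative_stats")
}

#' @export
print.normative_stats <- function(x, ...) {
  cat(sprintf("Normative CC OCTA intensity: mean %.4g, SD %.4g (n = %s)\n",
              x$mean, x$sd, x$n_subjects))
  invisible(x)
}

#' Simulate a normative database of normal eyes
#'
#' Draws `n_subjects` FV-free noise images around the scene's normal
#' intensity distribution, pools all pixels and returns their sample mean
#' and SD — the statistics that define the flow-void threshold
#' (mean minus one SD).
#'
#' @param n_subjects Number of normal subjects (default 20).
#' @param params A [scene_params()]; only the geometry and normal intensity
#'   fields are used.
#' @return A [normative_stats()].
#' @export
make_normative_db <- function(n_subjects = 20L, params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  if (n_subjects < 2) stop("'n_subjects' must be at least 2")
  set.seed(params$rng_seed)
  n_px <- params$geometry$grid_size_px^2
  pooled_mean <- 0; pooled_m2 <- 0; n_tot <- 0
  for (i in seq_len(n_subjects)) {
    img <- stats::rnorm(n_px, params$normal_mean, params$normal_sd)
    # streaming (Chan) update keeps memory flat for large grids
    m <- mean(img); m2 <- sum((img - m)^2)
    delta <- m - pooled_mean
    new_n <- n_tot + n_px
    pooled_mean <- pooled_mean + delta * n_px / new_n
    pooled_m2 <- pooled_m2 + m2 + delta^2 * n_tot * n_px / new_n
    n_tot <- new_n
  }
  sd_hat <- sqrt(pooled_m2 / (n_tot - 1))
  normative_stats(pooled_mean, sd_hat, n_subjects)
}

# Rasterize GA foci as smoothed random blobs: a disk whose radius is
# modulated by a low-frequency Fourier series in polar angle.
render_ga_blobs <- function(n, n_foci, radius_px) {
  ga <- matrix(FALSE, n, n)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  for (i in seq_len(n_foci)) {
    cx <- n / 2 + stats::runif(1, -n / 8, n / 8)
    cy <- n / 2 + stats::runif(1, -n / 8, n / 8)
    rad <- radius_px * stats::runif(1, 0.75, 1.25)
    amp <- stats::rnorm(3, 0, 0.08)
    phase <- stats::runif(3, 0, 2 * pi)
    dy <- rows - cy; dx <- cols - cx
    theta <- atan2(dy, dx)
    rtheta <- rad * (1 + amp[1] * cos(2 * theta + phase[1]) +
                       amp[2] * cos(3 * theta + phase[2]) +
                       amp[3] * cos(4 * theta + phase[3]))
    ga <- ga | (sqrt(dy^2 + dx^2) <= rtheta)
  }
  ga
}

# Clustered FV patches: threshold a smoothed Gaussian random field at the
# quantile that yields the requested density (possibly distance-dependent).
render_fv_patches <- function(n, density, dmap_px, smooth_sigma = 3) {
  z <- matrix(stats::rnorm(n * n), n, n)
  z <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(z),
                                                   sigma = smooth_sigma)))
  u <- matrix(rank(z, ties.method = "first") / (n * n + 1), n, n)
  d <- dmap_px
  d[is.na(d)] <- 0  # inside GA: irrelevant, give margin density
  dens <- if (is.function(density)) density(d) else density
  u > (1 - dens)
}

# Random-walk vessel branches of width 2-4 px.
render_vessel_tree <- function(n, vessel_density) {
  n_walks <- max(1L, round(vessel_density * n / 2))
  by_width <- list(`2` = matrix(FALSE, n, n), `3` = matrix(FALSE, n, n),
                   `4` = matrix(FALSE, n, n))
  for (w in seq_len(n_walks)) {
    side <- sample(4L, 1)
    pos <- switch(side,
                  c(1, stats::runif(1, 1, n)),
                  c(n, stats::runif(1, 1, n)),
                  c(stats::runif(1, 1, n), 1),
                  c(stats::runif(1, 1, n), n))
    ang <- atan2(n / 2 - pos[1], n / 2 - pos[2]) + stats::rnorm(1, 0, 0.3)
    width <- sample(2:4, 1)
    steps <- round(1.5 * n)
    path <- matrix(NA_real_, steps, 2)
    for (s in seq_len(steps)) {
      ang <- ang + stats::rnorm(1, 0, 0.12)
      pos <- pos + c(sin(ang), cos(ang))
      if (any(pos < 1) || any(pos > n)) break
      path[s, ] <- pos
    }
    path <- path[stats::complete.cases(path), , drop = FALSE]
    if (nrow(path) == 0) next
    idx <- unique(cbind(round(path[, 1]), round(path[, 2])))
    m <- by_width[[as.character(width)]]
    m[idx] <- TRUE
    by_width[[as.character(width)]] <- m
  }
  vessel <- matrix(FALSE, n, n)
  for (w in c(2, 3, 4)) {
    m <- by_width[[as.character(w)]]
    if (!any(m)) next
    brush <- EBImage::makeBrush(if (w %% 2 == 1) w else w + 1, shape = "disc")
    dil <- EBImage::dilate(EBImage::Image(m * 1), brush) > 0.5
    vessel <- vessel | as.matrix(dil)
  }
  vessel
}

# Gaussian drusen bumps outside GA; returns the elevation map in um.
render_drusen <- function(n, count, height_um, ga) {
  elev <- matrix(0, n, n)
  if (count == 0) return(elev)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  placed <- 0; attempts <- 0
  while (placed < count && attempts < 20 * count) {
    attempts <- attempts + 1
    cx <- stats::runif(1, 10, n - 10); cy <- stats::runif(1, 10, n - 10)
    if (ga[round(cy), round(cx)]) next
    r <- stats::runif(1, 4, 10)
    h <- height_um * stats::runif(1, 0.6, 1.4)
    d2 <- (rows - cy)^2 + (cols - cx)^2
    elev <- elev + h * exp(-d2 / (2 * (r / 2)^2))
    placed <- placed + 1
  }
  elev
}

# Shift a matrix by integer (dy, dx), filling exposed borders.
apply_shift <- function(m, dy, dx, fill = 0) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  src_r <- seq_len(n) - dy; src_c <- seq_len(p) - dx
  ok_r <- src_r >= 1 & src_r <= n; ok_c <- src_c >= 1 & src_c <= p
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

render_layers <- function(params, ga, fv, vessel, elev) {
  n <- params$geometry$grid_size_px
  mu <- params$normal_mean; s <- params$normal_sd
  cc <- matrix(stats::rnorm(n * n, mu, s), n, n)
  cc[fv] <- cc[fv] - params$fv_depth * s
  cc[vessel] <- cc[vessel] + 0.8 * s        # projection artifact
  cc <- cc * 50 / (50 + elev)               # drusen shadowing
  cc <- pmin(pmax(cc, 0), 65535)
  sub_rpe <- matrix(stats::rnorm(n * n, 18000, 2500), n, n)
  sub_rpe[ga] <- stats::rnorm(sum(ga), 45000, 2500)  # hyper-transmission
  sub_rpe <- pmin(pmax(sub_rpe, 0), 65535)
  inner <- matrix(stats::rnorm(n * n, 6000, 1500), n, n)
  inner[vessel] <- stats::rnorm(sum(vessel), 30000, 2000)
  inner <- pmin(pmax(inner, 0), 65535)
  list(cc_octa = cc, sub_rpe = sub_rpe, inner_retina_octa = inner)
}

#' Generate one synthetic visit pair with known ground truth
#'
#' Builds a baseline scene (GA foci, FV patches, drusen, vessels), grows
#' the GA to follow-up by the logistic conversion law, and renders both
#' visits' raster layers.  The follow-up layers are translated by a small
#' random integer shift (recoverable by [register_pair()]).  The returned
#' ground truth contains the exact masks and the per-pixel conversion
#' table.
#'
#' @param params A [scene_params()].
#' @param law A [growth_law()].
#' @param months_elapsed Months between visits (default 12).
#' @param render If `FALSE`, skip rendering of intensity layers (masks and
#'   conversion table only) — used by large simulation studies.
#' @param true_shift Integer `c(dy, dx)` applied to follow-up layers;
#'   `NULL` draws one uniformly from -5..5.
#' @return An object of class `eye_scene`: a list with `pair` (a
#'   [visit_pair()] when rendered, else `NULL`), `truth` (masks
#'   `ga_baseline`, `ga_followup`, `fv`, `vessel`, `drusen_elevation_um`,
#'   the `conversion` data.frame with columns `row`, `col`, `distance_px`,
#'   `fv`, `converted`, plus `true_shift` and `border_flag`), `params`,
#'   `law` and `months_elapsed`.
#' @export
make_eye_scene <- function(params = scene_params(), law = growth_law(),
                           months_elapsed = 12, render = TRUE,
                           true_shift = NULL) {
  stopifnot(inherits(params, "scene_params"), inherits(law, "growth_law"))
  set.seed(params$rng_seed)
  n <- params$geometry$grid_size_px
  ga <- render_ga_blobs(n, params$ga_foci, params$ga_radius_px)
  if (!any(ga)) stop("degenerate scene: no GA pixels generated")
  border_flag <- any(ga[1, ]) || any(ga[n, ]) || any(ga[, 1]) || any(ga[, n])
  dmap <- distance_map(ga)
  fv <- render_fv_patches(n, params$fv_patch_density, dmap)
  ring <- which(!ga & !is.na(dmap) & dmap <= law$max_ring_px)
  d <- dmap[ring]; f <- as.integer(fv[ring])
  p <- conversion_probability(law, d, f)
  converted <- stats::runif(length(ring)) < p
  ga_fu <- ga
  ga_fu[ring[converted]] <- TRUE
  conv <- data.frame(row = (ring - 1) %% n + 1,
                     col = (ring - 1) %/% n + 1,
                     distance_px = d, fv = f,
                     converted = as.integer(converted))
  elev <- render_drusen(n, params$drusen_count, params$drusen_height_um, ga)
  vessel <- render_vessel_tree(n, params$vessel_density)
  pair <- NULL
  if (render) {
    if (is.null(true_shift))
      true_shift <- sample(-5:5, 2, replace = TRUE)
    base_layers <- render_layers(params, ga, fv, vessel, elev)
    fu_layers <- render_layers(params, ga_fu, fv, vessel, elev)
    fu_layers <- lapply(fu_layers, apply_shift,
                        dy = true_shift[1], dx = true_shift[2])
    baseline <- eye_visit("synthetic", "right",
                          cc_octa = base_layers$cc_octa,
                          sub_rpe = base_layers$sub_rpe,
                          drusen_elevation_um = elev,
                          inner_retina_octa = base_layers$inner_retina_octa,
                          geometry = params$geometry)
    followup <- eye_visit("synthetic", "right",
                          cc_octa = fu_layers$cc_octa,
                          sub_rpe = fu_layers$sub_rpe,
                          drusen_elevation_um = apply_shift(elev, true_shift[1],
                                                            true_shift[2]),
                          inner_retina_octa = fu_layers$inner_retina_octa,
                          geometry = params$geometry)
    pair <- visit_pair(baseline, followup, months_elapsed)
  } else {
    true_shift <- c(0L, 0L)
  }
  structure(list(pair = pair,
                 truth = list(ga_baseline = ga, ga_followup = ga_fu,
                              fv = fv, vessel = vessel,
                              drusen_elevation_um = elev,
                              conversion = conv,
                              true_shift = true_shift,
                              border_flag = border_flag),
                 params = params, law = law,
                 months_elapsed = months_elapsed),
            class = "eye_scene")
}

#' Generate a synthetic cohort of visit pairs
#'
#' Emulates a longitudinal GA cohort: `n_patients` patients contributing
#' one or two eyes each, imaged at baseline and once 7 to 16 months later.
#' A patient-level latent severity shifts both the FV patch density and the
#' conversion intercept, inducing within-patient correlation and a positive
#' eye-level association between FV burden and growth.
#'
#' @param n_patients Number of patients (default 7).
#' @param eyes_per_patient Integer vector of 1s and 2s, one per patient
#'   (default five 2-eye and two 1-eye patients: 12 eyes from 7 patients).
#' @param params Baseline [scene_params()] shared by the cohort.
#' @param law Baseline [growth_law()].
#' @param between_sd SD of the patient-level latent severity.
#' @param within_sd SD of the eye-level severity deviation.
#' @param fv_coupling,growth_coupling Loadings of severity on the logit FV
#'   density and on the conversion intercept `beta0`.
#' @param months_range Range from which months between visits are drawn.
#' @param seed Integer master seed.
#' @param render Render intensity layers (disable for large simulations).
#' @param dir If non-`NULL`, write the full cohort layout (rasters,
#'   manifest, ground truth) under this directory.
#' @return An object of class `ccfv_cohort`: list with `manifest`
#'   (data.frame, one row per eye), `scenes` (named list of
#'   [make_eye_scene()] results), `geometry`, `params`, `law`, `seed`.
#' @export
make_cohort <- function(n_patients = 7L,
                        eyes_per_patient = NULL,
                        params = scene_params(), law = growth_law(),
                        between_sd = 1, within_sd = 0.4,
                        fv_coupling = 0.5, growth_coupling = 0.6,
                        months_range = c(7, 16),
                        seed = 1L, render = TRUE, dir = NULL) {
  if (n_patients < 2) stop("'n_patients' must be at least 2")
  if (is.null(eyes_per_patient)) {
    eyes_per_patient <- rep(2L, n_patients)
    if (n_patients >= 2) eyes_per_patient[seq_len(min(2, n_patients))] <- 1L
    eyes_per_patient <- rev(eyes_per_patient)
  }
  stopifnot(length(eyes_per_patient) == n_patients,
            all(eyes_per_patient %in% 1:2))
  set.seed(seed)
  n_eyes <- sum(eyes_per_patient)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n_eyes)
  base_dens <- if (is.function(params$fv_patch_density)) NULL else
    params$fv_patch_density
  manifest <- NULL; scenes <- list()
  k <- 0
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%02d", p)
    sev_p <- stats::rnorm(1, 0, between_sd)
    for (e in seq_len(eyes_per_patient[p])) {
      k <- k + 1
      eye <- if (e == 1) "right" else "left"
      eye_id <- paste0(pid, "_", ifelse(eye == "right", "OD", "OS"))
      sev <- sev_p + stats::rnorm(1, 0, within_sd)
      pp <- params
      if (!is.null(base_dens))
        pp$fv_patch_density <-
          stats::plogis(stats::qlogis(max(min(base_dens, 0.99), 0.01)) +
                          fv_coupling * sev)
      ll <- law
      ll$beta0 <- law$beta0 + growth_coupling * sev
      pp$rng_seed <- scene_seeds[k]
      months <- stats::runif(1, months_range[1], months_range[2])
      sc <- make_eye_scene(pp, ll, months_elapsed = months, render = render)
      if (render) {
        sc$pair$baseline$patient_id <- pid
        sc$pair$followup$patient_id <- pid
        sc$pair$baseline$eye <- eye
        sc$pair$followup$eye <- eye
      }
      scenes[[eye_id]] <- sc
      manifest <- rbind(manifest, data.frame(
        eye_id = eye_id, patient_id = pid, eye = eye,
        baseline_dir = file.path(eye_id, "baseline"),
        followup_dir = file.path(eye_id, "followup"),
        months_elapsed = months,
        signal_baseline = 10L, signal_followup = 10L,
        stringsAsFactors = FALSE))
    }
  }
  cohort <- structure(list(manifest = manifest, scenes = scenes,
                           geometry = params$geometry, params = params,
                           law = law, seed = seed),
                      class = "ccfv_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.ccfv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d eyes from %d patients (seed %d)\n",
              nrow(x$manifest), length(unique(x$manifest$patient_id)),
              x$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline layout
#'
#' Writes per-eye baseline/follow-up raster directories, ground-truth masks
#' and conversion tables, per-scene parameter files, and the cohort
#' manifest (`manifest.yaml`).
#'
#' @param cohort A [make_cohort()] result (rendered).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ccfv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (eye_id in names(cohort$scenes)) {
    sc <- cohort$scenes[[eye_id]]
    if (is.null(sc$pair))
      stop("cohort was generated with render = FALSE; nothing to write")
    eye_dir <- file.path(dir, eye_id)
    write_visit(sc$pair$baseline, file.path(eye_dir, "baseline"))
    write_visit(sc$pair$followup, file.path(eye_dir, "followup"))
    tdir <- file.path(eye_dir, "truth")
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    write_mask(sc$truth$ga_baseline, file.path(tdir, "ga_baseline.png"))
    write_mask(sc$truth$ga_followup, file.path(tdir, "ga_followup.png"))
    write_mask(sc$truth$fv, file.path(tdir, "fv.png"))
    conv <- sc$truth$conversion
    conv$row <- conv$row - 1L  # 0-based pixel indices on disk
    conv$col <- conv$col - 1L
    write_csv_table(conv, file.path(tdir, "ground_truth.csv"))
    yaml::write_yaml(list(
      rng_seed = sc$params$rng_seed,
      fv_patch_density = if (is.function(sc$params$fv_patch_density))
        "distance-dependent" else sc$params$fv_patch_density,
      ga_foci = sc$params$ga_foci,
      law = sc$law[c("beta0", "beta1", "beta2", "beta3", "max_ring_px",
                     "odds_ratio")],
      true_shift = as.integer(sc$truth$true_shift),
      border_flag = sc$truth$border_flag,
      months_elapsed = sc$months_elapsed
    ), file.path(tdir, "scene_params.yaml"))
  }
  write_manifest(cohort$manifest, cohort$geometry,
                 file.path(dir, "manifest.yaml"))
  invisible(dir)
}
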