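#' Geographic atrophy lesion
#'
#' @param mask Logical GA mask.
#' @param geometry A [scan_geometry()].
#' @return An object of class `ga_lesion` with `mask`, `area_mm2` (pixel
#'   count times squared pixel size), `n_foci` (8-connected components),
#'   `boundary` (logical mask of GA pixels 8-adjacent to non-GA pixels) and
#'   `border_flag` (lesion touches the scan border).
#' @export
ga_lesion <- function(mask, geometry = scan_geometry()) {
  stopifnot(is.matrix(mask), is.logical(mask))
  n <- nrow(mask)
  area_mm2 <- sum(mask) * (geometry$pixel_size_um / 1000)^2
  n_foci <- if (any(mask)) max(label_components(mask)) else 0L
  boundary <- ga_boundary(mask)
  border_flag <- any(mask) &&
    (any(mask[1, ]) || any(mask[n, ]) || any(mask[, 1]) || any(mask[, ncol(mask)]))
  structure(list(mask = mask, area_mm2 = area_mm2,
                 n_foci = as.integer(n_foci), boundary = boundary,
                 border_flag = border_flag, geometry = geometry),
            class = "ga_lesion")
}

#' @export
print.ga_lesion <- function(x, ...) {
  cat(sprintf("GA lesion: %.3f mm2, %d focus/foci%s\n", x$area_mm2, x$n_foci,
              if (x$border_flag) " [touches scan border]" else ""))
  invisible(x)
}

# GA pixels that are 8-adjacent to at least one non-GA pixel.
ga_boundary <- function(mask) {
  if (!any(mask)) return(mask)
  er <- as.matrix(EBImage::erode(EBImage::Image(mask * 1),
                                 EBImage::makeBrush(3, "box")) > 0.5)
  # erosion with a 3x3 box does not treat the image border as background;
  # lesion pixels on the border rim are boundary by convention
  b <- mask & !er
  b[1, ] <- mask[1, ]; b[nrow(mask), ] <- mask[nrow(mask), ]
  b[, 1] <- b[, 1] | mask[, 1]; b[, ncol(mask)] <- b[, ncol(mask)] | mask[, ncol(mask)]
  b
}

#' Segment GA from the sub-RPE en face structural image
#'
#' Atrophic regions appear bright on the sub-RPE slab (hyper-transmission).
#' The automatic segmentation thresholds the image (Otsu), applies
#' morphological closing with a 3-px disc, fills holes, and removes
#' components below a minimum area.  A user-supplied `override_mask`
#' (e.g., a manually corrected outline) is used verbatim instead.
#'
#' @param sub_rpe Numeric matrix, sub-RPE structural intensities.
#' @param override_mask Optional logical mask used verbatim.
#' @param min_area_mm2 Minimum component area retained (default 0.01).
#' @param geometry A [scan_geometry()].
#' @return A [ga_lesion()]; empty segmentations return an empty lesion
#'   with a warning.
#' @export
segment_ga <- function(sub_rpe, override_mask = NULL, min_area_mm2 = 0.01,
                       geometry = scan_geometry()) {
  if (!is.null(override_mask)) {
    stopifnot(is.matrix(override_mask), is.logical(override_mask))
    return(ga_lesion(override_mask, geometry))
  }
  stopifnot(is.matrix(sub_rpe))
  rng <- range(sub_rpe)
  if (rng[1] == rng[2]) {
    warning("uniform sub-RPE image: empty GA segmentation")
    return(ga_lesion(matrix(FALSE, nrow(sub_rpe), ncol(sub_rpe)), geometry))
  }
  scaled <- (sub_rpe - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  bw <- EBImage::Image((scaled > thr) * 1)
  brush <- EBImage::makeBrush(3, "disc")
  bw <- EBImage::closing(bw, brush)
  bw <- EBImage::fillHull(bw)
  mask <- as.matrix(bw) > 0.5
  if (any(mask)) {
    lab <- label_components(mask)
    areas_mm2 <- tabulate(lab[lab > 0]) * (geometry$pixel_size_um / 1000)^2
    mask <- matrix(lab %in% which(areas_mm2 >= min_area_mm2),
                   nrow(mask), ncol(mask))
  }
  if (!any(mask)) warning("GA segmentation is empty")
  ga_lesion(mask, geometry)
}

# Vessel mask for registration: Otsu threshold of the inner-retinal layer.
.vessel_mask <- function(img) {
  rng <- range(img)
  if (rng[1] == rng[2]) return(matrix(FALSE, nrow(img), ncol(img)))
  scaled <- (img - rng[1]) / (rng[2] - rng[1])
  scaled > EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
}

#' Register a follow-up visit to baseline by vessel landmarks
#'
#' Finds the integer translation (within `max_shift` pixels) that
#' maximizes the cross-correlation between the baseline and follow-up
#' retinal-vessel masks (computed by FFT on the mean-centred masks and
#' normalized by their global norms).  If either inner-retinal layer is
#' missing or the correlation peak is indistinct, a zero shift is returned
#' with a warning.
#'
#' @param baseline,followup [eye_visit()] objects.
#' @param max_shift Search window half-width in pixels (default 20).
#' @param min_peak Minimum normalized peak correlation considered reliable
#'   (default 0.1).
#' @return List with integer `dy`, `dx` — the estimated displacement of
#'   the follow-up image relative to baseline (apply `shift_visit(followup,
#'   -dy, -dx)` to align it), plus the `peak` correlation and logical
#'   `reliable`.
#' @export
register_pair <- function(baseline, followup, max_shift = 20,
                          min_peak = 0.1) {
  stopifnot(inherits(baseline, "eye_visit"), inherits(followup, "eye_visit"))
  if (is.null(baseline$inner_retina_octa) ||
      is.null(followup$inner_retina_octa)) {
    warning("inner-retinal layer missing; assuming zero shift")
    return(list(dy = 0L, dx = 0L, peak = NA_real_, reliable = FALSE))
  }
  a <- .vessel_mask(baseline$inner_retina_octa) * 1
  b <- .vessel_mask(followup$inner_retina_octa) * 1
  a <- a - mean(a); b <- b - mean(b)
  n <- nrow(a)
  # cross-correlation surface via FFT; entry (i, j) ~ shift (i-1, j-1) mod n
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / n^2
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom == 0) {
    warning("flat vessel masks; assuming zero shift")
    return(list(dy = 0L, dx = 0L, peak = NA_real_, reliable = FALSE))
  }
  cc <- cc / denom
  shifts <- c(0:max_shift, -(max_shift:1))
  idx <- ((shifts) %% n) + 1
  win <- cc[idx, idx]
  best <- arrayInd(which.max(win), dim(win))
  peak <- win[best]
  dy <- shifts[best[1]]; dx <- shifts[best[2]]
  if (peak < min_peak) {
    warning(sprintf("indistinct correlation peak (%.3f); assuming zero shift",
                    peak))
    return(list(dy = 0L, dx = 0L, peak = peak, reliable = FALSE))
  }
  list(dy = as.integer(-dy), dx = as.integer(-dx), peak = peak,
       reliable = TRUE)
}

#' Apply an integer shift to all raster layers of a visit
#'
#' @param visit An [eye_visit()].
#' @param dy,dx Integer shift (rows, columns).
#' @return The shifted [eye_visit()].
#' @export
shift_visit <- function(visit, dy, dx) {
  stopifnot(inherits(visit, "eye_visit"))
  for (nm in c("cc_octa", "sub_rpe", "drusen_elevation_um",
               "inner_retina_octa")) {
    if (!is.null(visit[[nm]]))
      visit[[nm]] <- apply_shift(visit[[nm]], dy, dx)
  }
  visit
}

#' Square-root-area GA growth rate
#'
#' The growth rate is the difference of the square roots of the follow-up
#' and baseline lesion areas, divided by the months elapsed — a metric
#' insensitive to baseline lesion size under constant radial expansion.
#' Square-root areas are reported in um (`sqrt(area_mm2) * 1000`), the
#' rate in um/month.
#'
#' @param pair A [visit_pair()].
#' @param baseline_lesion,followup_lesion [ga_lesion()] objects.
#' @return An object of class `growth_result` with
#'   `sqrt_area_baseline_um`, `sqrt_area_followup_um`, `months_elapsed`,
#'   `growth_rate_um_per_month` and the two areas in mm2.
#' @export
growth_rate <- function(pair, baseline_lesion, followup_lesion) {
  stopifnot(inherits(pair, "visit_pair"),
            inherits(baseline_lesion, "ga_lesion"),
            inherits(followup_lesion, "ga_lesion"))
  if (pair$months_elapsed <= 0) stop("'months_elapsed' must be positive")
  if (any(baseline_lesion$mask & !followup_lesion$mask))
    warning("follow-up GA mask is not a superset of baseline (atrophy regression?)")
  s0 <- sqrt(baseline_lesion$area_mm2) * 1000
  s1 <- sqrt(followup_lesion$area_mm2) * 1000
  structure(list(sqrt_area_baseline_um = s0, sqrt_area_followup_um = s1,
                 area_baseline_mm2 = baseline_lesion$area_mm2,
                 area_followup_mm2 = followup_lesion$area_mm2,
                 months_elapsed = pair$months_elapsed,
                 growth_rate_um_per_month = (s1 - s0) / pair$months_elapsed),
            class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat(sprintf("GA growth: %.3f -> %.3f mm2 over %.1f months = %.2f um/month\n",
              x$area_baseline_mm2, x$area_followup_mm2, x$months_elapsed,
              x$growth_rate_um_per_month))
  invisible(x)
}

#' Euclidean distance map to the GA boundary
#'
#' For every pixel outside the GA, the exact Euclidean distance (in
#' pixels, centre to centre) to the nearest GA pixel; for outside pixels
#' the nearest GA pixel always lies on the lesion boundary.  Pixels inside
#' the GA are `NA`.
#'
#' @param baseline_ga Non-empty logical GA mask.
#' @return Numeric matrix of distances (px), `NA` inside the GA.
#' @export
distance_map <- function(baseline_ga) {
  stopifnot(is.matrix(baseline_ga), is.logical(baseline_ga))
  if (!any(baseline_ga)) stop("empty GA mask: distance map undefined")
  d <- as.matrix(EBImage::imageData(
    EBImage::distmap(EBImage::Image((!baseline_ga) * 1),
                     metric = "euclidean")))
  d[baseline_ga] <- NA_real_
  d
}

#' Ring region of interest around the GA margin
#'
#' Pixels with distance `0 < d <= max_px` from the GA boundary, outside
#' the baseline GA and all exclusion masks.
#'
#' @param dmap Distance map from [distance_map()].
#' @param max_px Outer ring distance in pixels (conventionally 40, 60 or
#'   80).
#' @param exclusions List of logical exclusion masks.
#' @return Logical ring mask; an empty ring is an error.
#' @export
ring_roi <- function(dmap, max_px = 40, exclusions = list()) {
  stopifnot(is.matrix(dmap), max_px > 0)
  ring <- !is.na(dmap) & dmap > 0 & dmap <= max_px
  for (ex in exclusions) {
    stopifnot(all(dim(ex) == dim(dmap)))
    ring <- ring & !ex
  }
  if (!any(ring)) stop("ring ROI is empty: no pixels to model")
  ring
}
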