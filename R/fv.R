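#' Compensate the CC OCTA slab for RPE/BM shadowing
#'
#' Shadowing by the RPE/Bruch's-membrane complex attenuates both the
#' structural and the angiographic signal of the choriocapillaris slab.
#' The compensation rescales each OCTA pixel by the ratio of a reference
#' structural level to the locally smoothed structural intensity, with the
#' gain clipped to a configurable range so that noise-floor pixels are not
#' amplified without bound.
#'
#' @param cc_octa Numeric matrix, en face CC OCTA intensities.
#' @param sub_rpe_structure Numeric matrix of the same size, structural
#'   intensities of the same slab.
#' @param smooth_px Side of the square mean filter applied to the
#'   structural image before taking the ratio (default 5 px).
#' @param clip Length-2 numeric, allowed gain range (default `c(0.5, 2)`).
#' @param reference Reference structural level; default is the mean of the
#'   smoothed structural image.
#' @return Compensated OCTA matrix, same dimensions.
#' @export
compensate <- function(cc_octa, sub_rpe_structure, smooth_px = 5,
                       clip = c(0.5, 2), reference = NULL) {
  stopifnot(is.matrix(cc_octa), is.matrix(sub_rpe_structure))
  if (!all(dim(cc_octa) == dim(sub_rpe_structure)))
    stop("'cc_octa' and 'sub_rpe_structure' must have identical dimensions")
  if (all(sub_rpe_structure == 0))
    stop("all-zero structural image: compensation undefined")
  stopifnot(length(clip) == 2, clip[1] > 0, clip[2] >= clip[1])
  k <- matrix(1 / smooth_px^2, smooth_px, smooth_px)
  smoothed <- as.matrix(EBImage::imageData(
    EBImage::filter2(EBImage::Image(sub_rpe_structure), k)))
  if (is.null(reference)) reference <- mean(smoothed)
  gain <- reference / pmax(smoothed, .Machine$double.eps)
  gain <- pmin(pmax(gain, clip[1]), clip[2])
  cc_octa * gain
}

#' Flow-void intensity threshold from normative statistics
#'
#' The FV threshold is `k_sd` standard deviations below the normative mean
#' CC OCTA intensity (default one SD).
#'
#' @param norm A [normative_stats()].
#' @param k_sd Number of SDs below the mean (default 1).
#' @return The intensity threshold.
#' @examples
#' fv_threshold(normative_stats(100, 20))  # 80
#' @export
fv_threshold <- function(norm, k_sd = 1) {
  stopifnot(inherits(norm, "normative_stats"))
  norm$mean - k_sd * norm$sd
}

#' Binarize a compensated OCTA image into a flow-void map
#'
#' A pixel is a flow void iff its intensity is strictly below the
#' threshold; ties at the threshold are not FV.
#'
#' @param compensated Numeric intensity matrix.
#' @param threshold Finite intensity threshold.
#' @return Logical matrix of FV pixels.
#' @export
binarize_fv <- function(compensated, threshold) {
  stopifnot(is.matrix(compensated), is.finite(threshold) || threshold == -Inf)
  compensated < threshold
}

# 8-connected component labelling.  EBImage::bwlabel is 4-connected, so
# 4-connected labels that touch diagonally are merged with a union-find.
label_components <- function(mask) {
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1))))
  n_lab <- max(lab)
  if (n_lab <= 1) return(lab)
  parent <- seq_len(n_lab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (off in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(nr - 1), if (off[2] == 1) seq_len(nc - 1) else 2:nc]
    b <- lab[2:nr, if (off[2] == 1) 2:nc else seq_len(nc - 1)]
    sel <- which(a > 0 & b > 0 & a != b)
    for (s in sel) {
      ra <- find(a[s]); rb <- find(b[s])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n_lab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Drusen exclusion mask from an elevation map
#'
#' Thresholds the RPE elevation map at `height_cut_um`, labels connected
#' components, and keeps those whose equivalent diameter
#' `2 * sqrt(area_px / pi) * pixel_size_um` exceeds `min_diameter_um`
#' (drusen are defined as localized pigment-epithelial elevations larger
#' than 25 um across).
#'
#' @param elevation_um Non-negative numeric matrix of elevation in um.
#' @param height_cut_um Elevation threshold in um (default 15; not a
#'   literature constant — configurable).
#' @param min_diameter_um Minimum equivalent diameter in um (default 25).
#' @param geometry A [scan_geometry()].
#' @return Logical exclusion mask.
#' @export
drusen_exclusion <- function(elevation_um, height_cut_um = 15,
                             min_diameter_um = 25,
                             geometry = scan_geometry()) {
  stopifnot(is.matrix(elevation_um))
  if (any(elevation_um < 0)) stop("'elevation_um' must be non-negative")
  bw <- elevation_um >= height_cut_um
  if (!any(bw)) return(bw)
  lab <- label_components(bw)
  areas <- tabulate(lab[lab > 0])
  eq_diam_um <- 2 * sqrt(areas / pi) * geometry$pixel_size_um
  keep <- which(eq_diam_um > min_diameter_um)
  matrix(lab %in% keep, nrow(bw), ncol(bw))
}

#' Projection-artifact exclusion mask from the inner-retinal angiogram
#'
#' Retinal vessels replicate onto the CC slab as projection artifacts.
#' The vessel mask is obtained by automatic (Otsu) thresholding of the
#' inner-retinal en face OCTA image, then dilated by one pixel.
#'
#' @param inner_retina_octa Numeric matrix, or `NULL` (returns an empty
#'   mask of size `grid_size_px` with a warning).
#' @param geometry A [scan_geometry()], used only when the layer is
#'   missing.
#' @return Logical exclusion mask.
#' @export
projection_exclusion <- function(inner_retina_octa,
                                 geometry = scan_geometry()) {
  if (is.null(inner_retina_octa)) {
    warning("inner-retinal layer missing; projection exclusion mask empty")
    n <- geometry$grid_size_px
    return(matrix(FALSE, n, n))
  }
  stopifnot(is.matrix(inner_retina_octa))
  rng <- range(inner_retina_octa)
  if (rng[1] == rng[2])
    return(matrix(FALSE, nrow(inner_retina_octa), ncol(inner_retina_octa)))
  scaled <- (inner_retina_octa - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  vessel <- scaled > thr
  brush <- EBImage::makeBrush(3, shape = "box")  # one-pixel dilation
  as.matrix(EBImage::dilate(EBImage::Image(vessel * 1), brush) > 0.5)
}

#' Flow-void percentage within a region of interest
#'
#' The FV percentage is `100 * |fv intersect roi_eff| / |roi_eff|`, where
#' the effective ROI is the ROI minus all exclusion masks (drusen,
#' projection artifacts, baseline GA).
#'
#' @param fv Logical FV map.
#' @param roi Logical region-of-interest mask.
#' @param exclusions List of logical exclusion masks (possibly empty).
#' @return FV percentage in `[0, 100]`.
#' @export
fv_percentage <- function(fv, roi, exclusions = list()) {
  stopifnot(is.matrix(fv), is.matrix(roi), all(dim(fv) == dim(roi)))
  roi_eff <- roi
  for (ex in exclusions) {
    stopifnot(all(dim(ex) == dim(roi)))
    roi_eff <- roi_eff & !ex
  }
  n_roi <- sum(roi_eff)
  if (n_roi == 0) stop("effective ROI is empty: FV percentage undefined")
  100 * sum(fv & roi_eff) / n_roi
}

#' Annular band of given angular width around the GA margin
#'
#' Returns the pixels outside the GA whose Euclidean distance to the GA
#' boundary is at most the band width converted to pixels
#' (`round(degrees_to_um(width_deg) / pixel_size_um)`; 48 px, about
#' 571 um, for the default 2 degrees at 3.5 deg/mm and 12 um/px).
#'
#' @param baseline_ga Non-empty logical GA mask.
#' @param geometry A [scan_geometry()].
#' @param width_deg Angular band width in degrees (default 2).
#' @return Logical band mask.
#' @export
band_2deg <- function(baseline_ga, geometry = scan_geometry(),
                      width_deg = 2) {
  stopifnot(is.matrix(baseline_ga), is.logical(baseline_ga))
  if (!any(baseline_ga)) stop("empty GA mask: band undefined")
  width_px <- round(degrees_to_um(width_deg, geometry) /
                      geometry$pixel_size_um)
  d <- distance_map(baseline_ga)
  !baseline_ga & !is.na(d) & d > 0 & d <= width_px
}

#' Gaussian blur of a binary flow-void map
#'
#' Applies a Gaussian filter with sigma equal to `radius_px` (kernel
#' truncated at three sigma) to the {0,1} FV map, yielding a continuous
#' local FV fraction in `[0, 1]`.  At the default 9 px on a 500-px grid the
#' radius is about 2% of the image size.
#'
#' @param fv Logical FV map.
#' @param radius_px Blur radius, interpreted as the Gaussian sigma in
#'   pixels (default 9).
#' @return Numeric matrix in `[0, 1]`.
#' @export
blur_fv <- function(fv, radius_px = 9) {
  stopifnot(is.matrix(fv), radius_px > 0)
  img <- EBImage::Image(fv * 1)
  out <- as.matrix(EBImage::imageData(EBImage::gblur(img, sigma = radius_px)))
  pmin(pmax(out, 0), 1)
}

#' Assemble the full mask set for one eye
#'
#' Combines the binarized FV map, exclusion masks and ROIs (whole scan
#' minus exclusions minus GA; 2-degree band) into one validated container.
#'
#' @param fv Logical FV map.
#' @param drusen_excl,projection_excl,baseline_ga Logical exclusion masks.
#' @param geometry A [scan_geometry()].
#' @return An object of class `mask_set` with fields `fv`, `drusen_excl`,
#'   `projection_excl`, `baseline_ga`, `roi_all`, `roi_band2deg`.
#' @export
mask_set <- function(fv, drusen_excl, projection_excl, baseline_ga,
                     geometry = scan_geometry()) {
  masks <- list(fv = fv, drusen_excl = drusen_excl,
                projection_excl = projection_excl, baseline_ga = baseline_ga)
  dims <- dim(fv)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.matrix(m) || !is.logical(m) || !all(dim(m) == dims))
      stop(sprintf("mask '%s' must be a logical matrix of matching size", nm))
  }
  excl <- drusen_excl | projection_excl | baseline_ga
  roi_all <- !excl
  roi_band <- if (any(baseline_ga))
    band_2deg(baseline_ga, geometry) & roi_all
  else matrix(FALSE, dims[1], dims[2])
  structure(c(masks, list(roi_all = roi_all, roi_band2deg = roi_band)),
            class = "mask_set")
}

#' Flow-void masks and percentages for one visit
#'
#' Runs the per-eye FV stage: compensation, normative thresholding,
#' exclusion masks, and FV percentages over the whole-scan ROI and the
#' 2-degree band.
#'
#' @param visit An [eye_visit()] (baseline).
#' @param norm A [normative_stats()].
#' @param baseline_ga Logical GA mask for this eye.
#' @param k_sd SDs below the normative mean defining the threshold.
#' @param height_cut_um Drusen elevation cut (um).
#' @param use_compensation Apply shadow compensation before thresholding
#'   (default `TRUE`).
#' @return A list with the `mask_set`, the compensated image, the
#'   threshold, and a one-row `summary` data.frame (`fv_pct_all`,
#'   `fv_pct_band2deg`, `n_roi_px`, `n_band_px`, `n_drusen_px`,
#'   `n_projection_px`, `n_ga_px`).
#' @export
fv_analysis <- function(visit, norm, baseline_ga, k_sd = 1,
                        height_cut_um = 15, use_compensation = TRUE) {
  stopifnot(inherits(visit, "eye_visit"), inherits(norm, "normative_stats"))
  comp <- if (use_compensation)
    compensate(visit$cc_octa, visit$sub_rpe) else visit$cc_octa
  thr <- fv_threshold(norm, k_sd)
  fv <- binarize_fv(comp, thr)
  drusen <- if (is.null(visit$drusen_elevation_um))
    matrix(FALSE, nrow(fv), ncol(fv))
  else drusen_exclusion(visit$drusen_elevation_um, height_cut_um,
                        geometry = visit$geometry)
  proj <- if (is.null(visit$inner_retina_octa))
    matrix(FALSE, nrow(fv), ncol(fv))
  else projection_exclusion(visit$inner_retina_octa, visit$geometry)
  ms <- mask_set(fv, drusen, proj, baseline_ga, visit$geometry)
  excl <- list(ms$drusen_excl, ms$projection_excl, ms$baseline_ga)
  pct_all <- fv_percentage(ms$fv, ms$roi_all, list())
  pct_band <- if (any(ms$roi_band2deg))
    fv_percentage(ms$fv, ms$roi_band2deg, list()) else NA_real_
  list(masks = ms, compensated = comp, threshold = thr,
       summary = data.frame(
         fv_pct_all = pct_all, fv_pct_band2deg = pct_band,
         n_roi_px = sum(ms$roi_all), n_band_px = sum(ms$roi_band2deg),
         n_drusen_px = sum(ms$drusen_excl),
         n_projection_px = sum(ms$projection_excl),
         n_ga_px = sum(ms$baseline_ga)))
}
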