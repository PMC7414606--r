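#' A single eye at a single visit
#'
#' Bundles the en face raster layers acquired for one eye at one visit with
#' its metadata.  All raster layers are numeric matrices on the same grid:
#' the choriocapillaris (CC) OCTA slab, the sub-RPE structural slab used for
#' GA delineation, and optionally a drusen elevation map (um) and an
#' inner-retinal OCTA slab used for projection-artifact removal and vessel
#' landmark registration.
#'
#' @param patient_id Opaque patient identifier (string).
#' @param eye `"left"` or `"right"`.
#' @param cc_octa Numeric matrix, en face CC OCTA intensities.
#' @param sub_rpe Numeric matrix, en face sub-RPE structural intensities.
#' @param drusen_elevation_um Optional non-negative numeric matrix of RPE
#'   elevation in um.
#' @param inner_retina_octa Optional numeric matrix, inner-retinal en face
#'   OCTA.
#' @param signal_strength Integer 0-10, the device quality index.
#' @param visit_date Optional `Date` (or string coercible to one).
#' @param geometry A [scan_geometry()] shared by all layers.
#'
#' @return An object of class `eye_visit`.
#' @export
eye_visit <- function(patient_id, eye = c("right", "left"),
                      cc_octa, sub_rpe,
                      drusen_elevation_um = NULL,
                      inner_retina_octa = NULL,
                      signal_strength = 10L,
                      visit_date = NULL,
                      geometry = scan_geometry()) {
  eye <- match.arg(eye)
  stopifnot(is_scan_geometry(geometry), is.matrix(cc_octa), is.matrix(sub_rpe))
  n <- geometry$grid_size_px
  layers <- list(cc_octa = cc_octa, sub_rpe = sub_rpe,
                 drusen_elevation_um = drusen_elevation_um,
                 inner_retina_octa = inner_retina_octa)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (is.null(l)) next
    if (!is.matrix(l) || !all(dim(l) == c(n, n)))
      stop(sprintf("layer '%s' must be a %d x %d matrix matching the geometry",
                   nm, n, n))
  }
  if (!is.null(drusen_elevation_um) && any(drusen_elevation_um < 0))
    stop("'drusen_elevation_um' must be non-negative")
  if (!is.numeric(signal_strength) || length(signal_strength) != 1 ||
      signal_strength < 0 || signal_strength > 10)
    stop("'signal_strength' must be a single value in [0, 10]")
  if (!is.null(visit_date)) visit_date <- as.Date(visit_date)
  structure(list(
    patient_id = as.character(patient_id), eye = eye,
    visit_date = visit_date,
    cc_octa = cc_octa, sub_rpe = sub_rpe,
    drusen_elevation_um = drusen_elevation_um,
    inner_retina_octa = inner_retina_octa,
    signal_strength = as.integer(signal_strength),
    geometry = geometry
  ), class = "eye_visit")
}

#' @export
print.eye_visit <- function(x, ...) {
  cat(sprintf("Eye visit: patient %s, %s eye%s, signal strength %d\n",
              x$patient_id, x$eye,
              if (is.null(x$visit_date)) "" else paste0(", ", x$visit_date),
              x$signal_strength))
  cat(sprintf("  layers: cc_octa, sub_rpe%s%s (%d x %d px)\n",
              if (is.null(x$drusen_elevation_um)) "" else ", drusen_elevation_um",
              if (is.null(x$inner_retina_octa)) "" else ", inner_retina_octa",
              x$geometry$grid_size_px, x$geometry$grid_size_px))
  invisible(x)
}

# Average Gregorian month length in days, used when months are derived from
# calendar dates rather than supplied directly.
DAYS_PER_MONTH <- 30.4375

#' Pair a baseline and follow-up visit of the same eye
#'
#' @param baseline,followup [eye_visit()] objects for the same patient and
#'   eye.
#' @param months_elapsed Positive number of months between visits.  If
#'   `NULL`, computed from the visit dates as `days / 30.4375`.
#' @return An object of class `visit_pair`.
#' @export
visit_pair <- function(baseline, followup, months_elapsed = NULL) {
  stopifnot(inherits(baseline, "eye_visit"), inherits(followup, "eye_visit"))
  if (baseline$patient_id != followup$patient_id || baseline$eye != followup$eye)
    stop("baseline and follow-up must be the same patient and eye")
  if (is.null(months_elapsed)) {
    if (is.null(baseline$visit_date) || is.null(followup$visit_date))
      stop("'months_elapsed' must be given when visit dates are missing")
    months_elapsed <-
      as.numeric(followup$visit_date - baseline$visit_date) / DAYS_PER_MONTH
  }
  if (!is.finite(months_elapsed) || months_elapsed <= 0)
    stop("'months_elapsed' must be strictly positive")
  structure(list(baseline = baseline, followup = followup,
                 months_elapsed = as.numeric(months_elapsed)),
            class = "visit_pair")
}

#' Quality-control gate on signal strength
#'
#' Accepts a visit if and only if its device signal strength is at least
#' `min_signal` (scans with signal strength below 7 are conventionally
#' excluded).
#'
#' @param visit An [eye_visit()].
#' @param min_signal Minimum acceptable signal strength (default 7).
#' @return A list with logical `accept` and a `reason` string naming the
#'   failing check (`""` when accepted).
#' @examples
#' v <- eye_visit("p1", "right",
#'                matrix(0, 10, 10), matrix(0, 10, 10),
#'                signal_strength = 6,
#'                geometry = scan_geometry(grid_size_px = 10))
#' qc_gate(v)$accept  # FALSE
#' @export
qc_gate <- function(visit, min_signal = 7L) {
  stopifnot(inherits(visit, "eye_visit"))
  if (visit$signal_strength < min_signal) {
    list(accept = FALSE,
         reason = sprintf("signal_strength %d below minimum %d",
                          visit$signal_strength, as.integer(min_signal)))
  } else {
    list(accept = TRUE, reason = "")
  }
}
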