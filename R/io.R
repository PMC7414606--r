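#' Raster and table input/output
#'
#' Intensity grids are held in memory as numeric matrices of integers in
#' `[0, 65535]` and written to disk as 16-bit greyscale TIFF (the
#' preferred format, round-tripping losslessly).  PNG rasters are
#' supported for 8-bit data (values in `[0, 255]`, the format's limit
#' here); binary masks are written as 8-bit PNG/TIFF with values {0, 255}
#' and round-trip exactly.
#'
#' @param x Numeric matrix of intensities in `[0, 65535]` (`write_raster`)
#'   or logical matrix (`write_mask`).
#' @param path File path; format chosen by extension (`.tif`/`.tiff` or
#'   `.png`).
#' @return `read_raster` returns a numeric matrix of integers in
#'   `[0, 65535]`; `read_mask` a logical matrix.  The writers return `path`
#'   invisibly.
#' @name raster_io
NULL

.raster_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "png") return("png")
  stop(sprintf("unsupported raster format '%s' (use tif/tiff or png)", ext))
}

#' @rdname raster_io
#' @export
write_raster <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 65535))
    stop("intensities must be finite and within [0, 65535]")
  fmt <- .raster_format(path)
  if (fmt == "tiff") {
    tiff::writeTIFF(round(x) / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else {
    if (any(x > 255))
      stop("PNG rasters are written as 8-bit; use TIFF for 16-bit data")
    png::writePNG(round(x) / 255, path)
  }
  invisible(path)
}

#' @rdname raster_io
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read raster '%s'", path))
  fmt <- .raster_format(path)
  img <- switch(fmt, tiff = tiff::readTIFF(path), png = png::readPNG(path))
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * if (fmt == "tiff") 65535 else 255)
}

#' @rdname raster_io
#' @export
write_mask <- function(x, path) {
  stopifnot(is.matrix(x), is.logical(x))
  m <- matrix(as.numeric(x), nrow(x), ncol(x))
  switch(.raster_format(path),
         tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L,
                                compression = "none"),
         png = png::writePNG(m, path))
  invisible(path)
}

#' @rdname raster_io
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read mask '%s'", path))
  img <- switch(.raster_format(path),
                tiff = tiff::readTIFF(path),
                png = png::readPNG(path))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write or read a data table as CSV with a header row
#'
#' @param df A data.frame.
#' @param path CSV file path.
#' @return `read_csv_table` returns a data.frame.
#' @export
write_csv_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_csv_table
#' @export
read_csv_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read table '%s'", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read one eye visit from raster files
#'
#' @param cc_octa,sub_rpe Paths to the required intensity layers.
#' @param drusen_elevation_um,inner_retina_octa Optional layer paths.  The
#'   drusen layer stores elevation in um directly (one grey level = 1 um).
#' @inheritParams eye_visit
#' @return An [eye_visit()].
#' @export
read_visit <- function(patient_id, eye, cc_octa, sub_rpe,
                       drusen_elevation_um = NULL,
                       inner_retina_octa = NULL,
                       signal_strength = 10L, visit_date = NULL,
                       geometry = scan_geometry()) {
  rd <- function(p) if (is.null(p)) NULL else read_raster(p)
  eye_visit(patient_id, eye,
            cc_octa = read_raster(cc_octa),
            sub_rpe = read_raster(sub_rpe),
            drusen_elevation_um = rd(drusen_elevation_um),
            inner_retina_octa = rd(inner_retina_octa),
            signal_strength = signal_strength, visit_date = visit_date,
            geometry = geometry)
}

#' Write one eye visit's raster layers to a directory
#'
#' Layers are written as 16-bit TIFF files named `cc_octa.tif`,
#' `sub_rpe.tif`, `drusen_elevation_um.tif` and `inner_retina_octa.tif`.
#'
#' @param visit An [eye_visit()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written layer paths, invisibly.
#' @export
write_visit <- function(visit, dir) {
  stopifnot(inherits(visit, "eye_visit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in c("cc_octa", "sub_rpe", "drusen_elevation_um",
               "inner_retina_octa")) {
    if (is.null(visit[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tif"))
    write_raster(pmin(pmax(visit[[nm]], 0), 65535), p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Write or read a cohort manifest
#'
#' The manifest is a YAML file listing the scan geometry and, for every
#' eye, the patient id, laterality, per-visit directories, visit dates,
#' months elapsed and signal strengths.
#'
#' @param manifest A data.frame with one row per eye: columns `eye_id`,
#'   `patient_id`, `eye`, `baseline_dir`, `followup_dir`, `months_elapsed`,
#'   `signal_baseline`, `signal_followup`.
#' @param geometry The cohort [scan_geometry()].
#' @param path YAML file path.
#' @return `read_manifest` returns a list with elements `geometry` and
#'   `eyes` (the manifest data.frame).
#' @export
write_manifest <- function(manifest, geometry, path) {
  stopifnot(is.data.frame(manifest), is_scan_geometry(geometry))
  doc <- list(
    geometry = list(field_of_view_mm = geometry$field_of_view_mm,
                    grid_size_px = geometry$grid_size_px,
                    degrees_per_mm = geometry$degrees_per_mm),
    months_convention = "calendar months or days/30.4375 when dates given",
    eyes = lapply(seq_len(nrow(manifest)),
                  function(i) as.list(manifest[i, , drop = FALSE]))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read manifest '%s'", path))
  doc <- yaml::read_yaml(path)
  g <- doc$geometry
  geometry <- scan_geometry(g$field_of_view_mm, g$grid_size_px,
                            g$degrees_per_mm)
  eyes <- do.call(rbind, lapply(doc$eyes, function(e)
    as.data.frame(e, stringsAsFactors = FALSE)))
  list(geometry = geometry, eyes = eyes)
}
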