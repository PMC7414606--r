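#' Pipeline configuration
#'
#' Fully defaulted configuration for the end-to-end analysis.  Defaults
#' marked (fixed) implement the published measurement conventions; the
#' rest are implementation choices exposed for sensitivity analysis.
#'
#' @param k_sd SDs below the normative mean defining the FV threshold
#'   (fixed: 1).
#' @param height_cut_um Drusen elevation cut in um (choice: 15).
#' @param min_diameter_um Minimum drusen equivalent diameter in um
#'   (fixed: 25).
#' @param min_area_mm2 Minimum GA component area in mm2 (choice: 0.01).
#' @param ring_px Outer ring distance for the conversion model (fixed
#'   primary: 40).
#' @param degree Distance polynomial order (2 = primary).
#' @param use_blur Use the blurred FV predictor instead of the binary
#'   indicator.
#' @param blur_radius_px Gaussian blur radius in px (fixed: 9).
#' @param min_signal Minimum signal strength (fixed: 7).
#' @param band_deg Angular width of the near-margin band (fixed: 2).
#' @param use_compensation Apply shadow compensation before thresholding.
#' @param allow_border Include eyes whose GA touches the scan border
#'   (default `FALSE`).
#' @param normative List with `mean` and `sd`, or `NULL` to simulate a
#'   20-subject normative database from the scene parameters.
#' @param seed Seed for Monte-Carlo permutation p-values and the simulated
#'   normative database.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k_sd = 1, height_cut_um = 15,
                            min_diameter_um = 25, min_area_mm2 = 0.01,
                            ring_px = 40L, degree = 2L, use_blur = FALSE,
                            blur_radius_px = 9, min_signal = 7L,
                            band_deg = 2, use_compensation = TRUE,
                            allow_border = FALSE, normative = NULL,
                            seed = 20200603L) {
  structure(list(k_sd = k_sd, height_cut_um = height_cut_um,
                 min_diameter_um = min_diameter_um,
                 min_area_mm2 = min_area_mm2, ring_px = as.integer(ring_px),
                 degree = as.integer(degree), use_blur = use_blur,
                 blur_radius_px = blur_radius_px,
                 min_signal = as.integer(min_signal), band_deg = band_deg,
                 use_compensation = use_compensation,
                 allow_border = allow_border, normative = normative,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, doc)
}

# Analyse one eye: register, segment, quantify FV, build the conversion
# table.  Returns NULL (with a message) when the eye is excluded.
analyze_eye <- function(pair, norm, config, eye_id = "eye",
                        override_baseline_ga = NULL,
                        override_followup_ga = NULL) {
  for (which in c("baseline", "followup")) {
    gate <- qc_gate(pair[[which]], config$min_signal)
    if (!gate$accept) {
      message(sprintf("eye %s excluded (%s visit): %s", eye_id, which,
                      gate$reason))
      return(NULL)
    }
  }
  reg <- register_pair(pair$baseline, pair$followup)
  followup <- shift_visit(pair$followup, -reg$dy, -reg$dx)
  geometry <- pair$baseline$geometry
  base_lesion <- segment_ga(pair$baseline$sub_rpe, override_baseline_ga,
                            config$min_area_mm2, geometry)
  fu_lesion <- segment_ga(followup$sub_rpe, override_followup_ga,
                          config$min_area_mm2, geometry)
  if (!any(base_lesion$mask)) {
    message(sprintf("eye %s excluded: empty baseline GA segmentation", eye_id))
    return(NULL)
  }
  if (base_lesion$border_flag && !config$allow_border) {
    message(sprintf(
      "eye %s excluded: GA extends to the scan border (set allow_border)",
      eye_id))
    return(NULL)
  }
  fvres <- fv_analysis(pair$baseline, norm, base_lesion$mask,
                       k_sd = config$k_sd,
                       height_cut_um = config$height_cut_um,
                       use_compensation = config$use_compensation)
  growth <- growth_rate(pair, base_lesion, fu_lesion)
  dmap <- distance_map(base_lesion$mask)
  fv_pred <- if (config$use_blur)
    blur_fv(fvres$masks$fv, config$blur_radius_px)
  else fvres$masks$fv
  tab <- build_pixel_table(dmap, fv_pred, fu_lesion$mask,
                           exclusions = list(fvres$masks$drusen_excl,
                                             fvres$masks$projection_excl),
                           ring_px = config$ring_px, eye_id = eye_id)
  list(eye_id = eye_id,
       fv_summary = cbind(data.frame(eye_id = eye_id), fvres$summary),
       growth = data.frame(eye_id = eye_id,
                           area_baseline_mm2 = growth$area_baseline_mm2,
                           area_followup_mm2 = growth$area_followup_mm2,
                           months = growth$months_elapsed,
                           growth_rate_um_per_month =
                             growth$growth_rate_um_per_month,
                           n_foci = base_lesion$n_foci,
                           shift_dy = reg$dy, shift_dx = reg$dx),
       pixel_table = tab)
}

#' Run the full analysis on a set of visit pairs
#'
#' Per eye: QC gate, vessel-landmark registration, GA segmentation, FV
#' quantification with exclusions, square-root-area growth, and the Firth
#' conversion model on the margin ring.  At cohort level: clustered
#' Spearman correlation of FV percentage with growth rate (both ROIs),
#' clustered Wilcoxon signed-rank test on the per-eye FV coefficients,
#' median odds ratio and summary statistics.
#'
#' @param pairs Named list of [visit_pair()] objects (names = eye ids).
#' @param patient_ids Character vector of patient ids, one per pair.
#' @param config A [pipeline_config()].
#' @param norm A [normative_stats()], or `NULL` to derive one from
#'   `norm_params`.
#' @param norm_params [scene_params()] used to simulate the normative
#'   database when `norm` is `NULL`.
#' @param overrides Optional named list (by eye id) of lists with
#'   `baseline`/`followup` logical GA masks used verbatim.
#' @return An object of class `ccfv_result`.
#' @export
run_pipeline <- function(pairs, patient_ids, config = pipeline_config(),
                         norm = NULL, norm_params = NULL,
                         overrides = list()) {
  stopifnot(length(pairs) >= 1, length(patient_ids) == length(pairs))
  if (is.null(names(pairs)))
    names(pairs) <- sprintf("eye%02d", seq_along(pairs))
  if (is.null(norm)) {
    if (is.null(norm_params))
      norm_params <- scene_params(geometry = pairs[[1]]$baseline$geometry,
                                  rng_seed = config$seed)
    norm <- make_normative_db(20L, norm_params)
  }
  results <- list()
  for (eye_id in names(pairs)) {
    ov <- overrides[[eye_id]]
    res <- analyze_eye(pairs[[eye_id]], norm, config, eye_id,
                       override_baseline_ga = ov$baseline,
                       override_followup_ga = ov$followup)
    if (!is.null(res)) results[[eye_id]] <- res
  }
  if (length(results) == 0) stop("no eye passed quality control")
  kept <- names(results)
  patient_ids <- patient_ids[match(kept, names(pairs))]
  fv_summary <- do.call(rbind, lapply(results, `[[`, "fv_summary"))
  growth <- do.call(rbind, lapply(results, `[[`, "growth"))
  rownames(fv_summary) <- rownames(growth) <- NULL
  cf <- fit_cohort(lapply(results, `[[`, "pixel_table"),
                   degree = config$degree)
  eye_table <- data.frame(
    patient_id = patient_ids, eye_id = kept,
    fv_pct_all = fv_summary$fv_pct_all,
    fv_pct_band2deg = fv_summary$fv_pct_band2deg,
    growth_rate_um_per_month = growth$growth_rate_um_per_month,
    n_foci = growth$n_foci,
    beta3 = vapply(kept, function(e)
      cf$fits[[e]]$coefficients[["beta3"]], numeric(1)),
    stringsAsFactors = FALSE)
  try_spearman <- function(x) {
    tryCatch(clustered_spearman(x, eye_table$growth_rate_um_per_month,
                                eye_table$patient_id, seed = config$seed),
             error = function(e) {
               message("clustered Spearman unavailable: ", conditionMessage(e))
               .new_test(NA_real_, NA_real_, 0L, FALSE,
                         "Clustered Spearman rank correlation (not computed)",
                         estimate = NA_real_)
             })
  }
  sp_all <- try_spearman(eye_table$fv_pct_all)
  sp_band <- try_spearman(eye_table$fv_pct_band2deg)
  conv_ids <- names(cf$beta3)
  wx <- clustered_wilcoxon(cf$beta3,
                           eye_table$patient_id[match(conv_ids,
                                                      eye_table$eye_id)],
                           seed = config$seed)
  structure(list(fv_summary = fv_summary, growth = growth,
                 eye_table = eye_table, cohort_fit = cf,
                 spearman_all = sp_all, spearman_band = sp_band,
                 wilcoxon_beta3 = wx,
                 summary = cohort_summary(eye_table),
                 normative = norm, config = config),
            class = "ccfv_result")
}

#' @export
print.ccfv_result <- function(x, ...) {
  print(x$summary)
  cat(sprintf("  Spearman r (whole scan): %.3f, p = %.4g\n",
              x$spearman_all$estimate, x$spearman_all$p_value))
  cat(sprintf("  Spearman r (2-deg band): %.3f, p = %.4g\n",
              x$spearman_band$estimate, x$spearman_band$p_value))
  cat(sprintf("  Median OR (FV): %.3f; positive coefficients %d/%d\n",
              x$cohort_fit$median_or, x$cohort_fit$n_positive,
              length(x$cohort_fit$beta3)))
  cat(sprintf("  Clustered Wilcoxon on FV coefficients: p = %.4g\n",
              x$wilcoxon_beta3$p_value))
  invisible(x)
}

#' Simulate a cohort to disk
#'
#' Thin wrapper over [make_cohort()] + [write_cohort()].
#'
#' @param out_dir Output directory.
#' @param n_patients,eyes_per_patient,params,law,seed See [make_cohort()].
#' @return The cohort object, invisibly.
#' @export
ccfv_simulate <- function(out_dir, n_patients = 7L, eyes_per_patient = NULL,
                          params = scene_params(), law = growth_law(),
                          seed = 1L) {
  cohort <- make_cohort(n_patients = n_patients,
                        eyes_per_patient = eyes_per_patient,
                        params = params, law = law, seed = seed,
                        render = TRUE, dir = out_dir)
  message(sprintf("wrote %d-eye cohort to %s", nrow(cohort$manifest), out_dir))
  invisible(cohort)
}

# Load visit pairs from a cohort directory written by write_cohort().
load_cohort_pairs <- function(input_dir) {
  man <- read_manifest(file.path(input_dir, "manifest.yaml"))
  geometry <- man$geometry
  pairs <- list()
  for (i in seq_len(nrow(man$eyes))) {
    row <- man$eyes[i, ]
    read_one <- function(dir, signal) {
      p <- function(f) {
        fp <- file.path(input_dir, dir, f)
        if (file.exists(fp)) fp else NULL
      }
      read_visit(row$patient_id, row$eye,
                 cc_octa = file.path(input_dir, dir, "cc_octa.tif"),
                 sub_rpe = file.path(input_dir, dir, "sub_rpe.tif"),
                 drusen_elevation_um = p("drusen_elevation_um.tif"),
                 inner_retina_octa = p("inner_retina_octa.tif"),
                 signal_strength = signal, geometry = geometry)
    }
    base_dir <- file.path(input_dir, row$baseline_dir)
    fu_dir <- file.path(input_dir, row$followup_dir)
    if (!dir.exists(base_dir) || !dir.exists(fu_dir)) {
      message(sprintf("eye %s skipped: missing visit directory", row$eye_id))
      next
    }
    pairs[[row$eye_id]] <- visit_pair(
      read_one(row$baseline_dir, row$signal_baseline),
      read_one(row$followup_dir, row$signal_followup),
      months_elapsed = row$months_elapsed)
  }
  list(pairs = pairs, manifest = man$eyes, geometry = geometry)
}

#' Run the pipeline on a cohort directory
#'
#' Reads the manifest and raster layers, runs [run_pipeline()], and
#' writes `fv_summary.csv`, `growth_summary.csv`, `eye_fits.csv` and
#' `cohort_stats.json` to `out_dir`.
#'
#' @param input_dir Cohort directory with `manifest.yaml`.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return The [run_pipeline()] result, invisibly.
#' @export
ccfv_run <- function(input_dir, out_dir, config = pipeline_config()) {
  loaded <- load_cohort_pairs(input_dir)
  if (length(loaded$pairs) == 0) stop("no analysable eyes in the cohort")
  pid <- loaded$manifest$patient_id[match(names(loaded$pairs),
                                          loaded$manifest$eye_id)]
  norm <- if (!is.null(config$normative))
    normative_stats(config$normative$mean, config$normative$sd)
  else NULL
  res <- run_pipeline(loaded$pairs, pid, config, norm = norm,
                      norm_params = scene_params(geometry = loaded$geometry,
                                                 rng_seed = config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_table(res$fv_summary, file.path(out_dir, "fv_summary.csv"))
  write_csv_table(res$growth, file.path(out_dir, "growth_summary.csv"))
  fits <- do.call(rbind, lapply(res$cohort_fit$fits, function(f)
    data.frame(eye_id = f$eye_id, beta0 = f$coefficients[["beta0"]],
               beta1 = f$coefficients[["beta1"]],
               beta2 = f$coefficients[["beta2"]],
               beta3 = f$coefficients[["beta3"]], se3 = f$se_beta3,
               odds_ratio = f$odds_ratio, n_pixels = f$n_pixels,
               n_events = f$n_events, converged = f$converged)))
  fits$patient_id <- pid[match(fits$eye_id, names(loaded$pairs))]
  write_csv_table(fits, file.path(out_dir, "eye_fits.csv"))
  stats_out <- list(
    n_eyes = res$summary$n_eyes, n_patients = res$summary$n_patients,
    fv_pct_all_mean = res$summary$fv_pct_all_mean,
    fv_pct_all_sd = res$summary$fv_pct_all_sd,
    fv_pct_band2deg_mean = res$summary$fv_pct_band2deg_mean,
    fv_pct_band2deg_sd = res$summary$fv_pct_band2deg_sd,
    growth_um_month_mean = res$summary$growth_um_month_mean,
    growth_um_month_sd = res$summary$growth_um_month_sd,
    growth_um_year_mean = res$summary$growth_um_year_mean,
    spearman_r_all = res$spearman_all$estimate,
    spearman_p_all = res$spearman_all$p_value,
    spearman_r_band2deg = res$spearman_band$estimate,
    spearman_p_band2deg = res$spearman_band$p_value,
    wilcoxon_p_beta3 = res$wilcoxon_beta3$p_value,
    median_or = res$cohort_fit$median_or,
    n_positive_beta3 = res$cohort_fit$n_positive,
    method = list(
      spearman_exact = res$spearman_all$exact,
      spearman_n_perm = res$spearman_all$n_permutations,
      wilcoxon_exact = res$wilcoxon_beta3$exact,
      wilcoxon_n_perm = res$wilcoxon_beta3$n_permutations,
      seed = config$seed))
  jsonlite::write_json(stats_out, file.path(out_dir, "cohort_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Render a human-readable report from pipeline outputs
#'
#' Writes `report.md` plus two scatter plots (FV percentage versus GA
#' growth rate, whole scan and 2-degree band) into the output directory.
#'
#' @param results_dir Directory holding the [ccfv_run()] outputs.
#' @return Path to `report.md`, invisibly.
#' @export
ccfv_report <- function(results_dir) {
  stats_path <- file.path(results_dir, "cohort_stats.json")
  if (!file.exists(stats_path))
    stop(sprintf("missing %s: run the pipeline first", stats_path))
  st <- jsonlite::read_json(stats_path, simplifyVector = TRUE)
  fv <- read_csv_table(file.path(results_dir, "fv_summary.csv"))
  growth <- read_csv_table(file.path(results_dir, "growth_summary.csv"))
  tab <- merge(fv, growth, by = "eye_id")
  plot_one <- function(xcol, xlab, file) {
    grDevices::png(file.path(results_dir, file), width = 640, height = 480)
    on.exit(grDevices::dev.off())
    graphics::plot(tab[[xcol]], tab$growth_rate_um_per_month,
                   xlab = xlab, ylab = "GA growth rate (um/month)",
                   pch = 19, col = "steelblue",
                   main = sprintf("%s vs GA growth", xlab))
    graphics::abline(stats::lm(tab$growth_rate_um_per_month ~ tab[[xcol]]),
                     lty = 2, col = "grey40")
  }
  plot_one("fv_pct_all", "FV % (whole scan)", "scatter_fv_all.png")
  plot_one("fv_pct_band2deg", "FV % (2-deg band)", "scatter_fv_band.png")
  lines <- c(
    "# Choriocapillaris flow voids and GA growth",
    "",
    sprintf("Eyes analysed: %d from %d patients.", st$n_eyes, st$n_patients),
    "",
    "## Cohort summary",
    "",
    sprintf("- Mean FV%%, whole scan: %.2f%% (SD %.2f)",
            st$fv_pct_all_mean, st$fv_pct_all_sd),
    sprintf("- Mean FV%%, 2-degree band: %.2f%% (SD %.2f)",
            st$fv_pct_band2deg_mean, st$fv_pct_band2deg_sd),
    sprintf("- Mean GA growth: %.2f um/month (SD %.2f; %.1f um/year)",
            st$growth_um_month_mean, st$growth_um_month_sd,
            st$growth_um_year_mean),
    "",
    "## Association of FV with growth",
    "",
    sprintf("- Clustered Spearman r, whole scan: %.3f (p = %.4g)",
            st$spearman_r_all, st$spearman_p_all),
    sprintf("- Clustered Spearman r, 2-degree band: %.3f (p = %.4g)",
            st$spearman_r_band2deg, st$spearman_p_band2deg),
    "",
    "## Pixel-level conversion model",
    "",
    sprintf("- Median odds ratio for baseline FV: %.3f", st$median_or),
    sprintf("- Eyes with positive FV coefficient: %d/%d",
            st$n_positive_beta3, st$n_eyes),
    sprintf("- Clustered Wilcoxon p (FV coefficients): %.4g",
            st$wilcoxon_p_beta3),
    "",
    "![](scatter_fv_all.png)",
    "",
    "![](scatter_fv_band.png)",
    "")
  out <- file.path(results_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
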