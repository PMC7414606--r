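#' @title Cluster-permutation tests for paired-eye cohorts
#' @description Two eyes of one patient are correlated, so cohort-level
#'   inference permutes or sign-flips at the patient (cluster) level.
#' @name cluster_tests
NULL

# All permutations of 1..k as a (k! x k) matrix.
.all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

.new_test <- function(statistic, p_value, n_permutations, exact, method,
                      estimate = NULL) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations, exact = exact,
                 method = method, estimate = estimate),
            class = "ccfv_test")
}

#' @export
print.ccfv_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$estimate))
    cat(sprintf("  estimate: %.4f\n", x$estimate))
  cat(sprintf("  statistic = %.4f, two-sided p = %.5g (%s, %d permutations)\n",
              x$statistic, x$p_value,
              if (x$exact) "exact" else "Monte Carlo", x$n_permutations))
  invisible(x)
}

#' Clustered Spearman correlation with patient-level permutation
#'
#' Computes the Spearman rank correlation over all eyes and derives its
#' two-sided p-value by permuting whole patients: each patient's block of
#' y-values is reassigned to another patient.  Because the cohort mixes
#' one- and two-eye patients, blocks are permuted only among clusters of
#' equal size (composed across size classes), so every permuted dataset
#' remains structurally valid.  All block permutations are enumerated
#' exhaustively when the number of clusters is at most `exact_limit`;
#' otherwise `n_perm` Monte-Carlo permutations are drawn under a fixed
#' seed.
#'
#' @param x,y Paired per-eye values.
#' @param clusters Patient identifier per eye.
#' @param exact_limit Maximum number of clusters for exhaustive
#'   enumeration (default 9).
#' @param n_perm Monte-Carlo permutation count (default 10000).
#' @param seed Seed for the Monte-Carlo mode (default 20200603).
#' @return A `ccfv_test` with `estimate` = observed Spearman r.
#' @export
clustered_spearman <- function(x, y, clusters, exact_limit = 9L,
                               n_perm = 10000L, seed = 20200603L) {
  stopifnot(length(x) == length(y), length(clusters) == length(x))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  cl <- as.character(clusters)
  blocks <- split(seq_along(x), cl)
  k <- length(blocks)
  if (k < 3) stop("need at least 3 clusters for a nondegenerate null")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant x or y: Spearman correlation undefined")
  sizes <- lengths(blocks)
  r_obs <- stats::cor(x, y, method = "spearman")
  # permuted y for a given assignment: block i receives the y-values of
  # block assign[i] (same size), in stored order
  perm_y <- function(assign) {
    out <- numeric(length(y))
    for (i in seq_len(k)) out[blocks[[i]]] <- y[blocks[[assign[i]]]]
    out
  }
  size_classes <- split(seq_len(k), sizes)
  exact <- k <= exact_limit
  if (exact) {
    class_perms <- lapply(size_classes, function(members)
      matrix(members[.all_perms(length(members))], ncol = length(members)))
    n_tot <- prod(vapply(class_perms, nrow, numeric(1)))
    grid <- do.call(expand.grid,
                    lapply(class_perms, function(m) seq_len(nrow(m))))
    r_perm <- numeric(n_tot)
    for (g in seq_len(n_tot)) {
      assign <- integer(k)
      for (s in seq_along(size_classes)) {
        members <- size_classes[[s]]
        assign[members] <- class_perms[[s]][grid[g, s], ]
      }
      r_perm[g] <- stats::cor(x, perm_y(assign), method = "spearman")
    }
    p <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
    n_used <- n_tot
  } else {
    set.seed(seed)
    hits <- 0L
    for (g in seq_len(n_perm)) {
      assign <- integer(k)
      for (s in seq_along(size_classes)) {
        members <- size_classes[[s]]
        assign[members] <- members[sample.int(length(members))]
      }
      if (abs(stats::cor(x, perm_y(assign), method = "spearman")) >=
          abs(r_obs) - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)  # observed arrangement included
    n_used <- n_perm
  }
  .new_test(r_obs, p, n_used, exact,
            "Clustered Spearman rank correlation (patient-level permutation)",
            estimate = r_obs)
}

#' Clustered Wilcoxon signed-rank test with patient-level sign flips
#'
#' Tests whether per-eye values (for example the per-eye FV conversion
#' coefficients) are centred at zero.  The statistic is the signed-rank
#' sum over all eyes; its null distribution flips the signs of all values
#' within a patient jointly (2^k cluster sign-flip patterns), exhaustively
#' when the number of clusters is at most `exact_limit`, else by
#' Monte-Carlo sampling with a fixed seed.  Zeros are dropped before
#' ranking; midranks are used for ties.
#'
#' @param values Per-eye values.
#' @param clusters Patient identifier per eye.
#' @param exact_limit Maximum cluster count for exhaustive enumeration
#'   (default 20).
#' @param n_perm Monte-Carlo sample size (default 10000).
#' @param seed Seed for the Monte-Carlo mode.
#' @return A `ccfv_test`; statistic is the observed signed-rank sum.
#' @export
clustered_wilcoxon <- function(values, clusters, exact_limit = 20L,
                               n_perm = 10000L, seed = 20200603L) {
  stopifnot(length(values) == length(clusters))
  keep <- values != 0
  if (!any(keep)) {
    warning("all values are zero; p = 1 by convention")
    return(.new_test(0, 1, 0, TRUE,
                     "Clustered Wilcoxon signed-rank test (cluster sign-flips)"))
  }
  v <- values[keep]
  cl <- as.character(clusters)[keep]
  r <- rank(abs(v))  # midranks
  signed <- sign(v) * r
  s_c <- vapply(split(signed, cl), sum, numeric(1))
  k <- length(s_c)
  s_obs <- sum(s_c)
  exact <- k <= exact_limit
  if (exact) {
    n_tot <- 2^k
    hits <- 0
    chunk <- 2^min(k, 14)
    for (start in seq(0, n_tot - 1, by = chunk)) {
      ints <- start:(min(start + chunk, n_tot) - 1)
      signs <- matrix(1, length(ints), k)
      for (b in seq_len(k))
        signs[, b] <- 1 - 2 * bitwAnd(ints %/% 2^(b - 1), 1L)
      s_perm <- drop(signs %*% s_c)
      hits <- hits + sum(abs(s_perm) >= abs(s_obs) - 1e-9)
    }
    p <- hits / n_tot
    n_used <- n_tot
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * k, replace = TRUE), n_perm, k)
    s_perm <- drop(signs %*% s_c)
    p <- (sum(abs(s_perm) >= abs(s_obs) - 1e-9) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  .new_test(s_obs, p, n_used, exact,
            "Clustered Wilcoxon signed-rank test (cluster sign-flips)")
}

#' Cohort summary statistics
#'
#' Mean and SD of the per-eye FV percentages (whole scan and 2-degree
#' band) and of the GA growth rate, reported per month and per year, plus
#' eye, patient and multifocal counts.
#'
#' @param table Data.frame with columns `patient_id`, `eye_id`,
#'   `fv_pct_all`, `fv_pct_band2deg`, `growth_rate_um_per_month` and
#'   optionally `n_foci`.
#' @return An object of class `cohort_summary` (a list of the summary
#'   quantities; SDs are `NA` for a single eye).
#' @export
cohort_summary <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  m <- function(v) mean(v, na.rm = TRUE)
  s <- function(v) if (sum(is.finite(v)) > 1) stats::sd(v, na.rm = TRUE)
  else NA_real_
  structure(list(
    n_eyes = nrow(table),
    n_patients = length(unique(table$patient_id)),
    n_multifocal = if ("n_foci" %in% names(table))
      sum(table$n_foci > 1, na.rm = TRUE) else NA_integer_,
    fv_pct_all_mean = m(table$fv_pct_all),
    fv_pct_all_sd = s(table$fv_pct_all),
    fv_pct_band2deg_mean = m(table$fv_pct_band2deg),
    fv_pct_band2deg_sd = s(table$fv_pct_band2deg),
    growth_um_month_mean = m(table$growth_rate_um_per_month),
    growth_um_month_sd = s(table$growth_rate_um_per_month),
    growth_um_year_mean = 12 * m(table$growth_rate_um_per_month),
    growth_um_year_sd = if (is.na(s(table$growth_rate_um_per_month)))
      NA_real_ else 12 * s(table$growth_rate_um_per_month)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d eyes from %d patients", x$n_eyes, x$n_patients))
  if (!is.na(x$n_multifocal))
    cat(sprintf(" (%d multifocal)", x$n_multifocal))
  cat("\n")
  cat(sprintf("  FV%% whole scan:  %.2f +/- %s\n", x$fv_pct_all_mean,
              format(round(x$fv_pct_all_sd, 2))))
  cat(sprintf("  FV%% 2-deg band:  %.2f +/- %s\n", x$fv_pct_band2deg_mean,
              format(round(x$fv_pct_band2deg_sd, 2))))
  cat(sprintf("  GA growth: %.2f +/- %s um/month (%.1f um/year)\n",
              x$growth_um_month_mean, format(round(x$growth_um_month_sd, 2)),
              x$growth_um_year_mean))
  invisible(x)
}
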