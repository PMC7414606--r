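test_that("clustered Spearman reproduces the hand-enumerated exact p", {
  # 3 single-eye clusters, x = y = (1,2,3): 3! = 6 permutations, both the
  # identity and the full reversal reach |r| = 1
  res <- clustered_spearman(1:3, 1:3, c("a", "b", "c"))
  expect_equal(res$estimate, 1)
  expect_true(res$exact)
  expect_equal(res$n_permutations, 6)
  expect_equal(res$p_value, 2 / 6)
})

test_that("Spearman r is invariant under monotone transforms and input checks fire", {
  set.seed(24)
  x <- rnorm(8); y <- x + rnorm(8, 0, 0.5)
  cl <- rep(1:4, each = 2)
  r1 <- clustered_spearman(x, y, cl)
  r2 <- clustered_spearman(exp(x), y^3 + 10 * y, cl)
  expect_equal(r1$estimate, r2$estimate)
  expect_equal(r1$p_value, r2$p_value)
  expect_error(clustered_spearman(rep(1, 6), rnorm(6), rep(1:3, 2)),
               "constant")
  expect_error(clustered_spearman(1:4, 1:4, c(1, 1, 2, 2)), "3 clusters")
})

test_that("mixed cluster sizes permute only within size classes", {
  # 2 two-eye patients + 2 one-eye patients: 2! * 2! = 4 permutations
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  cl <- c("A", "A", "B", "B", "c", "d")
  res <- clustered_spearman(x, y, cl)
  expect_true(res$exact)
  expect_equal(res$n_permutations, 4)
})

test_that("Monte-Carlo and exhaustive Spearman nulls agree on small cohorts", {
  set.seed(25)
  x <- rnorm(8); y <- x + rnorm(8)
  cl <- rep(1:8)
  exact <- clustered_spearman(x, y, cl, exact_limit = 8)
  mc <- clustered_spearman(x, y, cl, exact_limit = 2, n_perm = 20000)
  expect_false(mc$exact)
  expect_equal(mc$p_value, exact$p_value, tolerance = 0.02)
})

test_that("clustered Wilcoxon reproduces the most-extreme enumeration", {
  # 7 all-positive singleton clusters: only the all-plus and all-minus
  # patterns reach |S|, so p = 2 / 2^7
  v <- c(0.5, 1.2, 0.3, 2.2, 0.9, 1.7, 0.4)
  res <- clustered_wilcoxon(v, 1:7)
  expect_true(res$exact)
  expect_equal(res$n_permutations, 128)
  expect_equal(res$p_value, 2 / 2^7)
  expect_equal(res$statistic, sum(rank(v)))
})

test_that("Wilcoxon p is invariant to positive rescaling and handles zeros", {
  v <- c(-0.2, 1.5, 0.8, -1.1, 0.6)
  cl <- c(1, 1, 2, 2, 3)
  r1 <- clustered_wilcoxon(v, cl)
  r2 <- clustered_wilcoxon(1000 * v, cl)
  expect_equal(r1$p_value, r2$p_value)
  expect_warning(r0 <- clustered_wilcoxon(rep(0, 4), 1:4), "zero")
  expect_equal(r0$p_value, 1)
  # zeros dropped: remaining values decide
  r3 <- clustered_wilcoxon(c(v, 0), c(cl, 4))
  expect_equal(r3$p_value, r1$p_value)
})

test_that("symmetric constructions land in the p = 1 region of the null", {
  v <- c(1.4, -1.4, 0.7, -0.7)
  res <- clustered_wilcoxon(v, 1:4)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("Monte-Carlo and exhaustive Wilcoxon nulls agree", {
  set.seed(26)
  v <- rnorm(8, 0.4)
  cl <- rep(1:4, each = 2)
  exact <- clustered_wilcoxon(v, cl)
  mc <- clustered_wilcoxon(v, cl, exact_limit = 2, n_perm = 20000)
  expect_equal(mc$p_value, exact$p_value, tolerance = 0.02)
})

test_that("singleton clusters reduce to the ordinary sign-flip test", {
  set.seed(27)
  v <- rnorm(9, 0.3)
  res <- clustered_wilcoxon(v, seq_along(v))
  # oracle: enumerate all 2^9 sign patterns directly
  r <- rank(abs(v)); s_obs <- sum(sign(v) * r)
  hits <- 0
  for (i in 0:(2^9 - 1)) {
    eps <- 1 - 2 * as.integer(intToBits(i)[1:9])
    if (abs(sum(eps * r)) >= abs(s_obs) - 1e-9) hits <- hits + 1
  }
  expect_equal(res$p_value, hits / 2^9)
})

test_that("both tests keep type-I error near nominal on clustered nulls", {
  n_rep <- 1000
  alpha <- 0.05
  rej_w <- 0; rej_s <- 0
  set.seed(28)
  for (i in seq_len(n_rep)) {
    # 6 patients x 2 eyes, strong within-patient correlation, null center
    pat <- rnorm(6)
    v <- rep(pat, each = 2) + rnorm(12, 0, 0.5)
    cl <- rep(1:6, each = 2)
    if (clustered_wilcoxon(v, cl)$p_value <= alpha) rej_w <- rej_w + 1
    # Spearman null: y independent of x but correlated within patient
    x <- rep(rnorm(6), each = 2) + rnorm(12, 0, 0.5)
    y <- rep(rnorm(6), each = 2) + rnorm(12, 0, 0.5)
    if (clustered_spearman(x, y, cl)$p_value <= alpha) rej_s <- rej_s + 1
  }
  mc_err <- sqrt(alpha * (1 - alpha) / n_rep)
  expect_lte(rej_w / n_rep, alpha + 2 * mc_err)
  expect_lte(rej_s / n_rep, alpha + 2 * mc_err)
})

test_that("cohort summaries compute means, SDs and counts", {
  tab <- data.frame(patient_id = c("a", "a", "b"),
                    eye_id = c("a1", "a2", "b1"),
                    fv_pct_all = c(10, 20, 30),
                    fv_pct_band2deg = c(15, 25, 35),
                    growth_rate_um_per_month = c(10, 20, 30),
                    n_foci = c(1, 2, 3))
  s <- cohort_summary(tab)
  expect_equal(s$n_eyes, 3); expect_equal(s$n_patients, 2)
  expect_equal(s$n_multifocal, 2)
  expect_equal(s$fv_pct_all_mean, 20)
  expect_equal(s$growth_um_year_mean, 240)
  # duplicating every row leaves means unchanged
  s2 <- cohort_summary(rbind(tab, tab))
  expect_equal(s2$fv_pct_all_mean, s$fv_pct_all_mean)
  expect_equal(s2$growth_um_month_mean, s$growth_um_month_mean)
  # single eye: SD not applicable
  s1 <- cohort_summary(tab[1, ])
  expect_true(is.na(s1$fv_pct_all_sd))
})
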