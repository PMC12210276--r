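# Weighted differential fit: OLS oracle equivalence, weight estimators,
# consensus correlation recovery, BH oracle, calibration and power.

test_that("unweighted fit reproduces hand-computed OLS t-statistics to 1e-9", {
  set.seed(40)
  sheet <- toy_sheet(n_subjects = 8)
  X <- design_spec(sheet, "case_vs_control@celltype1")
  y <- matrix(rnorm(5 * nrow(sheet)), 5,
              dimnames = list(paste0("r", 1:5), sheet$sample_id))
  tab <- fit_differential(y, X, moderate = FALSE)
  for (r in 1:5) {
    fit <- lm(y[r, ] ~ 0 + X$design)
    ct <- as.numeric(X$contrast)
    est <- sum(coef(fit) * ct)
    se <- sqrt(t(ct) %*% vcov(fit) %*% ct)
    expect_equal(tab$logFC[r], est, tolerance = 1e-9)
    expect_equal(tab$t[r], est / as.numeric(se), tolerance = 1e-9)
    p_or <- 2 * pt(-abs(est / as.numeric(se)), df = fit$df.residual)
    expect_equal(tab$p_value[r], p_or, tolerance = 1e-9)
  }
})

test_that("moderated t approaches ordinary t when the prior is uninformative", {
  set.seed(41)
  sheet <- toy_sheet(n_subjects = 10)
  y <- matrix(rnorm(200 * nrow(sheet)), 200,
              dimnames = list(paste0("r", 1:200), sheet$sample_id))
  X <- design_spec(sheet, "case_vs_control@celltype1")
  tmod <- fit_differential(y, X, moderate = TRUE)
  tord <- fit_differential(y, X, moderate = FALSE)
  # homoscedastic null: shrinkage changes little, ranks agree strongly
  expect_gt(cor(tmod$t, tord$t, method = "spearman"), 0.99)
})

test_that("BH adjustment matches the sort-and-scan oracle and is order-invariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(42)
  p <- runif(100)^2
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  perm <- sample(100)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  # monotone nondecreasing in p-rank
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("precision weights track the mean-variance trend", {
  set.seed(43)
  sheet <- toy_sheet(n_subjects = 10)
  ns <- nrow(sheet)
  # homoscedastic: weights near constant
  y0 <- matrix(rnorm(300 * ns), 300, dimnames = list(NULL, sheet$sample_id))
  X <- design_spec(sheet, "case_vs_control@celltype1")
  w0 <- estimate_precision_weights(y0, X$design)
  expect_true(all(w0 > 0))
  expect_lt(sd(w0) / mean(w0), 0.2)
  # count-like: variance decreasing in abundance -> weights increase with it
  mu <- runif(300, 2, 10)
  y1 <- matrix(rnorm(300 * ns, mean = mu, sd = rep(3 / sqrt(mu), ns)), 300,
               dimnames = list(NULL, sheet$sample_id))
  w1 <- estimate_precision_weights(y1, X$design)
  expect_gt(cor(mu, rowMeans(w1), method = "spearman"), 0.8)
  expect_error(estimate_precision_weights(y1[1:5, ], X$design), ">= 10")
})

test_that("sample weights single out a noisy sample", {
  set.seed(44)
  sheet <- toy_sheet(n_subjects = 10)
  ns <- nrow(sheet)
  y <- matrix(rnorm(400 * ns), 400, dimnames = list(NULL, sheet$sample_id))
  X <- design_spec(sheet, "case_vs_control@celltype1")
  w <- estimate_sample_weights(y, X$design)
  expect_equal(exp(mean(log(w))), 1, tolerance = 1e-12)
  expect_lt(max(abs(w - 1)), 0.3)            # iid -> near 1
  y_noisy <- y; y_noisy[, 7] <- y[, 7] * sqrt(5)
  w2 <- estimate_sample_weights(y_noisy, X$design)
  expect_equal(unname(which.min(w2)), 7)
})

test_that("consensus correlation recovers a planted subject intercept", {
  set.seed(45)
  sheet <- toy_sheet(n_subjects = 20)
  ns <- nrow(sheet)
  X <- design_spec(sheet, "case_vs_control@celltype1")
  subj <- factor(sheet$subject_id)
  make_y <- function(icc) {
    t(vapply(seq_len(500), function(r) {
      b <- rnorm(nlevels(subj), sd = sqrt(icc))
      b[as.integer(subj)] + rnorm(ns, sd = sqrt(1 - icc))
    }, numeric(ns))) -> y
    colnames(y) <- sheet$sample_id
    y
  }
  y_null <- make_y(0)
  expect_lt(abs(estimate_block_correlation(y_null, X$design, X$block)), 0.05)
  y_icc <- make_y(0.5)
  rho <- estimate_block_correlation(y_icc, X$design, X$block)
  expect_lt(abs(rho - 0.5), 0.1)
  # blocks of size 1 -> 0 with warning
  sheet1 <- toy_sheet(n_subjects = 6, cell_types = "celltype1")
  X1 <- design_spec(sheet1, "case_vs_control@celltype1")
  y1 <- matrix(rnorm(20 * 6), 20, dimnames = list(NULL, sheet1$sample_id))
  expect_warning(r0 <- estimate_block_correlation(y1, X1$design, X1$block),
                 "no block")
  expect_equal(r0, 0)
})

test_that("global-null calibration: fraction p < 0.05 near nominal", {
  sim <- simulate_atac_counts(atac_sim_spec(n_subjects = 20, n_regions = 2000,
                                            frac_differential = 0, seed = 46))
  nm <- normalize_pipeline(filter_low_signal(sim$counts)$filtered, sim$sheet)
  ds <- design_spec(sim$sheet, "case_vs_control@celltype1")
  tab <- fit_differential(nm$norm, ds,
                          obs_weights = estimate_precision_weights(nm$norm, ds$design),
                          sample_weights = estimate_sample_weights(nm$norm, ds$design),
                          block_correlation = estimate_block_correlation(
                            nm$norm, ds$design, ds$block))
  frac <- mean(tab$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("planted lfc = 2 regions are recovered with high power at q < 0.05", {
  sim <- simulate_atac_counts(atac_sim_spec(n_subjects = 20, n_regions = 500,
                                            frac_differential = 0.1,
                                            effect_lfc = 2, seed = 47))
  nm <- normalize_pipeline(filter_low_signal(sim$counts)$filtered, sim$sheet)
  tab <- run_differential_once(nm$norm, sim$sheet, "case_vs_control@celltype1")
  planted <- tab$region %in% sim$truth$differential_regions
  expect_gte(mean(tab$q_value[planted] < 0.05), 0.95)
  # false positives controlled among nulls
  expect_lte(mean(tab$q_value[!planted] < 0.05), 0.02)
})

test_that("empirical FDR stays near nominal on a mixed simulation", {
  fdps <- vapply(1:5, function(s) {
    sim <- simulate_atac_counts(atac_sim_spec(n_subjects = 20, n_regions = 400,
                                              frac_differential = 0.1,
                                              effect_lfc = 1.5,
                                              seed = 900 + s))
    nm <- normalize_pipeline(filter_low_signal(sim$counts)$filtered, sim$sheet)
    tab <- run_differential_once(nm$norm, sim$sheet,
                                 "case_vs_control@celltype1")
    hit <- tab$q_value < 0.05
    if (!any(hit)) return(0)
    mean(!(tab$region[hit] %in% sim$truth$differential_regions))
  }, numeric(1))
  expect_lte(mean(fdps), 1.5 * 0.05)
})
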