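# Filtering and normalization: CPM arithmetic, the ceiling rule, TMM against
# a brute-force oracle, quantile normalization, and pipeline invariants.

test_that("CPM is plain library-size scaling", {
  x <- tiny_counts(matrix(c(50, 0, 100, 0), 2,
                          dimnames = list(NULL, c("a", "b"))))
  x$library_sizes[] <- 1e6
  cpm <- cpm_transform(x)
  expect_equal(cpm["r01", "a"], 50)
  expect_equal(cpm["r01", "b"], 100)
  expect_equal(unname(cpm["r02", ]), c(0, 0))
})

test_that("low-signal filter applies the ceiling rule and is idempotent", {
  # 10 samples; r01 passes CPM >= 1 in exactly 1 sample: 1 >= ceiling(0.1*10)
  m <- matrix(0L, 3, 10, dimnames = list(NULL, sprintf("s%02d", 1:10)))
  m[1, 1] <- 10L   # CPM 10 in s01 only
  m[3, ] <- 100L   # everywhere
  m[2, ] <- 0L     # all-zero region
  x <- tiny_counts(m)
  x$library_sizes[] <- 1e6
  out <- filter_low_signal(x)
  expect_setequal(out$removed, "r02")
  expect_equal(out$filtered$regions$id, c("r01", "r03"))
  # idempotent
  again <- filter_low_signal(out$filtered)
  expect_length(again$removed, 0)
  expect_equal(again$filtered$counts, out$filtered$counts)
  # raising the required fraction drops r01 (needs ceiling(0.2*10) = 2)
  out2 <- filter_low_signal(x, normalization_params(min_fraction = 0.2))
  expect_setequal(out2$removed, c("r01", "r02"))
})

test_that("TMM factors match a brute-force double-trim oracle to 1e-9", {
  set.seed(10)
  m <- matrix(rnbinom(8 * 200, mu = 50, size = 5), 200, 8,
              dimnames = list(NULL, paste0("s", 1:8)))
  m[, 3] <- m[, 3] * 4L   # scale distortion
  x <- tiny_counts(m)
  f <- tmm_factors(x, reference = "s1")
  raw <- vapply(seq_len(8), function(j) {
    oracle_tmm_pair(m[, j], m[, 1], x$library_sizes[j], x$library_sizes[1])
  }, numeric(1))
  oracle <- raw / exp(mean(log(raw)))
  expect_equal(unname(f), oracle, tolerance = 1e-9)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("TMM is exact on the identical and proportional toy cases", {
  m <- matrix(c(10, 20, 30, 40, 10, 20, 30, 40), 4,
              dimnames = list(NULL, c("a", "b")))
  f <- tmm_factors(tiny_counts(m))
  expect_equal(unname(f), c(1, 1))
  # B = 3 x A elementwise: library-size scaling absorbs it, all M = 0
  m2 <- m; m2[, 2] <- 3L * m[, 1]
  f2 <- tmm_factors(tiny_counts(m2))
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-12)
})

test_that("TMM factors are invariant to scaling one sample", {
  set.seed(11)
  m <- matrix(rnbinom(6 * 300, mu = 80, size = 10), 300, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  f1 <- tmm_factors(tiny_counts(m))
  m2 <- m; m2[, 4] <- m[, 4] * 5L
  f2 <- tmm_factors(tiny_counts(m2))
  # effective library sizes (lib * factor) keep the same relative values
  eff1 <- colSums(m) * f1
  eff2 <- colSums(m2) * f2
  expect_equal(unname(eff2 / eff1)[-4], rep(1, 5) * (eff2[1] / eff1[1]),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("within-group quantile normalization equalizes distributions", {
  v <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize_within_group(v, groups = c("g", "g"))
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))
  # identical columns unchanged
  w <- cbind(a = c(1, 5, 2), b = c(1, 5, 2))
  expect_equal(quantile_normalize_within_group(w, c("g", "g")), w)
  # two groups normalized separately
  v4 <- cbind(a = 1:3, b = 4:6, c = c(10, 20, 30), d = c(40, 50, 60))
  out4 <- quantile_normalize_within_group(v4, c("g1", "g1", "g2", "g2"))
  expect_equal(unname(out4[, 1]), unname(out4[, 2]))
  expect_equal(unname(out4[, 3]), unname(out4[, 4]))
  expect_false(isTRUE(all.equal(out4[, 1], out4[, 3])))
  # group of one passes through with a warning
  v3 <- cbind(a = 1:3, b = 4:6, c = c(9, 8, 7))
  expect_warning(out1 <- quantile_normalize_within_group(v3, c("g1", "g1", "g2")),
                 "single sample")
  expect_equal(out1[, 3], v3[, 3])
  # tie-free group: sorted columns agree exactly after normalization
  set.seed(14)
  vt <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  outt <- quantile_normalize_within_group(vt, rep("g", 4))
  sorted <- apply(outt, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
})

test_that("pipeline preserves within-sample rank order before quantile step", {
  sim <- simulate_atac_counts(atac_sim_spec(n_subjects = 8, n_regions = 120,
                                            seed = 12))
  x <- filter_low_signal(sim$counts)$filtered
  f <- tmm_factors(x)
  logcpm <- edgeR::cpm(x$counts, lib.size = x$library_sizes * f, log = TRUE,
                       prior.count = 0.5)
  for (j in c(1, 5)) {
    ord <- order(x$counts[, j])
    expect_true(all(diff(logcpm[ord, j]) >= -1e-12))
  }
})

test_that("pipeline output: per-group column distributions identical", {
  sim <- simulate_atac_counts(atac_sim_spec(n_subjects = 10, n_regions = 150,
                                            seed = 13))
  x <- filter_low_signal(sim$counts)$filtered
  nm <- normalize_pipeline(x, sim$sheet)
  # ties among low log-CPM values get averaged target quantiles, so on count
  # data the sorted columns agree closely; exact identity is checked on
  # tie-free data above
  for (g in unique(sim$sheet$cell_type)) {
    cols <- which(sim$sheet$cell_type == g)
    sorted <- apply(nm$norm[, cols], 2, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 0.2)
    expect_lt(stats::median(abs(sorted - sorted[, 1])), 1e-9)
  }
  # equal-count equal-library matrix -> constant output per region
  m <- matrix(rep(c(5L, 50L, 500L), 4), 3,
              dimnames = list(NULL, paste0("s", 1:4)))
  sheet_c <- sample_sheet(data.frame(
    sample_id = paste0("s", 1:4), subject_id = paste0("p", 1:4),
    cell_type = "ct1", diagnosis = rep(c("case", "control"), 2),
    sex = "male"))
  nm2 <- normalize_pipeline(tiny_counts(m), sheet_c)
  expect_lt(max(apply(nm2$norm, 1, function(r) diff(range(r)))), 1e-12)
})
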