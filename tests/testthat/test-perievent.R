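# Peri-event machinery: bout merging, rescaling, window statistics, the
# circular null, classification rules, synchrony and paired comparisons.

test_that("bout merging combines gaps under 2 s transitively", {
  iv <- data.frame(start_s = c(0, 2.5), end_s = c(1, 4))
  m <- merge_bouts(iv)                       # gap 1.5 < 2 -> single bout
  expect_equal(nrow(m$intervals), 1)
  expect_equal(m$intervals$start_s, 0)
  expect_equal(m$intervals$end_s, 4)
  expect_equal(m$entry_times, 0)
  # far-apart bouts unchanged
  iv2 <- data.frame(start_s = c(0, 5), end_s = c(1, 6))
  expect_equal(nrow(merge_bouts(iv2)$intervals), 2)
  # transitive chain: 0-1, 2-3, 4-5 all merge
  iv3 <- data.frame(start_s = c(0, 2, 4), end_s = c(1, 3, 5))
  m3 <- merge_bouts(iv3)
  expect_equal(nrow(m3$intervals), 1)
  expect_equal(m3$intervals$end_s, 5)
  expect_error(merge_bouts(data.frame(start_s = c(5, 0), end_s = c(6, 1))),
               "sorted")
})

test_that("rescaling standardizes with the population SD and is idempotent", {
  tr <- matrix(c(1, 2, 3), 1)
  s <- calcium_session(tr, rate_hz = 1)
  r <- rescale_traces(s)
  expect_equal(as.numeric(r$traces), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  r2 <- rescale_traces(r)
  expect_equal(r2$traces, r$traces, tolerance = 1e-12)
  expect_error(rescale_traces(calcium_session(matrix(1, 1, 5), 1)),
               "constant trace")
})

test_that("peri-event statistic: hand-computed window means", {
  # unit step at the event time: pre mean 0, post mean 1 -> statistic 1
  rate <- 10
  trace <- c(rep(0, 100), rep(1, 100))   # step at t = 10 s
  expect_equal(perievent_statistic(trace, 10, rate), 1)
  # identically zero trace -> 0
  expect_equal(perievent_statistic(numeric(200), 10, rate), 0)
  # explicit two-event toy with asymmetric windows
  tr2 <- seq(0, 19.9, by = 0.1)          # ramp: mean of window = mid-time
  stat <- perievent_statistic(tr2, c(5, 12), rate)
  # for a ramp x(t) = t, post mean - pre mean = 2 + 2 = 4 per event
  expect_equal(stat, 4, tolerance = 1e-9)
  # out-of-range events drop with warning; all dropped -> error
  expect_warning(s <- perievent_statistic(trace, c(1, 10), rate), "dropped")
  expect_equal(s, 1)
  expect_error(suppressWarnings(perievent_statistic(trace, 1, rate)), "all events")
})

test_that("circular null is seed-stable, centred, and wrap-consistent", {
  set.seed(70)
  trace <- rnorm(2000)
  ev <- c(50, 100, 150)
  n1 <- circular_null(trace, ev, 10, n_shuffles = 200, seed = 71)
  n2 <- circular_null(trace, ev, 10, n_shuffles = 200, seed = 71)
  expect_identical(n1, n2)
  # white noise: null mean within 3 SE of 0
  expect_lt(abs(mean(n1)), 3 * sd(n1) / sqrt(length(n1)))
  # fast path agrees with the generic path exactly
  res <- ocrstats:::perievent_null_fast(trace, ev, 10, n_shuffles = 200,
                                        seed = 71)
  expect_equal(res$null, n1, tolerance = 1e-12)
  expect_equal(res$observed, perievent_statistic(trace, ev, 10),
               tolerance = 1e-12)
})

test_that("modulation classification follows the add-one two-tailed rule", {
  null <- seq(-1, 1, length.out = 1000)
  up <- classify_modulation(2, null)
  expect_equal(up$bootstrap_probability, 1 / 1001)
  expect_equal(up$label, "up")
  down <- classify_modulation(-2, null)
  expect_equal(down$bootstrap_probability, 1001 / 1001 - 0 / 1001, tolerance = 1e-9)
  expect_equal(down$label, "down")
  mid <- classify_modulation(0, null)
  expect_equal(mid$label, "non")
  # tie case: observed equal to every null -> middle, non
  tie <- classify_modulation(5, rep(5, 1000))
  expect_equal(tie$label, "non")
  # invariant to adding a constant to both
  shift <- classify_modulation(2 + 10, null + 10)
  expect_equal(shift$label, up$label)
  expect_equal(shift$bootstrap_probability, up$bootstrap_probability)
  expect_error(classify_modulation(1, numeric(0)), "empty")
})

test_that("planted up/down cells are recovered; labels match truth", {
  sim <- simulate_calcium_session(
    calcium_sim_spec(n_cells = 30, frac_up = 0.3, frac_down = 0.3,
                     transient_amplitude = 3, seed = 72))
  rep <- classify_session(sim$session, seed = 73)
  truth <- sim$truth$modulated_cells
  correct <- c(rep$label[truth == "up"] == "up",
               rep$label[truth == "down"] == "down")
  expect_gte(mean(correct), 0.9)                 # pooled over 18 cells
  expect_gte(mean(rep$label[truth == "up"] == "up"), 0.8)
  expect_gte(mean(rep$label[truth == "down"] == "down"), 0.8)
  expect_lte(mean(rep$label[truth == "none"] != "non"), 0.25)
})

test_that("state-restricted means and synchrony match hand computations", {
  rate <- 1
  traces <- rbind(cell_a = c(1, 1, 1, 1, 1, 1),
                  cell_b = c(0, 0, 1, 1, 0, 0))
  s <- calcium_session(traces, rate,
                       events = data.frame(start_s = 2, end_s = 4))
  sa <- state_mean_activity(s)
  # interval [2,4) at 1 Hz covers samples 3..4
  expect_equal(sa$mean_inside, c(1, 1))
  expect_equal(sa$mean_outside, c(1, 0))
  expect_error(state_mean_activity(s, data.frame(start_s = numeric(0),
                                                 end_s = numeric(0))),
               "empty interval")
  # synchrony: duplicated cell -> 1; negated -> -1; hand Pearson toy
  set.seed(74)
  base <- rnorm(50)
  tr3 <- rbind(a = base, b = base, c = -base, d = rnorm(50))
  s3 <- calcium_session(tr3, 1, events = data.frame(start_s = 0, end_s = 50))
  cm <- pairwise_synchrony(s3)
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "c"], -1)
  expect_equal(cm["a", "d"], cor(base, tr3["d", ]), tolerance = 1e-12)
  expect_equal(diag(cm), setNames(rep(1, 4), rownames(tr3)))
  # zero-variance cell flagged
  tr4 <- rbind(a = base, z = rep(2, 50))
  s4 <- calcium_session(tr4, 1, events = data.frame(start_s = 0, end_s = 50))
  cm4 <- pairwise_synchrony(s4)
  expect_true(all(is.na(cm4["z", ])))
  expect_equal(attr(cm4, "degenerate"), "z")
})

test_that("paired pre/post change tracks a planted shift in rescaled means", {
  set.seed(75)
  n <- 1000
  pre_tr <- matrix(rnorm(3 * n), 3,
                   dimnames = list(c("c1", "c2", "c3"), NULL))
  post_tr <- pre_tr
  pre <- calcium_session(pre_tr, 10, session_id = "pre")
  post <- calcium_session(post_tr, 10, session_id = "post")
  reg <- data.frame(pre_cell = c("c1", "c2", "c3"),
                    post_cell = c("c1", "c2", "c3"))
  # identical sessions -> all zeros
  out0 <- paired_session_change(pre, post, reg)
  expect_equal(out0$difference, rep(0, 3), tolerance = 1e-12)
  # rescaling is per session, so a global shift cancels; a shift confined to
  # one epoch of the test window shows up: use intervals
  post_tr2 <- pre_tr
  post_tr2["c2", 1:500] <- post_tr2["c2", 1:500] + 2
  post2 <- calcium_session(post_tr2, 10, session_id = "post2")
  iv <- data.frame(start_s = 0, end_s = 50)   # first half = test epoch
  out <- paired_session_change(pre, post2, reg,
                               pre_intervals = iv, post_intervals = iv)
  expect_gt(out$difference[out$pre_cell == "c2"], 0.5)
  expect_lt(max(abs(out$difference[out$pre_cell != "c2"])), 0.2)
  # unregistered cells excluded and reported
  reg2 <- data.frame(pre_cell = c("c1", "ghost"), post_cell = c("c1", "c9"))
  out2 <- paired_session_change(pre, post, reg2)
  expect_equal(nrow(out2), 1)
  expect_equal(attr(out2, "excluded")$pre_cell, "ghost")
})

test_that("circular shifts leave the trace (and its autocorrelation) untouched", {
  sim <- simulate_calcium_session(calcium_sim_spec(n_cells = 1, seed = 76))
  tr <- sim$session$traces[1, ]
  before <- acf(tr, 5, plot = FALSE)$acf
  invisible(circular_null(tr, sim$truth$event_times, 10, n_shuffles = 50,
                          seed = 77))
  expect_identical(acf(tr, 5, plot = FALSE)$acf, before)
})
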