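# Peri-event statistics for dF/F traces: bout merging, rescaling, the
# post-minus-pre peri-event statistic, the circular-permutation null, the
# two-tailed modulation classifier, state-restricted mean activity, pairwise
# synchrony, and paired pre/post session comparison.

# [a, b) window in seconds -> sample indices (1-based); round half-up
window_indices <- function(t0, win, rate_hz) {
  i1 <- round_half_up((t0 + win[1]) * rate_hz) + 1L
  i2 <- round_half_up((t0 + win[2]) * rate_hz)
  i1:i2
}

#' Merge nearby bouts
#'
#' Consecutive intervals separated by a gap shorter than `min_gap_s` (default
#' 2 s) are merged transitively into single bouts; overlapping intervals are
#' merged too. Input must be sorted by start time.
#'
#' @param intervals data.frame with `start_s`, `end_s`.
#' @param min_gap_s merge threshold in seconds (default 2).
#' @return list (classed `event_series`): `intervals` (merged, non
#'   overlapping) and `entry_times` (the merged start times, used as events).
#' @export
merge_bouts <- function(intervals, min_gap_s = 2.0) {
  stopifnot(all(c("start_s", "end_s") %in% names(intervals)))
  if (is.unsorted(intervals$start_s))
    stop("intervals must be sorted by start_s", call. = FALSE)
  if (any(intervals$end_s <= intervals$start_s))
    stop("interval end_s must exceed start_s", call. = FALSE)
  if (!nrow(intervals))
    return(structure(list(intervals = intervals,
                          entry_times = numeric(0)), class = "event_series"))
  starts <- intervals$start_s; ends <- intervals$end_s
  out_s <- starts[1]; out_e <- ends[1]
  for (i in seq_len(nrow(intervals))[-1]) {
    if (starts[i] - out_e[length(out_e)] < min_gap_s) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], ends[i])
    } else {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, ends[i])
    }
  }
  structure(list(intervals = data.frame(start_s = out_s, end_s = out_e),
                 entry_times = out_s),
            class = "event_series")
}

#' Rescale traces to zero mean, unit SD
#'
#' Standardizes each cell's trace over the full session using the population
#' SD (`sqrt(mean((x - mean(x))^2))`), removing baseline and scale
#' differences so cells are comparable. Idempotent.
#'
#' @param session a [calcium_session()].
#' @return the session with rescaled traces.
#' @export
rescale_traces <- function(session) {
  stopifnot(inherits(session, "calcium_session"))
  m <- rowMeans(session$traces)
  s <- sqrt(rowMeans((session$traces - m)^2))
  if (any(s == 0))
    stop("constant trace for cell(s): ",
         paste(session$cells[s == 0], collapse = ", "), call. = FALSE)
  session$traces <- (session$traces - m) / s
  session
}

#' Peri-event post-minus-pre statistic
#'
#' Mean over events of (mean trace in the post window minus mean trace in the
#' pre window). Windows are given in seconds relative to the event time,
#' half-open on the right, and discretized at the trace rate with
#' round-half-up. Events whose windows leave the recording are dropped with a
#' warning; if all events drop, an error is raised. With `wrap = TRUE`
#' window indices wrap circularly (used by the circular-permutation null so
#' every shuffle keeps all events).
#'
#' @param trace numeric vector (one cell's dF/F).
#' @param event_times event times in seconds.
#' @param rate_hz sampling rate.
#' @param post_window_s,pre_window_s length-2 windows in seconds relative to
#'   the event (defaults `(1, 3)` and its mirror `(-3, -1)`).
#' @param wrap wrap out-of-range window indices circularly (default FALSE).
#' @return the statistic (dF/F units).
#' @export
perievent_statistic <- function(trace, event_times, rate_hz,
                                post_window_s = c(1, 3),
                                pre_window_s = c(-3, -1),
                                wrap = FALSE) {
  n <- length(trace)
  diffs <- vapply(event_times, function(t0) {
    ip <- window_indices(t0, post_window_s, rate_hz)
    iq <- window_indices(t0, pre_window_s, rate_hz)
    if (wrap) {
      ip <- ((ip - 1L) %% n) + 1L
      iq <- ((iq - 1L) %% n) + 1L
    } else if (min(iq, ip) < 1L || max(iq, ip) > n) {
      return(NA_real_)
    }
    mean(trace[ip]) - mean(trace[iq])
  }, numeric(1))
  dropped <- sum(is.na(diffs))
  if (dropped > 0) {
    if (dropped == length(diffs))
      stop("all events have windows outside the recording", call. = FALSE)
    warning(dropped, " event(s) dropped: window outside the recording")
  }
  mean(diffs, na.rm = TRUE)
}

#' Circular-permutation null distribution
#'
#' Builds the null by adding, per shuffle, a single uniform circular offset
#' to all event times modulo the recording length and recomputing the
#' statistic. Offsets are drawn as integer sample shifts (uniform on the
#' sample grid) and windows wrap circularly, so every shuffle uses every
#' event and the trace itself - hence its autocorrelation - is untouched.
#'
#' @param trace numeric vector.
#' @param event_times event times in seconds.
#' @param rate_hz sampling rate.
#' @param statistic_fn function(trace, event_times, rate_hz, wrap) -> number;
#'   defaults to [perievent_statistic()].
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed integer seed.
#' @return numeric vector of `n_shuffles` null statistics.
#' @export
circular_null <- function(trace, event_times, rate_hz, statistic_fn = NULL,
                          n_shuffles = 1000, seed = 1L) {
  set.seed(check_count(seed, "seed", min = 0L))
  n <- length(trace)
  if (is.null(statistic_fn)) statistic_fn <- perievent_statistic
  offsets <- sample.int(n, n_shuffles, replace = TRUE) - 1L
  T_s <- n / rate_hz
  vapply(offsets, function(off) {
    shifted <- (event_times + off / rate_hz) %% T_s
    statistic_fn(trace, shifted, rate_hz, wrap = TRUE)
  }, numeric(1))
}

# fast path used by classify_session / acceptance: rolling window means via
# cumsum, all shuffles at once
perievent_null_fast <- function(trace, event_times, rate_hz,
                                post_window_s = c(1, 3),
                                pre_window_s = c(-3, -1),
                                n_shuffles = 1000, seed = 1L) {
  set.seed(seed)
  n <- length(trace)
  wlen_post <- round_half_up(post_window_s[2] * rate_hz) -
    round_half_up(post_window_s[1] * rate_hz)
  wlen_pre <- round_half_up(pre_window_s[2] * rate_hz) -
    round_half_up(pre_window_s[1] * rate_hz)
  cs <- cumsum(c(trace, trace))          # doubled for wrap
  wmean <- function(start_idx, wlen) {   # start_idx 1-based, wrapped
    s <- ((start_idx - 1L) %% n) + 1L
    (cs[s + wlen - 1L] - c(0, cs)[s]) / wlen
  }
  post_start <- round_half_up(outer(event_times, post_window_s[1], "+") * rate_hz) + 1L
  pre_start <- round_half_up(outer(event_times, pre_window_s[1], "+") * rate_hz) + 1L
  offsets <- sample.int(n, n_shuffles, replace = TRUE) - 1L
  null_stats <- vapply(offsets, function(off) {
    mean(wmean(post_start + off, wlen_post) - wmean(pre_start + off, wlen_pre))
  }, numeric(1))
  observed <- mean(wmean(post_start, wlen_post) - wmean(pre_start, wlen_pre))
  list(observed = observed, null = null_stats)
}

#' Classify a cell's modulation from its null distribution
#'
#' Bootstrap probability with the add-one convention:
#' `p = (1 + #{null >= observed}) / (n_shuffles + 1)` (never exactly 0 or 1),
#' with exact ties between null and observed counted at half weight so the
#' degenerate all-tie case (e.g. a constant trace) sits mid-distribution;
#' under a continuous null ties have probability zero and the two
#' conventions coincide. Two-tailed rule at level `alpha`: `up` if
#' `p < alpha/2`, `down` if `p > 1 - alpha/2`, else `non`. Adding a constant
#' to both observed and null leaves the label unchanged.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null statistics (nonempty).
#' @param alpha two-tailed level (default 0.05).
#' @return list: `observed`, `bootstrap_probability`, `label`, `n_shuffles`,
#'   `alpha`.
#' @export
classify_modulation <- function(observed, null, alpha = 0.05) {
  if (!length(null)) stop("empty null distribution", call. = FALSE)
  p <- (1 + sum(null > observed) + 0.5 * sum(null == observed)) /
    (length(null) + 1)
  label <- if (p < alpha / 2) "up" else if (p > 1 - alpha / 2) "down" else "non"
  list(observed = observed, bootstrap_probability = p, label = label,
       n_shuffles = length(null), alpha = alpha)
}

#' Classify every cell of a session
#'
#' Runs the peri-event statistic, circular-permutation null and two-tailed
#' classifier for each cell, using the session's event entry times (bouts
#' merged at `min_gap_s` first).
#'
#' @param session a [calcium_session()].
#' @param post_window_s,pre_window_s windows in seconds (defaults `(1, 3)` /
#'   `(-3, -1)`).
#' @param n_shuffles shuffles per cell (default 1000).
#' @param alpha two-tailed level (default 0.05).
#' @param min_gap_s bout-merge threshold (default 2 s).
#' @param seed integer seed (per-cell seeds derived deterministically).
#' @return data.frame (classed `modulation_report`): per cell `observed`,
#'   `bootstrap_probability`, `label`.
#' @export
classify_session <- function(session, post_window_s = c(1, 3),
                             pre_window_s = c(-3, -1), n_shuffles = 1000,
                             alpha = 0.05, min_gap_s = 2.0, seed = 1L) {
  stopifnot(inherits(session, "calcium_session"))
  ev <- merge_bouts(session$events, min_gap_s)$entry_times
  if (!length(ev)) stop("session has no events", call. = FALSE)
  rows <- lapply(seq_len(nrow(session$traces)), function(i) {
    res <- perievent_null_fast(session$traces[i, ], ev, session$rate_hz,
                               post_window_s, pre_window_s, n_shuffles,
                               seed = (seed + i) %% .Machine$integer.max)
    cl <- classify_modulation(res$observed, res$null, alpha)
    data.frame(cell = session$cells[i], observed = cl$observed,
               bootstrap_probability = cl$bootstrap_probability,
               label = cl$label, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  attr(report, "n_shuffles") <- n_shuffles
  attr(report, "alpha") <- alpha
  class(report) <- c("modulation_report", "data.frame")
  report
}

# sample-index union of intervals
interval_sample_idx <- function(intervals, rate_hz, n) {
  idx <- integer(0)
  for (i in seq_len(nrow(intervals))) {
    i1 <- round_half_up(intervals$start_s[i] * rate_hz) + 1L
    i2 <- round_half_up(intervals$end_s[i] * rate_hz)
    if (i2 >= i1) idx <- c(idx, i1:min(i2, n))
  }
  sort(unique(idx[idx >= 1 & idx <= n]))
}

#' Mean activity inside and outside a set of intervals
#'
#' Per-cell mean dF/F over the union of interval samples (e.g. social-zone
#' occupancy) and over its complement.
#'
#' @param session a [calcium_session()].
#' @param intervals data.frame `start_s`, `end_s`; defaults to the session's
#'   events.
#' @return data.frame: `cell`, `mean_inside`, `mean_outside`.
#' @export
state_mean_activity <- function(session, intervals = NULL) {
  stopifnot(inherits(session, "calcium_session"))
  if (is.null(intervals)) intervals <- session$events
  n <- ncol(session$traces)
  idx <- interval_sample_idx(intervals, session$rate_hz, n)
  if (!length(idx)) stop("empty interval union", call. = FALSE)
  comp <- setdiff(seq_len(n), idx)
  data.frame(cell = session$cells,
             mean_inside = rowMeans(session$traces[, idx, drop = FALSE]),
             mean_outside = if (length(comp))
               rowMeans(session$traces[, comp, drop = FALSE]) else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise synchrony restricted to in-zone samples
#'
#' Pearson correlation between all cell pairs over the samples inside the
#' given intervals. Cells with zero in-zone variance get `NA` rows/columns
#' and are listed in the `degenerate` attribute.
#'
#' @param session a [calcium_session()].
#' @param intervals data.frame `start_s`, `end_s`; defaults to the session's
#'   events.
#' @return symmetric correlation matrix (unit diagonal for well-defined
#'   cells) with attributes `mean_offdiag` and `degenerate`.
#' @export
pairwise_synchrony <- function(session, intervals = NULL) {
  stopifnot(inherits(session, "calcium_session"))
  if (is.null(intervals)) intervals <- session$events
  idx <- interval_sample_idx(intervals, session$rate_hz, ncol(session$traces))
  if (length(idx) < 2L) stop("need >= 2 in-zone samples", call. = FALSE)
  sub <- session$traces[, idx, drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  degen <- session$cells[sds == 0]
  cm <- suppressWarnings(stats::cor(t(sub)))
  cm[sds == 0, ] <- NA_real_; cm[, sds == 0] <- NA_real_
  diag(cm)[sds > 0] <- 1
  off <- cm[upper.tri(cm)]
  attr(cm, "mean_offdiag") <- mean(off, na.rm = TRUE)
  attr(cm, "degenerate") <- degen
  cm
}

#' Paired pre/post change in rescaled mean activity
#'
#' Rescales each session independently ([rescale_traces()]), computes the
#' per-cell mean rescaled activity over the test epoch (whole session by
#' default, or supplied intervals per session), and returns post minus pre
#' for every registered cell. Unregistered cells are excluded and reported.
#'
#' @param pre_session,post_session [calcium_session()] objects.
#' @param cell_registry data.frame with columns `pre_cell`, `post_cell`
#'   (one-to-one mapping).
#' @param pre_intervals,post_intervals optional test-epoch intervals.
#' @return data.frame: `pre_cell`, `post_cell`, `pre_mean`, `post_mean`,
#'   `difference`; attribute `excluded` lists unregistered cells.
#' @export
paired_session_change <- function(pre_session, post_session, cell_registry,
                                  pre_intervals = NULL,
                                  post_intervals = NULL) {
  stopifnot(all(c("pre_cell", "post_cell") %in% names(cell_registry)))
  if (anyDuplicated(cell_registry$pre_cell) ||
      anyDuplicated(cell_registry$post_cell))
    stop("cell_registry must be one-to-one", call. = FALSE)
  keep <- cell_registry$pre_cell %in% pre_session$cells &
    cell_registry$post_cell %in% post_session$cells
  excluded <- cell_registry[!keep, , drop = FALSE]
  reg <- cell_registry[keep, , drop = FALSE]
  if (!nrow(reg)) stop("no registered cell present in both sessions",
                       call. = FALSE)
  epoch_means <- function(session, intervals) {
    s <- rescale_traces(session)
    if (is.null(intervals))
      return(stats::setNames(rowMeans(s$traces), s$cells))
    sm <- state_mean_activity(s, intervals)
    stats::setNames(sm$mean_inside, sm$cell)
  }
  pre_m <- epoch_means(pre_session, pre_intervals)
  post_m <- epoch_means(post_session, post_intervals)
  out <- data.frame(pre_cell = reg$pre_cell, post_cell = reg$post_cell,
                    pre_mean = as.numeric(pre_m[reg$pre_cell]),
                    post_mean = as.numeric(post_m[reg$post_cell]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$difference <- out$post_mean - out$pre_mean
  attr(out, "excluded") <- excluded
  out
}
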