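#' Specification for the calcium-trace simulator
#'
#' Describes a synthetic microendoscopy session: stationary AR(1) Gaussian
#' noise traces (marginal SD 1, so `transient_amplitude` is in units of the
#' noise SD) sampled at `rate_hz`, with a planted subset of cells adding
#' positive (up-modulated) or negative (down-modulated) exponentially decaying
#' transients at each event time. Event times are drawn uniformly with a
#' minimum spacing larger than the peri-event window span so windows never
#' overlap.
#'
#' @param n_cells number of cells.
#' @param duration_s recording length in seconds.
#' @param rate_hz sampling rate (the study's processed traces run at 10 Hz).
#' @param ar_coefficient AR(1) coefficient in `(-1, 1)`.
#' @param n_events number of zone-entry events.
#' @param frac_up,frac_down fractions of cells planted as up-/down-modulated;
#'   must sum to at most 1.
#' @param transient_amplitude peak dF/F of the planted transient (noise-SD
#'   units); 0 plants nothing and all truth labels are `none`.
#' @param transient_decay_s exponential decay time constant in seconds.
#' @param min_spacing_s minimum spacing between consecutive events (default
#'   6 s: twice the 3 s reach of the peri-event windows).
#' @param seed integer seed.
#' @return validated `calcium_sim_spec` list.
#' @export
calcium_sim_spec <- function(n_cells = 50, duration_s = 600, rate_hz = 10,
                             ar_coefficient = 0.8, n_events = 10,
                             frac_up = 0, frac_down = 0,
                             transient_amplitude = 3, transient_decay_s = 2,
                             min_spacing_s = 6, seed = 1L) {
  check_positive(rate_hz, "rate_hz")
  check_positive(duration_s, "duration_s")
  check_count(n_cells, "n_cells")
  check_count(n_events, "n_events")
  if (abs(ar_coefficient) >= 1)
    stop_field("ar_coefficient", "must lie in (-1, 1)")
  check_fraction(frac_up, "frac_up"); check_fraction(frac_down, "frac_down")
  if (frac_up + frac_down > 1)
    stop_field("frac_up/frac_down", "fractions must sum to <= 1")
  if (duration_s * rate_hz < 10 * n_events)
    stop_field("n_events", "recording too short: need duration_s*rate_hz >= 10*n_events")
  structure(list(n_cells = n_cells, duration_s = duration_s, rate_hz = rate_hz,
                 ar_coefficient = ar_coefficient, n_events = n_events,
                 frac_up = frac_up, frac_down = frac_down,
                 transient_amplitude = transient_amplitude,
                 transient_decay_s = check_positive(transient_decay_s,
                                                    "transient_decay_s"),
                 min_spacing_s = check_positive(min_spacing_s, "min_spacing_s"),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "calcium_sim_spec")
}

# event start times uniform in [margin, duration - margin] with minimum
# spacing; drawn by the order-statistics gap construction (exact, no rejection)
draw_event_times <- function(n_events, duration_s, min_spacing_s, margin_s) {
  lo <- margin_s; hi <- duration_s - margin_s
  slack <- (hi - lo) - (n_events - 1) * min_spacing_s
  if (slack <= 0)
    stop("cannot place ", n_events, " events with spacing ", min_spacing_s,
         " s in [", lo, ", ", hi, "] s", call. = FALSE)
  u <- sort(stats::runif(n_events, 0, slack))
  lo + u + (seq_len(n_events) - 1) * min_spacing_s
}

#' Simulate a calcium session with planted modulated cells
#'
#' @param spec a [calcium_sim_spec()].
#' @return list with `session` (a [calcium_session()]; events are intervals
#'   starting at each planted event time) and `truth` (`modulated_cells`:
#'   named vector over cells with values `up`/`down`/`none`, and
#'   `event_times`).
#' @export
simulate_calcium_session <- function(spec) {
  if (!inherits(spec, "calcium_sim_spec")) spec <- do.call(calcium_sim_spec, spec)
  set.seed(spec$seed)
  n <- round(spec$duration_s * spec$rate_hz)
  phi <- spec$ar_coefficient
  margin <- spec$min_spacing_s / 2
  ev <- draw_event_times(spec$n_events, spec$duration_s, spec$min_spacing_s,
                         margin)
  # bout intervals: dwell short enough never to reach the next event window
  dwell <- stats::runif(spec$n_events, 0.5, min(2, spec$min_spacing_s / 3))
  events <- data.frame(start_s = ev, end_s = ev + dwell)

  n_up <- if (spec$transient_amplitude == 0) 0L else ceiling(spec$frac_up * spec$n_cells)
  n_down <- if (spec$transient_amplitude == 0) 0L else ceiling(spec$frac_down * spec$n_cells)
  labels <- rep("none", spec$n_cells)
  if (n_up > 0) labels[seq_len(n_up)] <- "up"
  if (n_down > 0) labels[n_up + seq_len(n_down)] <- "down"

  tgrid <- (seq_len(n) - 1) / spec$rate_hz
  kernel <- numeric(n)
  for (t0 in ev) {
    after <- tgrid >= t0
    kernel[after] <- kernel[after] +
      exp(-(tgrid[after] - t0) / spec$transient_decay_s)
  }

  innov_sd <- sqrt(1 - phi^2)   # marginal SD 1
  traces <- matrix(0, spec$n_cells, n,
                   dimnames = list(sprintf("cell%04d", seq_len(spec$n_cells)),
                                   NULL))
  for (i in seq_len(spec$n_cells)) {
    x <- as.numeric(stats::arima.sim(list(ar = phi), n, sd = innov_sd))
    if (labels[i] == "up") x <- x + spec$transient_amplitude * kernel
    if (labels[i] == "down") x <- x - spec$transient_amplitude * kernel
    traces[i, ] <- x
  }
  session <- calcium_session(traces, spec$rate_hz, events,
                             session_id = sprintf("sim_seed%d", spec$seed))
  list(session = session,
       truth = list(modulated_cells = stats::setNames(labels, rownames(traces)),
                    event_times = ev))
}
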