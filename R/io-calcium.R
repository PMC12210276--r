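# Calcium traces on disk: wide CSV with a leading time column (seconds) and
# one column per cell; events as CSV with start_s,end_s columns.

#' Write calcium traces and events to CSV
#'
#' @param session a [calcium_session()].
#' @param traces_path wide CSV path (`time_s` column then one column per
#'   cell).
#' @param events_path optional CSV path for events (`start_s`, `end_s`).
#' @export
write_calcium <- function(session, traces_path, events_path = NULL) {
  stopifnot(inherits(session, "calcium_session"))
  n <- ncol(session$traces)
  df <- data.frame(time_s = (seq_len(n) - 1) / session$rate_hz,
                   t(session$traces), check.names = FALSE)
  utils::write.csv(df, traces_path, row.names = FALSE, quote = FALSE)
  if (!is.null(events_path))
    utils::write.csv(session$events, events_path, row.names = FALSE,
                     quote = FALSE)
  invisible(session)
}

#' Load a calcium session from CSV files
#'
#' @param traces_path wide CSV with a `time_s` column and one column per cell.
#' @param events_path optional events CSV (`start_s`, `end_s`, sorted,
#'   non-overlapping).
#' @param rate_hz sampling rate; must agree with the time column spacing
#'   within 1e-6 s.
#' @param session_id identifier.
#' @return a [calcium_session()].
#' @export
load_calcium <- function(traces_path, events_path = NULL, rate_hz,
                         session_id = basename(traces_path)) {
  df <- utils::read.csv(traces_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df))
    stop("traces CSV must have a time_s column", call. = FALSE)
  tm <- df$time_s
  if (length(tm) > 1 && any(abs(diff(tm) - 1 / rate_hz) > 1e-6))
    stop("time column spacing does not match rate_hz = ", rate_hz,
         call. = FALSE)
  traces <- t(as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE]))
  events <- NULL
  if (!is.null(events_path)) {
    events <- utils::read.csv(events_path, stringsAsFactors = FALSE)
    if (!all(c("start_s", "end_s") %in% names(events)))
      stop("events CSV must have start_s and end_s columns", call. = FALSE)
  }
  calcium_session(traces, rate_hz, events, session_id)
}
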