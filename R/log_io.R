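# Canonical numeric form used in log entries: a double exactly equal to
# its 6-decimal representation, so that JSONL serialization round-trips
# to the identical in-memory value.
canon_num <- function(x) as.numeric(sprintf("%.6f", x))

canon_payload <- function(payload) {
  lapply(payload, function(v) if (is.numeric(v)) canon_num(v) else v)
}

#' Export an event log as JSON Lines
#'
#' One log entry per line with fields `t_s`, `event`, `payload`. The
#' representation is canonical: exporting, reading back and exporting
#' again yields a byte-identical file, and [read_log()] returns a list
#' identical to the one exported.
#'
#' @param x An `engine_state`, a `team_log`, or a bare list of log
#'   entries.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_log <- function(x, path) {
  entries <- as_log_entries(x)
  lines <- vapply(entries, function(e) {
    jsonlite::toJSON(list(t_s = e$t_s, event = e$event,
                          payload = e$payload),
                     auto_unbox = TRUE, digits = NA, null = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

as_log_entries <- function(x) {
  if (inherits(x, "engine_state")) x$log
  else if (inherits(x, "team_log")) x$log
  else if (is.list(x)) x
  else stop("cannot interpret object as an event log", call. = FALSE)
}

#' Read a JSONL event log
#'
#' Validates each record (known event type, nonnegative time) and the
#' strict time ordering invariant: `t_s` must be nondecreasing (ties are
#' resolved by line order). Malformed or out-of-order records raise an
#' error naming the offending line number.
#'
#' @param path Path to a JSONL file written by [export_log()].
#' @return List of log entries (`t_s`, `event`, `payload`).
#' @export
read_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  entries <- vector("list", length(lines))
  last_t <- -Inf
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      stop("malformed log record at line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    if (is.null(rec$t_s) || is.null(rec$event))
      stop("malformed log record at line ", i, ": missing t_s or event",
           call. = FALSE)
    t_s <- as.numeric(rec$t_s)
    if (!is.finite(t_s) || t_s < 0)
      stop("malformed log record at line ", i, ": bad t_s", call. = FALSE)
    if (!rec$event %in% log_event_types())
      stop("malformed log record at line ", i, ": unknown event '",
           rec$event, "'", call. = FALSE)
    if (t_s < last_t)
      stop("log ordering violated at line ", i,
           ": t_s decreases", call. = FALSE)
    last_t <- t_s
    payload <- rec$payload %||% list()
    payload <- lapply(as.list(payload),
                      function(v) if (is.numeric(v)) as.numeric(v) else v)
    entries[[i]] <- list(t_s = t_s, event = as.character(rec$event),
                         payload = payload)
  }
  entries
}
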