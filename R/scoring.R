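#' Load a deviation checklist or clinical-performance task list
#'
#' Instruments are declarative YAML: each item/task names an anchor
#' event (and button for taps) plus optional payload constraints, a time
#' window, and a minimum event count. Checklist items score 0 when their
#' rule holds and 1 (a deviation) otherwise; performance tasks score 0
#' when absent, full points when fully met and full-minus-one when
#' partial/late/incorrect.
#'
#' @param path YAML instrument file; defaults to the bundled
#'   reconstructions.
#' @return A list of class `checklist` / `cpt_tasks`.
#' @export
load_checklist <- function(path = resusim_extdata("cdevplus.yaml")) {
  raw <- yaml::read_yaml(path)
  items <- lapply(raw$items, validate_rule_item)
  structure(list(instrument = raw$instrument %||% "checklist",
                 items = items, max_items = raw$max_items %||% length(items)),
            class = "checklist")
}

#' @rdname load_checklist
#' @export
load_cpt <- function(path = resusim_extdata("cpt_asystole.yaml")) {
  raw <- yaml::read_yaml(path)
  tasks <- lapply(raw$tasks, function(t) {
    t <- validate_rule_item(t)
    if (!is_scalar_number(t$max_points) || !t$max_points %in% c(1, 2))
      stop("task '", t$id, "': max_points must be 1 or 2", call. = FALSE)
    t
  })
  structure(list(instrument = raw$instrument %||% "cpt", tasks = tasks,
                 max_total = raw$max_total %||%
                   sum(vapply(tasks, function(t) t$max_points, 0))),
            class = "cpt_tasks")
}

validate_rule_item <- function(item) {
  if (!is_scalar_string(item$id))
    stop("instrument item without id", call. = FALSE)
  r <- item$rule
  if (is.null(r$event) || !r$event %in% log_event_types())
    stop("item '", item$id, "': rule must name a known event type",
         call. = FALSE)
  if (!is.null(r$window) &&
      !(r$window$from %||% "case_start") %in% c("case_start", "recognition"))
    stop("item '", item$id, "': window 'from' must be case_start or ",
         "recognition", call. = FALSE)
  item
}

# Events of the log matching the rule's anchor (event type + button).
matching_events <- function(log, rule) {
  Filter(function(e) {
    e$event == rule$event &&
      (is.null(rule$button) || identical(e$payload$button, rule$button))
  }, log)
}

# Evaluate one declarative rule against a team log.
# Returns list(present, satisfied): `present` = anchor event(s) found in
# the required count; `satisfied` = present AND payload/window criteria
# met. A payload constraint referencing a key absent from a matched
# event is a scoring error (the instrument does not fit the log schema).
eval_rule <- function(team, rule, item_id) {
  ev <- matching_events(team$log, rule)
  min_count <- rule$min_count %||% 1
  if (length(ev) < min_count)
    return(list(present = FALSE, satisfied = FALSE))
  ok <- TRUE
  if (!is.null(rule$payload)) {
    key <- rule$payload$key
    vals <- lapply(ev, function(e) {
      if (!key %in% names(e$payload))
        stop("scoring error in item '", item_id, "': payload key '", key,
             "' missing from matched event", call. = FALSE)
      e$payload[[key]]
    })
    ok <- if (!is.null(rule$payload$equals_key)) {
      refs <- lapply(ev, function(e) {
        if (!rule$payload$equals_key %in% names(e$payload))
          stop("scoring error in item '", item_id, "': payload key '",
               rule$payload$equals_key, "' missing from matched event",
               call. = FALSE)
        e$payload[[rule$payload$equals_key]]
      })
      any(mapply(function(v, r) isTRUE(all.equal(v, r)), vals, refs))
    } else {
      any(vapply(vals, function(v) identical(v, rule$payload$equals), TRUE))
    }
  }
  if (ok && !is.null(rule$window)) {
    origin <- if ((rule$window$from %||% "case_start") == "recognition")
      team$ca_recognition_t_s else 0
    if (is.na(origin)) ok <- FALSE # timeliness cannot be established
    else {
      t_first <- min(vapply(ev, function(e) e$t_s, 0))
      ok <- (t_first - origin) <= rule$window$max_s
    }
  }
  list(present = TRUE, satisfied = ok)
}

#' Score a team log with the 16-item deviation checklist
#'
#' Each item contributes 0 when the correct critical action was
#' performed (its rule holds) and 1 point otherwise; the total ranges
#' 0-16 and higher totals mean more deviations from the guidelines.
#'
#' @param team A `team_log` (from [run_scenario()] or [read_cohort()]).
#' @param checklist A [load_checklist()] instrument.
#' @return List of class `checklist_result`: `per_item` (named 0/1
#'   vector) and `total`.
#' @export
score_cdevplus <- function(team, checklist = load_checklist()) {
  stopifnot(inherits(checklist, "checklist"))
  if (length(checklist$items) != checklist$max_items)
    stop("checklist must have exactly ", checklist$max_items, " items",
         call. = FALSE)
  per_item <- vapply(checklist$items, function(item) {
    res <- eval_rule(team, item$rule, item$id)
    if (res$satisfied) 0L else 1L
  }, 0L)
  names(per_item) <- vapply(checklist$items, function(i) i$id, "")
  structure(list(per_item = per_item, total = sum(per_item)),
            class = "checklist_result")
}

#' @export
print.checklist_result <- function(x, ...) {
  cat("<checklist_result> total deviations:", x$total, "/",
      length(x$per_item), "\n")
  flagged <- names(x$per_item)[x$per_item == 1L]
  if (length(flagged)) cat("  deviated:", paste(flagged, collapse = ", "),
                           "\n")
  invisible(x)
}

#' Score a team log with the clinical-performance task list
#'
#' @param team A `team_log`.
#' @param tasks A [load_cpt()] instrument.
#' @return List of class `cpt_result`: `per_task` scores and `total`
#'   (0-13 for the bundled asystole section).
#' @export
score_cpt <- function(team, tasks = load_cpt()) {
  stopifnot(inherits(tasks, "cpt_tasks"))
  per_task <- vapply(tasks$tasks, function(task) {
    res <- eval_rule(team, task$rule, task$id)
    if (!res$present) 0
    else if (res$satisfied) task$max_points
    else task$max_points - 1
  }, 0)
  names(per_task) <- vapply(tasks$tasks, function(t) t$id, "")
  structure(list(per_task = per_task, total = sum(per_task),
                 max_total = tasks$max_total),
            class = "cpt_result")
}

#' @export
print.cpt_result <- function(x, ...) {
  cat("<cpt_result> total:", x$total, "/", x$max_total, "\n")
  invisible(x)
}

#' Time from recognition of arrest to first epinephrine
#'
#' @param team A `team_log` containing the recognition marker.
#' @param epi_button Button id of the administration action.
#' @return Seconds (numeric), or `NA` when epinephrine was never
#'   administered.
#' @export
time_to_epinephrine <- function(team,
                                epi_button = "administer_epinephrine") {
  if (is.null(team$ca_recognition_t_s) || is.na(team$ca_recognition_t_s))
    stop("log lacks a recognition-of-arrest marker", call. = FALSE)
  ev <- Filter(function(e) e$event == "TAP" &&
                 identical(e$payload$button, epi_button), team$log)
  if (!length(ev)) return(NA_real_)
  t_adm <- min(vapply(ev, function(e) e$t_s, 0))
  if (t_adm < team$ca_recognition_t_s)
    stop("administration precedes recognition: log ordering invalid",
         call. = FALSE)
  t_adm - team$ca_recognition_t_s
}

#' Score a whole cohort into a tidy table
#'
#' One row per team: arm, every checklist item (0/1), the deviation
#' total, the clinical-performance total and time to epinephrine.
#'
#' @param cohort List of `team_log` objects.
#' @param checklist,tasks Instruments.
#' @return A data frame.
#' @export
score_cohort <- function(cohort, checklist = load_checklist(),
                         tasks = load_cpt()) {
  rows <- lapply(cohort, function(team) {
    cd <- score_cdevplus(team, checklist)
    cp <- score_cpt(team, tasks)
    tte <- if (is.null(team$ca_recognition_t_s) ||
               is.na(team$ca_recognition_t_s)) NA_real_
           else time_to_epinephrine(team)
    c(list(team_id = team$team_id, arm = team$arm),
      as.list(cd$per_item),
      list(cdevplus_total = cd$total, cpt_total = cp$total,
           time_to_epi_s = tte))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                        stringsAsFactors = FALSE)))
}
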