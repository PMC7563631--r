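#' Start a resuscitation case
#'
#' Creates the live engine state at the graph's start node, with the
#' rhythm-check timer armed (120 s by default) and `CASE_START` logged at
#' t = 0. The engine is purely functional: every operation takes a state
#' and returns a new one, and time only advances through [tick()], never
#' from a wall clock, so identical inputs always give identical logs.
#'
#' @param graph A validated [flow_graph][load_flow_graph].
#' @param profile A [patient_profile()].
#' @param config An `engine_config` from [load_engine_config()].
#' @return An object of class `engine_state`.
#' @examples
#' st <- start_case(load_flow_graph(), patient_profile(10))
#' st$timers$rhythm_check$remaining_s
#' @export
start_case <- function(graph, profile, config = load_engine_config()) {
  stopifnot(inherits(graph, "flow_graph"), inherits(config, "engine_config"))
  if (!inherits(profile, "patient_profile"))
    profile <- patient_profile(profile)
  timers <- list()
  for (nm in names(config$timers)) {
    spec <- timer_spec(config, nm)
    start_now <- nm != "medication" ||
      (config$timers$medication$start %||% "first_epi") == "case_start"
    timers[[nm]] <- list(spec = spec, remaining_s = spec$period_s,
                         active = start_now)
  }
  state <- structure(list(
    graph = graph, profile = profile, config = config,
    node_id = graph$start_node, elapsed_s = 0, total_counter_s = 0,
    cycle_count = 0L, epi_dose_count = 0L, shock_count = 0L,
    timers = timers, overlay = NULL, pending_alerts = list(),
    tapped = character(0), ended = FALSE, log = list()
  ), class = "engine_state")
  log_append(state, "CASE_START",
             list(weight_kg = profile$weight_kg, node = graph$start_node))
}

log_append <- function(state, event, payload = list()) {
  stopifnot(event %in% log_event_types())
  entry <- list(t_s = canon_num(state$elapsed_s), event = event,
                payload = canon_payload(payload))
  state$log[[length(state$log) + 1L]] <- entry
  state
}

current_node <- function(state) state$graph$nodes[[state$node_id]]

advance_to <- function(state, target) {
  if (is.null(target)) return(state) # terminal screen: stay
  state$node_id <- target
  state$tapped <- character(0)
  state
}

#' Tap a button on the current screen
#'
#' Sequential buttons are marked done and the screen advances only once
#' every sequential button has been tapped; choice buttons advance
#' immediately along their edge. Tapping a button that is not visible on
#' the current screen is rejected and leaves the state (and log)
#' unchanged. Certain configured buttons carry side effects: the
#' epinephrine-administration button increments the dose counter, arms
#' the medication timer on the first dose (under the default
#' `start: first_epi` policy) and clears any pending medication alert;
#' the shock button increments the shock counter.
#'
#' @param state An `engine_state`.
#' @param button_id Button identifier on the current node.
#' @param payload Optional named list recorded in the log entry (e.g.
#'   observed compression ratio).
#' @return The new `engine_state`.
#' @export
tap <- function(state, button_id, payload = list()) {
  nd <- current_node(state)
  btn <- NULL
  for (b in nd$buttons) if (b$id == button_id) { btn <- b; break }
  if (is.null(btn))
    stop("button '", button_id, "' is not visible on node '", nd$id, "'",
         call. = FALSE)
  state <- log_append(state, "TAP",
                      c(list(button = button_id, node = nd$id), payload))
  state <- apply_button_effects(state, button_id)
  if ((btn$kind %||% "ACTION") == "CHOICE") {
    target <- if (is.list(nd$on_advance)) nd$on_advance[[button_id]]
              else nd$on_advance
    if (is.null(target))
      stop("node '", nd$id, "' has no edge for choice '", button_id, "'",
           call. = FALSE)
    return(advance_to(state, target))
  }
  state$tapped <- union(state$tapped, button_id)
  seq_ids <- vapply(Filter(function(b) b$layout == "SEQUENTIAL", nd$buttons),
                    function(b) b$id, "")
  if (nd$advance_rule == "ALL_SEQUENTIAL_TAPPED" &&
      all(seq_ids %in% state$tapped)) {
    state <- advance_to(state, if (is.list(nd$on_advance))
      nd$on_advance[[1]] else nd$on_advance)
  }
  state
}

apply_button_effects <- function(state, button_id) {
  btns <- state$config$buttons
  if (identical(button_id, btns$epinephrine_administration)) {
    state$epi_dose_count <- state$epi_dose_count + 1L
    med <- state$timers$medication
    if (!is.null(med)) {
      med$active <- TRUE
      med$remaining_s <- med$spec$period_s
      state$timers$medication <- med
    }
    state <- drop_alerts(state, "medication")
  }
  if (identical(button_id, btns$shock_delivery))
    state$shock_count <- state$shock_count + 1L
  state
}

drop_alerts <- function(state, name) {
  state$pending_alerts <- Filter(function(a) a$name != name,
                                 state$pending_alerts)
  state
}

#' Acknowledge (clear) a pending alert
#'
#' Alerts persist in `pending_alerts` until acknowledged; the
#' rhythm-check alert is cleared implicitly by [select_rhythm()] and the
#' medication alert by the epinephrine-administration tap.
#'
#' @param state An `engine_state`.
#' @param name Timer/alert name.
#' @return The new `engine_state`.
#' @export
acknowledge_alert <- function(state, name) drop_alerts(state, name)

#' Select the identified cardiac rhythm
#'
#' Only valid on a rhythm-choice screen. Branches into the pathway tagged
#' for the rhythm class: asystole/PEA to the nonshockable pathway, VF or
#' pulseless VT to the shockable pathway (with shock advice and the
#' weight-based energy logged), and an organized rhythm with a pulse to
#' post-resuscitation care (`ROSC_DECLARED`). Clears any pending
#' rhythm-check alert.
#'
#' @param state An `engine_state` currently on a rhythm-choice node.
#' @param rhythm One of the values accepted by [rhythm_class()].
#' @return The new `engine_state`.
#' @export
select_rhythm <- function(state, rhythm) {
  nd <- current_node(state)
  if (!isTRUE(nd$rhythm_choice))
    stop("rhythm selection outside a rhythm-choice node ('", nd$id, "')",
         call. = FALSE)
  cls <- rhythm_class(rhythm)
  state <- log_append(state, "RHYTHM_SELECTED",
                      list(rhythm = rhythm, class = cls))
  state <- drop_alerts(state, "rhythm_check")
  if (cls == "shockable") {
    j <- defib_energy(state$shock_count + 1L, state$profile,
                      state$config$energy)
    state <- log_append(state, "SHOCK_ADVISED",
                        list(shock_number = state$shock_count + 1L,
                             energy_j = j))
  }
  if (cls == "rosc")
    state <- log_append(state, "ROSC_DECLARED", list(rhythm = rhythm))
  target <- nd$on_advance[[cls]]
  if (is.null(target))
    stop("rhythm-choice node '", nd$id, "' has no edge for class '", cls, "'",
         call. = FALSE)
  advance_to(state, target)
}

#' Advance past the current screen
#'
#' With `force = FALSE` this is only permitted once the node's advance
#' rule is satisfied (the default app behaviour: progression requires all
#' recommended actions to be tapped). `force = TRUE` models teams working
#' without enforced prompts — e.g. the control arm of a simulated study,
#' or a team moving on despite omitted actions — and advances along the
#' node's first edge regardless.
#'
#' @param state An `engine_state`.
#' @param force Allow advancing with incomplete actions.
#' @return The new `engine_state`.
#' @export
advance_node <- function(state, force = FALSE) {
  nd <- current_node(state)
  seq_ids <- vapply(Filter(function(b) b$layout == "SEQUENTIAL", nd$buttons),
                    function(b) b$id, "")
  complete <- nd$advance_rule == "ALL_SEQUENTIAL_TAPPED" &&
    all(seq_ids %in% state$tapped)
  if (!force && !complete)
    stop("cannot advance: recommended actions on '", nd$id,
         "' not all tapped", call. = FALSE)
  target <- if (is.list(nd$on_advance)) nd$on_advance[[1]] else nd$on_advance
  advance_to(state, target)
}

#' Advance simulated time
#'
#' Adds `dt_s` seconds to the case clock, decrementing every active
#' countdown. A timer reaching zero logs `TIMER_FIRED` and `ALERT_RAISED`
#' at the exact firing instant, re-arms if repeating, and queues a
#' pending alert; firings are processed in-order within the tick, so a
#' single large `dt_s` fires a 120 s repeating timer `floor(dt_s/120)`
#' times. When the medication and rhythm-check timers expire at the same
#' instant the medication alert is raised (and queued) first — timer-
#' triggered medication actions have priority. Each rhythm-check firing
#' increments the completed-cycle counter whether or not the user
#' responds. Overlays do not stop timers.
#'
#' @param state An `engine_state`.
#' @param dt_s Positive time step in seconds.
#' @return The new `engine_state`.
#' @export
tick <- function(state, dt_s) {
  if (!is_scalar_number(dt_s) || dt_s <= 0)
    stop("dt_s must be a positive number", call. = FALSE)
  eps <- 1e-9
  remaining <- dt_s
  while (remaining > eps) {
    active <- Filter(function(t) isTRUE(t$active), state$timers)
    step <- remaining
    if (length(active))
      step <- min(remaining, min(vapply(active, function(t) t$remaining_s,
                                        0)))
    step <- max(step, 0)
    state$elapsed_s <- state$elapsed_s + step
    state$total_counter_s <- state$elapsed_s
    remaining <- remaining - step
    fired <- character(0)
    for (nm in names(state$timers)) {
      t <- state$timers[[nm]]
      if (!isTRUE(t$active)) next
      t$remaining_s <- t$remaining_s - step
      if (t$remaining_s <= eps) fired <- c(fired, nm)
      state$timers[[nm]] <- t
    }
    if (length(fired)) {
      ranks <- vapply(fired, function(nm)
        state$timers[[nm]]$spec$priority_rank, 0)
      for (nm in fired[order(ranks)]) {
        t <- state$timers[[nm]]
        state <- log_append(state, "TIMER_FIRED", list(timer = nm))
        state <- log_append(state, "ALERT_RAISED",
                            list(alert = nm,
                                 priority_rank = t$spec$priority_rank))
        state$pending_alerts[[length(state$pending_alerts) + 1L]] <-
          list(name = nm, priority_rank = t$spec$priority_rank,
               t_raised = state$elapsed_s)
        if (nm == "rhythm_check")
          state$cycle_count <- state$cycle_count + 1L
        if (t$spec$repeating) t$remaining_s <- t$spec$period_s
        else { t$active <- FALSE; t$remaining_s <- 0 }
        state$timers[[nm]] <- t
      }
      ord <- order(vapply(state$pending_alerts,
                          function(a) a$priority_rank, 0))
      state$pending_alerts <- state$pending_alerts[ord]
    }
  }
  state
}

#' Open or close the CPR / ROSC overlay
#'
#' The overlay recaps (CPR quality, or post-resuscitation management) are
#' available from every screen; opening one never changes the underlying
#' node or stops any timer. Closing with no overlay open is a logged
#' no-op.
#'
#' @param state An `engine_state`.
#' @param which `"CPR"` or `"ROSC"`.
#' @return The new `engine_state`.
#' @export
open_overlay <- function(state, which = c("CPR", "ROSC")) {
  which <- match.arg(which)
  state$overlay <- which
  log_append(state, "OVERLAY_OPENED", list(overlay = which))
}

#' @rdname open_overlay
#' @export
close_overlay <- function(state) {
  if (is.null(state$overlay))
    return(log_append(state, "OVERLAY_CLOSED", list(ignored = TRUE)))
  which <- state$overlay
  state["overlay"] <- list(NULL)
  log_append(state, "OVERLAY_CLOSED", list(overlay = which))
}

#' Compute and log a weight-based drug dose from within a case
#'
#' Looks up the drug's dose specification in the engine config, computes
#' the recommended dose with [compute_dose()], and logs a `DOSE_COMPUTED`
#' entry. `actual_mass_mg`/`actual_dilution` record what the team
#' actually drew up (defaulting to the recommendation), so downstream
#' checklist scoring can compare prepared against recommended.
#'
#' @param state An `engine_state`.
#' @param drug Drug name present in the config (default `"epinephrine"`).
#' @param actual_mass_mg,actual_dilution Optionally the prepared dose.
#' @return The new `engine_state`.
#' @export
engine_compute_dose <- function(state, drug = "epinephrine",
                                actual_mass_mg = NULL,
                                actual_dilution = NULL) {
  spec <- dose_spec(state$config, drug)
  d <- compute_dose(state$profile, spec)
  log_append(state, "DOSE_COMPUTED", list(
    drug = drug,
    recommended_mg = d$mass_mg,
    mass_mg = actual_mass_mg %||% d$mass_mg,
    volume_ml = d$volume_ml,
    dilution = actual_dilution %||% (spec$dilution %||% "")))
}

#' End the case
#'
#' @param state An `engine_state`.
#' @param reason Free-text reason recorded in the `CASE_END` payload.
#' @return The new `engine_state` (flagged ended).
#' @export
end_case <- function(state, reason = "") {
  state$ended <- TRUE
  log_append(state, "CASE_END", list(reason = reason))
}

#' @export
print.engine_state <- function(x, ...) {
  cat("<engine_state> node '", x$node_id, "', t = ",
      format(x$elapsed_s), " s\n", sep = "")
  cat("  cycles: ", x$cycle_count, "  epi doses: ", x$epi_dose_count,
      "  shocks: ", x$shock_count,
      "  overlay: ", x$overlay %||% "none", "\n", sep = "")
  for (nm in names(x$timers)) {
    t <- x$timers[[nm]]
    cat("  timer ", format(nm, width = 14),
        if (isTRUE(t$active)) sprintf("%7.1f s remaining", t$remaining_s)
        else "   (inactive)", "\n", sep = "")
  }
  if (length(x$pending_alerts))
    cat("  pending alerts: ",
        paste(vapply(x$pending_alerts, function(a) a$name, ""),
              collapse = ", "), "\n", sep = "")
  cat("  log entries: ", length(x$log), "\n", sep = "")
  invisible(x)
}
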