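# Shared fixtures, all built in code.

write_graph_yaml <- function(text) {
  path <- tempfile(fileext = ".yaml")
  writeLines(text, path)
  path
}

# Minimal untagged linear graph: one 3-button screen then a terminal.
tiny_graph <- function() {
  load_flow_graph(write_graph_yaml("
start_node: a
nodes:
  - id: a
    advance_rule: ALL_SEQUENTIAL_TAPPED
    on_advance: b
    buttons:
      - {id: b1, label_key: k1, layout: SEQUENTIAL, kind: ACTION}
      - {id: b2, label_key: k2, layout: SEQUENTIAL, kind: ACTION}
      - {id: b3, label_key: k3, layout: SEQUENTIAL, kind: ACTION}
  - id: b
    advance_rule: ALL_SEQUENTIAL_TAPPED
    on_advance: ~
    buttons:
      - {id: done, label_key: k4, layout: SEQUENTIAL, kind: ACTION}
"))
}

# Engine config with the medication countdown armed from case start, so
# timer-priority interactions can be driven without scripting taps.
config_med_at_start <- function() {
  cfg <- load_engine_config()
  cfg$timers$medication$start <- "case_start"
  validate_engine_config(unclass(cfg))
}

# A team log with every required action absent (recognition unknown).
empty_team_log <- function() {
  st <- start_case(load_flow_graph(), patient_profile(10))
  st <- end_case(st, "none")
  structure(list(team_id = "empty", arm = "control", log = st$log,
                 ca_recognition_t_s = NA_real_, weight_kg = 10),
            class = "team_log")
}

# Hand-built team log: recognition marker at rec_t, optional epinephrine
# administration tap at adm_t.
stub_team_log <- function(rec_t = 30, adm_t = 195, include_adm = TRUE) {
  log <- list(
    list(t_s = 0, event = "CASE_START", payload = list(weight_kg = 10)),
    list(t_s = rec_t, event = "TAP",
         payload = list(button = "recognize_arrest", node = "start")))
  if (include_adm)
    log[[length(log) + 1]] <- list(
      t_s = adm_t, event = "TAP",
      payload = list(button = "administer_epinephrine",
                     node = "epi_administration"))
  structure(list(team_id = "stub", arm = "control", log = log,
                 ca_recognition_t_s = rec_t, weight_kg = 10),
            class = "team_log")
}

ideal_team_log <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_scenario(scenario_spec(), ideal_policy(),
                             team_id = "ideal")
    cache
  }
})

# Single-fault injection map: for every checklist item, a policy whose
# only induced failure is that item.
fault_injectors <- function() {
  base <- function(...) {
    pol <- ideal_policy()
    mods <- list(...)
    for (nm in names(mods)) pol[[nm]] <- mods[[nm]]
    pol
  }
  list(
    timely_recognition = base(recognition_latency_median_s = 70),
    help_called = base(omission_prob = c(call_for_help = 1)),
    early_cpr = base(extra_delay_s = c(start_cpr = 35)),
    correct_compression_ratio = base(faults = "incorrect_ratio"),
    monitor_attached = base(omission_prob = c(attach_monitor = 1)),
    airway_opened = base(omission_prob = c(open_airway = 1)),
    vascular_access = base(omission_prob = c(obtain_vascular_access = 1)),
    epinephrine_prepared = base(omission_prob = c(prepare_epinephrine = 1)),
    correct_epinephrine_dose = base(faults = "dose_error"),
    correct_dilution = base(faults = "dilution_error"),
    timely_epinephrine = base(epi_latency_median_s = 400),
    line_flushed = base(omission_prob = c(flush_line = 1)),
    reversible_causes_search = base(omission_prob = c(assess_hypovolemia = 1)),
    hypovolemia_treated = base(omission_prob = c(give_fluid_bolus = 1)),
    effective_ventilation = base(omission_prob = c(ventilate_effectively = 1)),
    rhythm_reassessed = base(faults = "skip_rhythm_reassessment")
  )
}

# Printed usability table: per-scale mean, SD and 95% CI used as a
# regression fixture for the interval arithmetic.
usability_table <- function() {
  data.frame(
    scale = c("attractiveness", "perspicuity", "efficiency",
              "dependability", "stimulation", "novelty"),
    mean = c(1.712, 1.750, 1.932, 1.568, 1.598, 2.205),
    sd = c(1.434, 0.880, 0.929, 1.102, 1.333, 0.740),
    ci_low = c(0.865, 1.230, 1.383, 0.917, 0.811, 1.767),
    ci_high = c(2.559, 2.270, 2.481, 2.219, 2.386, 2.642))
}

# Independent Mann-Whitney oracle: enumerate every assignment of the
# pooled values to the first group and count splits at least as extreme
# (distance of U from its null mean), computing U by direct pair
# comparison rather than ranks.
mw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_of <- function(a, b) sum(outer(a, b, ">") + 0.5 * outer(a, b, "=="))
  U_obs <- u_of(x, y)
  center <- n * m / 2
  splits <- utils::combn(n + m, n)
  stat <- apply(splits, 2, function(ix)
    u_of(pooled[ix], pooled[-ix]))
  mean(abs(stat - center) >= abs(U_obs - center) - 1e-9)
}
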