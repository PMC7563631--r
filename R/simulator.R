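#' Scenario specification
#'
#' Defines the simulated case: the initial (nonshockable) rhythm, the
#' patient weight, rules for rhythm transitions as the case evolves, and
#' a hard duration cap. The default reconstructs the study scenario: a
#' 10 kg infant in asystole whose rhythm becomes organized with a pulse
#' after two epinephrine doses and at least six minutes.
#'
#' @param initial_rhythm `"ASYSTOLE"` or `"PEA"`.
#' @param weight_kg Patient weight in kilograms.
#' @param transition_rules List of rules, each
#'   `list(when = list(min_epi_doses =, min_elapsed_s =), rhythm =)`;
#'   the last satisfied rule wins.
#' @param max_duration_s Case duration cap in seconds.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(initial_rhythm = "ASYSTOLE", weight_kg = 10,
                          transition_rules = list(
                            list(when = list(min_epi_doses = 2,
                                             min_elapsed_s = 360),
                                 rhythm = "ORGANIZED_WITH_PULSE")),
                          max_duration_s = 600) {
  if (!initial_rhythm %in% c("ASYSTOLE", "PEA"))
    stop("initial_rhythm must be nonshockable (ASYSTOLE or PEA)",
         call. = FALSE)
  stopifnot(is_scalar_number(max_duration_s), max_duration_s > 0)
  for (r in transition_rules) {
    if (!is_scalar_string(r$rhythm) || !r$rhythm %in% rhythm_values())
      stop("transition rule with unknown rhythm", call. = FALSE)
    bad <- setdiff(names(r$when),
                   c("min_epi_doses", "min_elapsed_s", "min_cycles"))
    if (length(bad))
      stop("transition rule references unknown counter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(initial_rhythm = initial_rhythm, weight_kg = weight_kg,
                 transition_rules = transition_rules,
                 max_duration_s = max_duration_s),
            class = "scenario_spec")
}

#' Read a scenario specification from YAML
#' @param path YAML file; defaults to the bundled study scenario.
#' @return A [scenario_spec()].
#' @export
load_scenario <- function(path = resusim_extdata("scenario_default.yaml")) {
  raw <- yaml::read_yaml(path)
  scenario_spec(initial_rhythm = raw$initial_rhythm %||% "ASYSTOLE",
                weight_kg = raw$weight_kg %||% 10,
                transition_rules = raw$transition_rules %||% list(),
                max_duration_s = raw$max_duration_s %||% 600)
}

scenario_rhythm <- function(spec, elapsed_s, epi_doses, cycles) {
  rhythm <- spec$initial_rhythm
  for (r in spec$transition_rules) {
    w <- r$when
    ok <- (is.null(w$min_epi_doses) || epi_doses >= w$min_epi_doses) &&
      (is.null(w$min_elapsed_s) || elapsed_s >= w$min_elapsed_s) &&
      (is.null(w$min_cycles) || cycles >= w$min_cycles)
    if (ok) rhythm <- r$rhythm
  }
  rhythm
}

#' Scripted-team agent policy
#'
#' Behavioural parameters for one simulated team. Action latencies are
#' lognormal (parameterized by median and log-scale sigma) for their
#' positivity and right skew; the epinephrine latency is the interval
#' from recognition of arrest to the first administration. Faults are
#' either injected deterministically (`faults`) or drawn per team from
#' `fault_probs`; per-button omission probabilities model skipped
#' actions. The `arm` label never changes engine rules — control teams
#' run against the same flow graph with completion enforcement relaxed.
#'
#' @param arm `"control"` or `"intervention"`.
#' @param seed Integer RNG seed for this team.
#' @param tap_latency_median_s,tap_latency_sigma Per-tap latency model.
#' @param recognition_latency_median_s,recognition_latency_sigma Time to
#'   recognize the arrest.
#' @param epi_latency_median_s,epi_latency_sigma Recognition-to-first-
#'   epinephrine interval.
#' @param omission_prob Named numeric vector of per-button omission
#'   probabilities (all in `[0, 1]`).
#' @param extra_delay_s Named numeric vector of fixed additional seconds
#'   added to the latency of specific buttons (timing-fault injection).
#' @param fault_probs Named probabilities for the named faults
#'   (`incorrect_ratio`, `dose_error`, `dilution_error`,
#'   `omit_reversible_causes`, `omit_epinephrine`, `omit_epi_repeat`,
#'   `skip_rhythm_reassessment`, `skip_dose_check`).
#' @param faults Character vector of faults injected with certainty.
#' @return An object of class `agent_policy`.
#' @export
agent_policy <- function(arm = c("intervention", "control"), seed = 1L,
                         tap_latency_median_s = 6, tap_latency_sigma = 0.4,
                         recognition_latency_median_s = 25,
                         recognition_latency_sigma = 0.3,
                         epi_latency_median_s = 254,
                         epi_latency_sigma = 0.3,
                         omission_prob = numeric(0),
                         extra_delay_s = numeric(0),
                         fault_probs = numeric(0),
                         faults = character(0)) {
  arm <- match.arg(arm)
  stopifnot(tap_latency_median_s > 0, recognition_latency_median_s > 0,
            epi_latency_median_s > 0)
  if (length(omission_prob) &&
      (any(omission_prob < 0) || any(omission_prob > 1)))
    stop("omission probabilities must lie in [0, 1]", call. = FALSE)
  if (length(fault_probs) && (any(fault_probs < 0) || any(fault_probs > 1)))
    stop("fault probabilities must lie in [0, 1]", call. = FALSE)
  known <- c("incorrect_ratio", "dose_error", "dilution_error",
             "omit_reversible_causes", "omit_epinephrine",
             "omit_epi_repeat", "skip_rhythm_reassessment",
             "skip_dose_check")
  bad <- setdiff(c(names(fault_probs), faults), known)
  if (length(bad))
    stop("unknown fault(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(arm = arm, seed = as.integer(seed),
                 tap_latency_median_s = tap_latency_median_s,
                 tap_latency_sigma = tap_latency_sigma,
                 recognition_latency_median_s = recognition_latency_median_s,
                 recognition_latency_sigma = recognition_latency_sigma,
                 epi_latency_median_s = epi_latency_median_s,
                 epi_latency_sigma = epi_latency_sigma,
                 omission_prob = omission_prob,
                 extra_delay_s = extra_delay_s,
                 fault_probs = fault_probs,
                 faults = faults),
            class = "agent_policy")
}

#' Default per-arm policies reproducing the study conditions
#'
#' Control teams: epinephrine latency median 165 s; fault probabilities
#' 0.2 (incorrect compression ratio), 0.2 (dose error) and 0.4
#' (reversible-causes omission). Intervention teams: epinephrine latency
#' median 254 s; reversible-causes omission probability 0.18 and no
#' ratio/dose faults. These are the observed arm-level rates, fixed once
#' as the simulator's study conditions.
#'
#' @param arm `"control"` or `"intervention"`.
#' @param seed Team seed.
#' @return An [agent_policy()].
#' @export
default_policy <- function(arm = c("intervention", "control"), seed = 1L) {
  arm <- match.arg(arm)
  if (arm == "control")
    agent_policy(arm = "control", seed = seed,
                 epi_latency_median_s = 165, epi_latency_sigma = 0.25,
                 fault_probs = c(incorrect_ratio = 0.2, dose_error = 0.2,
                                 omit_reversible_causes = 0.4))
  else
    agent_policy(arm = "intervention", seed = seed,
                 epi_latency_median_s = 254, epi_latency_sigma = 0.3,
                 fault_probs = c(omit_reversible_causes = 0.18))
}

#' Idealized zero-variance policy
#'
#' Deterministic fast team: short fixed latencies, epinephrine at the
#' earliest legal moment, no omissions or faults. Useful as the
#' perfect-performance reference (scores zero deviations and the full
#' clinical-performance total).
#'
#' @param arm Arm label.
#' @param seed Team seed (unused randomness; kept for symmetry).
#' @return An [agent_policy()].
#' @export
ideal_policy <- function(arm = "intervention", seed = 1L) {
  agent_policy(arm = arm, seed = seed,
               tap_latency_median_s = 4, tap_latency_sigma = 0,
               recognition_latency_median_s = 10,
               recognition_latency_sigma = 0,
               epi_latency_median_s = 1e-6, epi_latency_sigma = 0)
}

draw_latency <- function(median_s, sigma) {
  x <- if (sigma <= 0) median_s else rlnorm(1, log(median_s), sigma)
  max(canon_num(x), 1e-6)
}

#' Run one scripted resuscitation scenario
#'
#' Drives the guidance engine with a scripted agent: the agent walks the
#' current screen's buttons with lognormal latencies, selects the rhythm
#' dictated by the scenario's transition rules at each rhythm check
#' (waiting for the 2-minute reminder on re-checks), administers the
#' first epinephrine dose at recognition time plus the policy's
#' epinephrine latency, repeats doses when the medication alert fires,
#' and performs post-resuscitation actions once an organized rhythm with
#' a pulse appears. Omitted actions leave no trace in the log and the
#' agent force-advances past the incomplete screen. Fully deterministic
#' given the policy seed.
#'
#' @param spec A [scenario_spec()].
#' @param policy An [agent_policy()].
#' @param graph,config Engine flow graph and configuration.
#' @param team_id Identifier stored in the resulting log.
#' @return An object of class `team_log`: fields `team_id`, `arm`,
#'   `log` (engine event list), `ca_recognition_t_s`, `weight_kg`.
#' @export
run_scenario <- function(spec = scenario_spec(), policy = default_policy(),
                         graph = load_flow_graph(),
                         config = load_engine_config(),
                         team_id = "team_1") {
  stopifnot(inherits(spec, "scenario_spec"), inherits(policy, "agent_policy"))
  with_seed(policy$seed, {
    faults <- policy$faults
    for (f in names(policy$fault_probs))
      if (runif(1) < policy$fault_probs[[f]]) faults <- c(faults, f)
    faults <- unique(faults)
    omit <- names(policy$omission_prob)[
      runif(length(policy$omission_prob)) < policy$omission_prob]
    if ("omit_reversible_causes" %in% faults)
      omit <- union(omit, c("assess_hypovolemia", "give_fluid_bolus",
                            "assess_hypoxia", "assess_metabolic",
                            "assess_obstructive"))
    epi_latency <- draw_latency(policy$epi_latency_median_s,
                                policy$epi_latency_sigma)
    st <- start_case(graph, patient_profile(spec$weight_kg), config)
    ca_recognition_t <- NA_real_
    epi_btn <- config$buttons$epinephrine_administration
    rec_btn <- config$buttons$recognition
    rhythm_selected <- 0L

    wait_until <- function(st, target_t) {
      if (target_t > st$elapsed_s) tick(st, target_t - st$elapsed_s)
      else st
    }

    visit_sequential <- function(st) {
      nd <- current_node(st)
      # the dose check happens on entering the preparation screen, so tap
      # omissions and the dose-check fault stay independent
      if (any(vapply(nd$buttons, function(b)
        b$id == "prepare_epinephrine", TRUE)) &&
        !"skip_dose_check" %in% faults) {
        actual <- NULL
        if ("dose_error" %in% faults) {
          rec <- compute_dose(st$profile,
                              dose_spec(config, "epinephrine"))$mass_mg
          actual <- canon_num(rec * 10)
        }
        st <- engine_compute_dose(st, "epinephrine", actual_mass_mg = actual)
      }
      incomplete <- FALSE
      for (b in nd$buttons) {
        if (st$ended || st$elapsed_s >= spec$max_duration_s) break
        id <- b$id
        if (id %in% omit ||
            (id == epi_btn && "omit_epinephrine" %in% faults) ||
            (id == epi_btn && st$epi_dose_count >= 1L &&
             "omit_epi_repeat" %in% faults)) {
          incomplete <- TRUE
          next
        }
        lat <- if (id == rec_btn)
          draw_latency(policy$recognition_latency_median_s,
                       policy$recognition_latency_sigma)
        else draw_latency(policy$tap_latency_median_s,
                          policy$tap_latency_sigma)
        if (id %in% names(policy$extra_delay_s))
          lat <- lat + policy$extra_delay_s[[id]]
        st <- tick(st, lat)
        if (id == epi_btn) {
          if (st$epi_dose_count == 0L) {
            sched <- (if (is.na(ca_recognition_t)) 0 else ca_recognition_t) +
              epi_latency
            st <- wait_until(st, min(sched, spec$max_duration_s))
          } else {
            # repeat doses follow the medication alert
            med <- st$timers$medication
            if (!length(Filter(function(a) a$name == "medication",
                               st$pending_alerts)) && isTRUE(med$active))
              st <- tick(st, min(med$remaining_s + 1e-6,
                                 max(spec$max_duration_s - st$elapsed_s,
                                     1e-6)))
          }
        }
        if (st$elapsed_s >= spec$max_duration_s) { incomplete <- TRUE; break }
        payload <- list()
        if (id == "resume_cpr")
          payload <- list(ratio = if ("incorrect_ratio" %in% faults)
            "30:2" else "15:2")
        if (id == "verify_dilution")
          payload <- list(dilution = if ("dilution_error" %in% faults)
            "1:1000" else "1:10000")
        st <- tap(st, id, payload)
        if (id == rec_btn && is.na(ca_recognition_t))
          ca_recognition_t <<- st$elapsed_s
      }
      # node advanced automatically iff every sequential button was tapped
      if (current_node(st)$id == nd$id && !st$ended)
        st <- advance_node(st, force = TRUE)
      st
    }

    while (!st$ended && st$elapsed_s < spec$max_duration_s) {
      nd <- current_node(st)
      if (isTRUE(nd$rhythm_choice)) {
        pending <- length(Filter(function(a) a$name == "rhythm_check",
                                 st$pending_alerts)) > 0
        if (rhythm_selected > 0L && !pending) {
          # wait for the 2-minute reminder before re-checking
          rem <- st$timers$rhythm_check$remaining_s
          if (st$elapsed_s + rem >= spec$max_duration_s) {
            st <- wait_until(st, spec$max_duration_s)
            break
          }
          st <- tick(st, rem + 1e-6)
        }
        st <- tick(st, draw_latency(policy$tap_latency_median_s,
                                    policy$tap_latency_sigma))
        if (st$elapsed_s >= spec$max_duration_s) break
        if (rhythm_selected > 0L &&
            "skip_rhythm_reassessment" %in% faults) {
          st <- acknowledge_alert(st, "rhythm_check")
          st <- advance_node(st, force = TRUE)
        } else {
          rhythm <- scenario_rhythm(spec, st$elapsed_s, st$epi_dose_count,
                                    st$cycle_count)
          st <- select_rhythm(st, rhythm)
          rhythm_selected <- rhythm_selected + 1L
        }
      } else if (nd$id == "rosc_care") {
        st <- visit_sequential(st)
        st <- end_case(st, "rosc")
      } else {
        st <- visit_sequential(st)
      }
    }
    if (!st$ended) st <- end_case(st, "timeout")
    structure(list(team_id = team_id, arm = policy$arm, log = st$log,
                   ca_recognition_t_s = ca_recognition_t,
                   weight_kg = spec$weight_kg),
              class = "team_log")
  })
}

#' @export
print.team_log <- function(x, ...) {
  cat("<team_log> ", x$team_id, " (", x$arm, "), ", length(x$log),
      " events, recognition at ",
      if (is.na(x$ca_recognition_t_s)) "NA" else
        format(x$ca_recognition_t_s), " s\n", sep = "")
  invisible(x)
}

#' Generate a two-arm cohort of simulated team logs
#'
#' Per-team seeds are derived from the master seed with [derive_seed()]
#' (a documented Lehmer-style integer hash), so the same master seed
#' always reproduces the same cohort, and any team can be regenerated in
#' isolation.
#'
#' @param n_control,n_intervention Number of teams per arm.
#' @param spec A [scenario_spec()] shared by all teams.
#' @param policies List with elements `control` and `intervention`, each
#'   a template [agent_policy()] whose seed is replaced per team.
#' @param seed Master seed.
#' @param faults Optional per-arm deterministic fault injection: list
#'   with `control` / `intervention`, each a named list mapping team
#'   index (as character) to a character vector of faults.
#' @param graph,config Engine inputs.
#' @return List of [run_scenario()] `team_log` objects, control teams
#'   first.
#' @export
generate_cohort <- function(n_control = 5, n_intervention = 11,
                            spec = scenario_spec(),
                            policies = list(
                              control = default_policy("control"),
                              intervention = default_policy("intervention")),
                            seed = 1L, faults = list(),
                            graph = load_flow_graph(),
                            config = load_engine_config()) {
  stopifnot(n_control >= 0, n_intervention >= 0)
  logs <- list()
  idx <- 0L
  for (arm in c("control", "intervention")) {
    n <- if (arm == "control") n_control else n_intervention
    template <- policies[[arm]]
    for (i in seq_len(n)) {
      idx <- idx + 1L
      pol <- template
      pol$seed <- derive_seed(seed, idx)
      extra <- (faults[[arm]] %||% list())[[as.character(i)]]
      if (!is.null(extra)) pol$faults <- unique(c(pol$faults, extra))
      logs[[idx]] <- run_scenario(spec, pol, graph = graph, config = config,
                                  team_id = sprintf("%s_%02d", arm, i))
    }
  }
  logs
}

#' Write / read a cohort as JSONL logs plus a CSV manifest
#'
#' @param cohort List of `team_log` objects.
#' @param dir Output directory (created if missing).
#' @return `write_cohort`: the manifest path, invisibly. `read_cohort`:
#'   a list of `team_log` objects.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    team_id = vapply(cohort, function(x) x$team_id, ""),
    arm = vapply(cohort, function(x) x$arm, ""),
    ca_recognition_t_s = vapply(cohort, function(x)
      x$ca_recognition_t_s, 0),
    weight_kg = vapply(cohort, function(x) x$weight_kg, 0),
    file = vapply(cohort, function(x) paste0(x$team_id, ".jsonl"), ""))
  for (tl in cohort) export_log(tl, file.path(dir, paste0(tl$team_id,
                                                          ".jsonl")))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    structure(list(team_id = manifest$team_id[i], arm = manifest$arm[i],
                   log = read_log(file.path(dir, manifest$file[i])),
                   ca_recognition_t_s = manifest$ca_recognition_t_s[i],
                   weight_kg = manifest$weight_kg[i]),
              class = "team_log")
  })
}

#' Generate synthetic questionnaire responses
#'
#' Draws item (UEQ) or subscale (RTLX) responses from a truncated normal
#' discretized onto the instrument grid: UEQ items are integers in
#' \[-3, 3\], RTLX subscales multiples of 5 in \[0, 100\]. Deterministic
#' per seed.
#'
#' @param n Number of respondents.
#' @param instrument `"UEQ"` or `"RTLX"`.
#' @param profile Per-scale (UEQ) or per-subscale (RTLX) targets: a named
#'   list of `list(mean =, sd =)`. Means must lie within the instrument
#'   range. Missing scales default to `mean = 1.5, sd = 1` (UEQ) or
#'   `mean = 60, sd = 15` (RTLX).
#' @param seed RNG seed.
#' @param scale_map UEQ scale map (see [load_ueq_scales()]).
#' @return Data frame: `respondent_id` plus `item_1..item_26` (UEQ) or
#'   the six subscale columns (RTLX).
#' @export
generate_questionnaires <- function(n, instrument = c("UEQ", "RTLX"),
                                    profile = list(), seed = 1L,
                                    scale_map = load_ueq_scales()) {
  instrument <- match.arg(instrument)
  stopifnot(is_scalar_number(n), n >= 0)
  with_seed(seed, {
    if (instrument == "UEQ") {
      items <- matrix(NA_real_, nrow = n, ncol = 26)
      for (sc in names(scale_map$scales)) {
        p <- profile[[sc]] %||% list(mean = 1.5, sd = 1)
        if (p$mean < -3 || p$mean > 3)
          stop("UEQ scale mean out of range for '", sc, "'", call. = FALSE)
        # respondent-level latent score plus item noise, so items within a
        # scale are positively correlated (nonzero internal consistency);
        # sd = 0 collapses every item to the mean
        item_sd <- p$item_sd %||% (p$sd / 2)
        latent <- draw_truncated(n, p$mean, p$sd, -3, 3)
        for (ix in scale_map$scales[[sc]]) {
          v <- latent + rnorm(n, 0, item_sd)
          v <- pmin(3, pmax(-3, round(v)))
          # polarity maps the latent "goodness" value to the raw answer
          items[, ix] <- v * scale_map$polarity[ix]
        }
      }
      out <- data.frame(respondent_id = sprintf("r%02d", seq_len(n)))
      for (ix in 1:26) out[[paste0("item_", ix)]] <- items[, ix]
      out
    } else {
      subs <- c("mental", "physical", "temporal", "performance", "effort",
                "frustration")
      out <- data.frame(respondent_id = sprintf("r%02d", seq_len(n)))
      for (s in subs) {
        p <- profile[[s]] %||% list(mean = 60, sd = 15)
        if (p$mean < 0 || p$mean > 100)
          stop("RTLX subscale mean out of range for '", s, "'",
               call. = FALSE)
        v <- draw_truncated(n, p$mean, p$sd, 0, 100)
        out[[s]] <- pmin(100, pmax(0, 5 * round(v / 5)))
      }
      out
    }
  })
}

# Truncated-normal draws by rejection; degenerate sd gives the mean.
draw_truncated <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}
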