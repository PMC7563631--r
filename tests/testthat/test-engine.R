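graph <- load_flow_graph()
config <- load_engine_config()

test_that("case start arms the rhythm-check countdown and logs once", {
  st <- start_case(graph, patient_profile(10), config)
  expect_identical(st$node_id, graph$start_node)
  expect_equal(st$elapsed_s, 0)
  expect_equal(st$timers$rhythm_check$remaining_s, 120)
  expect_length(st$log, 1)
  expect_identical(st$log[[1]]$event, "CASE_START")
  expect_error(patient_profile(0), "positive")
  expect_error(patient_profile(-5), "positive")
  expect_error(patient_profile(250), "maximum")
})

test_that("sequential screens advance only when all actions are tapped", {
  st <- start_case(tiny_graph(), patient_profile(10), config)
  st <- tap(st, "b1")
  st <- tap(st, "b2")
  expect_identical(st$node_id, "a")
  st3 <- tap(st, "b3")
  expect_identical(st3$node_id, "b")
  # tapping a button from another screen is rejected, log untouched
  expect_error(tap(st, "done"), "not visible")
  expect_length(tap(st3, "done")$log, 5)
})

test_that("rhythm selection branches into the tagged pathway", {
  st0 <- start_case(graph, patient_profile(10), config)
  for (b in c("recognize_arrest", "call_for_help", "start_cpr",
              "attach_monitor"))
    st0 <- tap(st0, b)
  expect_identical(st0$node_id, "rhythm_check")

  st <- select_rhythm(st0, "ASYSTOLE")
  expect_identical(graph$pathway_tags[[st$node_id]], "nonshockable")

  st <- select_rhythm(st0, "VF")
  expect_identical(graph$pathway_tags[[st$node_id]], "shockable")
  events <- vapply(st$log, function(e) e$event, "")
  expect_true("SHOCK_ADVISED" %in% events)
  adv <- st$log[[which(events == "SHOCK_ADVISED")]]
  expect_equal(adv$payload$energy_j, 20) # 2 J/kg x 10 kg, first shock

  st <- select_rhythm(st0, "ORGANIZED_WITH_PULSE")
  expect_identical(st$node_id, "rosc_care")
  expect_true("ROSC_DECLARED" %in% vapply(st$log, function(e) e$event, ""))

  # outside a rhythm-choice screen selection is rejected
  expect_error(select_rhythm(start_case(graph, patient_profile(10), config),
                             "ASYSTOLE"), "rhythm-choice")
})

test_that("the 2-minute reminder fires, re-arms and counts cycles", {
  st <- start_case(graph, patient_profile(10), config)
  st1 <- tick(st, 1)
  expect_equal(st1$timers$rhythm_check$remaining_s, 119)
  expect_length(st1$pending_alerts, 0)

  st120 <- tick(st, 120)
  expect_equal(st120$cycle_count, 1L)
  expect_equal(st120$timers$rhythm_check$remaining_s, 120)
  expect_identical(st120$pending_alerts[[1]]$name, "rhythm_check")

  # one large step fires the repeating timer floor(dt/120) times
  st500 <- tick(st, 500)
  expect_equal(st500$cycle_count, 4L)
  expect_error(tick(st, 0), "positive")
  expect_error(tick(st, -3), "positive")
})

test_that("medication alerts outrank rhythm-check alerts", {
  cfg <- config_med_at_start()
  st <- start_case(graph, patient_profile(10), cfg)
  # 360 s is a common multiple of both periods: both fire at that instant
  st <- tick(st, 360)
  nm <- vapply(st$pending_alerts, function(a) a$name, "")
  expect_identical(nm[1], "medication")
  # logged firing order at the shared instant also puts medication first
  ev <- Filter(function(e) e$event == "TIMER_FIRED" && e$t_s == 360, st$log)
  expect_identical(ev[[1]]$payload$timer, "medication")

  # property: under random tick partitions the medication alert is always
  # ahead of the rhythm-check alert whenever both are pending
  set.seed(42)
  for (rep in 1:10) {
    st <- start_case(graph, patient_profile(10), cfg)
    remaining <- 720
    while (remaining > 0) {
      dt <- min(remaining, round(runif(1, 1, 90), 3))
      st <- tick(st, dt)
      remaining <- remaining - dt
      nm <- vapply(st$pending_alerts, function(a) a$name, "")
      if (all(c("medication", "rhythm_check") %in% nm))
        expect_lt(match("medication", nm), match("rhythm_check", nm))
    }
  }
})

test_that("rhythm-check firings depend only on total elapsed time", {
  set.seed(7)
  for (total in c(240, 600)) {
    for (rep in 1:5) {
      st <- start_case(graph, patient_profile(10), config)
      left <- total
      while (left > 1e-9) {
        dt <- min(left, round(runif(1, 0.5, 77), 3))
        st <- tick(st, dt)
        left <- left - dt
      }
      expect_equal(st$cycle_count, as.integer(floor(total / 120)),
                   info = paste("total =", total))
    }
  }
})

test_that("overlays never change the node or stop timers", {
  st <- start_case(graph, patient_profile(10), config)
  stc <- open_overlay(st, "CPR")
  expect_identical(stc$overlay, "CPR")
  expect_identical(stc$node_id, st$node_id)
  # timer still fires with the overlay open
  stc <- tick(stc, 120)
  expect_equal(stc$cycle_count, 1L)

  # open/close round trip returns the same state except the log
  stoc <- close_overlay(open_overlay(st, "ROSC"))
  keep <- setdiff(names(st), "log")
  expect_equal(stoc[keep], st[keep])

  # closing with nothing open is a recorded no-op
  stn <- close_overlay(st)
  expect_true(isTRUE(stn$log[[length(stn$log)]]$payload$ignored))
})

test_that("epinephrine tap counts doses, arms the countdown and clears its alert", {
  st <- start_case(graph, patient_profile(10), config)
  expect_false(st$timers$medication$active)
  for (b in c("recognize_arrest", "call_for_help", "start_cpr",
              "attach_monitor"))
    st <- tap(st, b)
  st <- select_rhythm(st, "ASYSTOLE")
  st <- tap(st, "resume_cpr")
  st <- tap(st, "obtain_vascular_access")
  st <- tap(st, "prepare_epinephrine")
  st <- tap(st, "verify_dilution")
  st <- tap(st, "administer_epinephrine")
  expect_equal(st$epi_dose_count, 1L)
  expect_true(st$timers$medication$active)
  expect_equal(st$timers$medication$remaining_s, 180)
})

test_that("identical scripts give identical states and logs", {
  script <- function() {
    st <- start_case(graph, patient_profile(12.5), config)
    st <- tap(st, "recognize_arrest")
    st <- tick(st, 13.7)
    st <- tap(st, "call_for_help")
    st <- open_overlay(st, "CPR")
    st <- tick(st, 250)
    st <- close_overlay(st)
    tap(st, "start_cpr")
  }
  expect_identical(script(), script())
})
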