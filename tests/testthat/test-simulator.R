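test_that("the same scenario, policy and seed reproduce the log exactly", {
  a <- run_scenario(scenario_spec(), default_policy("intervention", 9))
  b <- run_scenario(scenario_spec(), default_policy("intervention", 9))
  expect_identical(a, b)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  export_log(a, fa); export_log(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("an ideal team administers epinephrine at the earliest legal time", {
  tl <- ideal_team_log()
  ev <- vapply(tl$log, function(e) e$event, "")
  # the administration tap follows the preparation screen with only the
  # fixed tap latencies in between: no waiting on the drug
  taps <- Filter(function(e) e$event == "TAP", tl$log)
  btn <- vapply(taps, function(e) e$payload$button, "")
  t_adm <- taps[[match("administer_epinephrine", btn)]]$t_s
  t_prep <- taps[[match("verify_dilution", btn)]]$t_s
  expect_equal(t_adm - t_prep, 4) # one 4 s tap latency, nothing else
  expect_lt(time_to_epinephrine(tl), 60)
  expect_true("ROSC_DECLARED" %in% ev)
  expect_identical(tl$log[[length(tl$log)]]$event, "CASE_END")
})

test_that("certain omission leaves no trace of the omitted actions", {
  pol <- ideal_policy()
  pol$faults <- "omit_reversible_causes"
  tl <- run_scenario(scenario_spec(), pol)
  btns <- vapply(Filter(function(e) e$event == "TAP", tl$log),
                 function(e) e$payload$button, "")
  expect_false(any(c("assess_hypovolemia", "give_fluid_bolus",
                     "assess_hypoxia") %in% btns))
  # downstream screens were still reached
  expect_true("open_airway" %in% btns)
})

test_that("cohorts are sized, labeled and reproducible from the master seed", {
  co <- generate_cohort(2, 3, seed = 4)
  expect_length(co, 5)
  expect_identical(vapply(co, function(x) x$arm, ""),
                   c("control", "control", "intervention", "intervention",
                     "intervention"))
  co2 <- generate_cohort(2, 3, seed = 4)
  expect_identical(co, co2)
  expect_length(generate_cohort(0, 0, seed = 1), 0)
})

test_that("cohort directories round-trip through the manifest", {
  co <- generate_cohort(1, 2, seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_length(back, 3)
  expect_identical(lapply(back, function(x) x$log),
                   lapply(co, function(x) x$log))
  expect_identical(vapply(back, function(x) x$team_id, ""),
                   vapply(co, function(x) x$team_id, ""))
})

test_that("simulated logs always validate and score without errors", {
  for (seed in 1:6) {
    co <- generate_cohort(1, 1, seed = seed)
    for (tl in co) {
      f <- tempfile()
      export_log(tl, f)
      expect_identical(read_log(f), tl$log)
      unlink(f)
      expect_no_error(score_cdevplus(tl))
      expect_no_error(score_cpt(tl))
      expect_no_error(time_to_epinephrine(tl))
    }
  }
})

test_that("questionnaire generation honors the instrument grids", {
  # zero variance pins every item at the target mean
  q <- generate_questionnaires(11, "UEQ",
                               profile = sapply(names(load_ueq_scales()$scales),
                                                function(s)
                                                  list(mean = 2, sd = 0),
                                                simplify = FALSE),
                               seed = 1)
  items <- as.matrix(q[, paste0("item_", 1:26)])
  expect_true(all(items == 2))

  q2 <- generate_questionnaires(40, "UEQ", seed = 2)
  expect_true(all(as.matrix(q2[, -1]) %in% -3:3))

  r <- generate_questionnaires(40, "RTLX", seed = 3)
  vals <- unlist(r[, -1])
  expect_true(all(vals %in% seq(0, 100, by = 5)))

  expect_error(generate_questionnaires(
    5, "UEQ", profile = list(novelty = list(mean = 4, sd = 1))),
    "out of range")
  expect_error(generate_questionnaires(
    5, "RTLX", profile = list(effort = list(mean = 120, sd = 5))),
    "out of range")
})

test_that("generated scale means concentrate on the target for large n", {
  n <- 400
  q <- generate_questionnaires(
    n, "UEQ", profile = list(efficiency = list(mean = 1.5, sd = 1)),
    seed = 6)
  sm <- score_ueq(q)
  eff <- sm[sm$scale == "efficiency", ]
  se <- eff$sd / sqrt(n)
  # allow three standard errors plus the small discretization bias
  expect_lt(abs(eff$mean - 1.5), 3 * se + 0.06)

  r <- generate_questionnaires(
    n, "RTLX", profile = list(mental = list(mean = 65, sd = 12)), seed = 7)
  expect_lt(abs(mean(r$mental) - 65), 3 * 12 / sqrt(n) + 1)
})
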