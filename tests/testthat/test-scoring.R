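test_that("a flawless team scores zero deviations and the full task total", {
  tl <- ideal_team_log()
  cd <- score_cdevplus(tl)
  expect_equal(cd$total, 0)
  expect_true(all(cd$per_item == 0))
  cp <- score_cpt(tl)
  expect_equal(cp$total, 13)
})

test_that("a log with every required action absent scores the maximum", {
  tl <- empty_team_log()
  cd <- score_cdevplus(tl)
  expect_equal(cd$total, 16)
  expect_true(all(cd$per_item == 1))
  expect_equal(score_cpt(tl)$total, 0)
})

test_that("each checklist item is failed by exactly one injected fault", {
  checklist <- load_checklist()
  injectors <- fault_injectors()
  expect_setequal(names(injectors),
                  vapply(checklist$items, function(i) i$id, ""))
  for (item in names(injectors)) {
    tl <- run_scenario(scenario_spec(), injectors[[item]],
                       team_id = paste0("fault_", item))
    cd <- score_cdevplus(tl, checklist)
    expect_equal(unname(cd$per_item[item]), 1L,
                 info = paste("item not flagged:", item))
    expect_equal(cd$total, 1,
                 info = paste("fault bled beyond its item:", item,
                              "- flagged:",
                              paste(names(cd$per_item)[cd$per_item == 1],
                                    collapse = ", ")))
  }
})

test_that("an incorrect dilution alone flags only the dilution item", {
  pol <- ideal_policy()
  pol$faults <- "dilution_error"
  cd <- score_cdevplus(run_scenario(scenario_spec(), pol))
  expect_equal(unname(cd$per_item["correct_dilution"]), 1L)
  expect_equal(cd$total, 1)
})

test_that("removing a required event never decreases the deviation total", {
  tl <- ideal_team_log()
  base <- score_cdevplus(tl)$total
  tap_idx <- which(vapply(tl$log, function(e) e$event, "") %in%
                     c("TAP", "DOSE_COMPUTED", "RHYTHM_SELECTED"))
  for (i in tap_idx) {
    mod <- tl
    mod$log <- tl$log[-i]
    expect_gte(score_cdevplus(mod)$total, base)
  }
})

test_that("scores ignore irrelevant events and survive re-serialization", {
  tl <- ideal_team_log()
  base_cd <- score_cdevplus(tl)
  base_cp <- score_cpt(tl)

  noisy <- tl
  noisy$log <- append(tl$log,
                      list(list(t_s = tl$log[[5]]$t_s,
                                event = "OVERLAY_OPENED",
                                payload = list(overlay = "CPR"))), after = 5)
  expect_identical(score_cdevplus(noisy)$per_item, base_cd$per_item)
  expect_identical(score_cpt(noisy)$per_task, base_cp$per_task)

  f <- withr::local_tempfile()
  export_log(tl, f)
  reread <- tl
  reread$log <- read_log(f)
  expect_identical(score_cdevplus(reread)$per_item, base_cd$per_item)
  expect_identical(score_cpt(reread)$per_task, base_cp$per_task)
})

test_that("time to epinephrine is measured from recognition", {
  expect_equal(time_to_epinephrine(stub_team_log(30, 195)), 165)
  expect_true(is.na(time_to_epinephrine(stub_team_log(include_adm = FALSE))))
  expect_error(time_to_epinephrine(empty_team_log()), "recognition")
  bad <- stub_team_log(30, 195)
  bad$ca_recognition_t_s <- 200
  expect_error(time_to_epinephrine(bad), "precedes")
})

test_that("late actions earn partial credit on the task list", {
  pol <- ideal_policy()
  pol$recognition_latency_median_s <- 70 # past the 60 s window
  cp <- score_cpt(run_scenario(scenario_spec(), pol))
  expect_equal(unname(cp$per_task["recognition_and_help"]), 1)
  expect_equal(cp$total, 12)
})

test_that("a payload constraint naming a missing key is a scoring error", {
  checklist <- load_checklist()
  checklist$items[[4]]$rule$payload$key <- "no_such_key"
  expect_error(score_cdevplus(ideal_team_log(), checklist),
               "correct_compression_ratio")
})

test_that("cohort scoring yields one labeled row per team", {
  co <- generate_cohort(1, 2, seed = 3)
  sc <- score_cohort(co)
  expect_equal(nrow(sc), 3)
  expect_identical(sc$arm, c("control", "intervention", "intervention"))
  expect_true(all(c("cdevplus_total", "cpt_total", "time_to_epi_s") %in%
                    names(sc)))
  expect_true(all(sc$cdevplus_total >= 0 & sc$cdevplus_total <= 16))
  expect_true(all(sc$cpt_total >= 0 & sc$cpt_total <= 13))
})
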