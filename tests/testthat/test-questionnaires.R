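test_that("the normal interval reproduces the published usability table", {
  tab <- usability_table()
  for (i in seq_len(nrow(tab))) {
    ci <- scale_ci(tab$mean[i], tab$sd[i], n = 11)
    expect_lt(abs(ci[["low"]] - tab$ci_low[i]), 0.005)
    expect_lt(abs(ci[["high"]] - tab$ci_high[i]), 0.005)
  }
})

test_that("scale scoring averages polarity-adjusted items per respondent", {
  # uniform +3 answers give every scale mean 3 with zero spread
  q <- data.frame(respondent_id = sprintf("r%02d", 1:5))
  for (i in 1:26) q[[paste0("item_", i)]] <- rep(3L, 5)
  sm <- score_ueq(q)
  expect_true(all(sm$mean == 3))
  expect_true(all(sm$sd == 0))
  expect_true(all(sm$ci_low == 3 & sm$ci_high == 3)) # CI collapses
  expect_true(all(is.na(sm$alpha))) # alpha undefined, reported absent
  expect_true(all(sm$evaluation == "positive"))

  # a reversed item contributes with flipped sign
  map <- load_ueq_scales()
  map$polarity[2] <- -1 # item_2 sits on perspicuity
  q2 <- q
  q2$item_2 <- rep(-3L, 5)
  sm2 <- score_ueq(q2, map)
  expect_equal(sm2$mean[sm2$scale == "perspicuity"], 3)
})

test_that("out-of-range items are rejected naming the respondent", {
  q <- generate_questionnaires(3, "UEQ", seed = 1)
  q$item_5[2] <- 4
  expect_error(score_ueq(q), q$respondent_id[2])
  expect_error(score_ueq(generate_questionnaires(1, "UEQ", seed = 1)),
               "2 respondents")
})

test_that("summaries are invariant to respondent and within-scale item order", {
  q <- generate_questionnaires(11, "UEQ", seed = 12)
  sm <- score_ueq(q)

  perm <- q[sample(nrow(q)), ]
  expect_equal(score_ueq(perm)[, -1], sm[, -1], tolerance = 1e-12)

  # swap two items inside efficiency (indices 9 and 20)
  swapped <- q
  swapped$item_9 <- q$item_20
  swapped$item_20 <- q$item_9
  sm2 <- score_ueq(swapped)
  eff <- sm$scale == "efficiency"
  expect_equal(sm2$mean[eff], sm$mean[eff])
  expect_equal(sm2$sd[eff], sm$sd[eff])
})

test_that("coefficient alpha matches its closed forms", {
  set.seed(3)
  x <- rnorm(30)
  # two perfectly correlated items
  expect_equal(cronbach_alpha(cbind(x, x)), 1)
  # uncorrelated equal-variance items: population alpha 0
  y <- matrix(rnorm(3000), ncol = 3)
  expect_lt(abs(cronbach_alpha(y)), 0.15)
  expect_true(is.na(cronbach_alpha(cbind(rep(1, 10), rep(2, 10)))))
})

test_that("scale scores map onto the evaluation bands", {
  expect_identical(interpret_ueq(1.93), "positive")
  expect_identical(interpret_ueq(0), "neutral")
  expect_identical(interpret_ueq(0.8), "neutral")
  expect_identical(interpret_ueq(-0.8), "neutral")
  expect_identical(interpret_ueq(-0.81), "negative")
  expect_error(interpret_ueq(3.2), "-3, 3")
})

test_that("raw TLX averages six subscales into workload bands", {
  all70 <- c(mental = 70, physical = 70, temporal = 70, performance = 70,
             effort = 70, frustration = 70)
  res <- score_rtlx(all70)
  expect_equal(res$overall, 70)
  expect_identical(res$band, "high")

  expect_identical(score_rtlx(all70 * 0)$band, "low")

  mixed <- c(mental = 40, physical = 40, temporal = 40, performance = 60,
             effort = 60, frustration = 60)
  res <- score_rtlx(mixed)
  expect_equal(res$overall, 50)
  expect_identical(res$band, "moderate")

  # band boundaries are inclusive for "moderate"
  expect_identical(score_rtlx(all70 * 0 + 40)$band, "moderate")
  expect_identical(score_rtlx(all70 * 0 + 60)$band, "moderate")
  expect_identical(score_rtlx(all70 * 0 + 65)$band, "high")
  expect_identical(score_rtlx(all70 * 0 + 35)$band, "low")

  off_grid <- all70; off_grid["effort"] <- 63
  expect_error(score_rtlx(off_grid), "multiples of 5")
  expect_error(score_rtlx(all70[-1]), "six subscales")
})

test_that("generated questionnaires flow through cohort scoring", {
  r <- generate_questionnaires(11, "RTLX",
                               profile = list(mental = list(mean = 70,
                                                            sd = 10)),
                               seed = 9)
  out <- score_rtlx_cohort(r)
  expect_equal(nrow(out), 11)
  expect_true(all(out$band %in% c("low", "moderate", "high")))
})
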