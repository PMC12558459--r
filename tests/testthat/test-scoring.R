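test_that("hand-built sessions score to the hand-counted sheets", {
  sch <- generate_main_schedule(1)

  # flawless participant: all zero, KA 0, KEf 1, all KPr 1
  sh <- score_session(perfect_session(sch))
  expect_equal(sum(sh$position_omissions), 0)
  expect_equal(c(sh$RSU, sh$LSU, sh$RSB, sh$LSB, sh$RH, sh$LH,
                 sh$NIR, sh$NIL, sh$NIB), rep(0L, 9))
  expect_equal(sh$KA_bilateral, 0)
  expect_equal(sh$KA_all, 0)
  expect_equal(sh$KEf_all, 1)
  expect_equal(c(sh$KPrL_bilateral, sh$KPrR_bilateral,
                 sh$KPrL_all, sh$KPrR_all), rep(1, 4))

  # "right" on every trial, digits correct: misses the whole left hemifield
  # and hallucinates right on each of the 21 unilateral-left trials
  sh <- score_session(fixed_side_session(sch, "right"))
  expect_equal(sh$LSU, 21L); expect_equal(sh$LSB, 33L)
  expect_equal(sh$RSU, 0L); expect_equal(sh$RSB, 0L)
  expect_equal(sh$RH, 21L); expect_equal(sh$LH, 0L)
  expect_equal(c(sh$NIR, sh$NIL, sh$NIB), rep(0L, 3))
  expect_equal(sh$KA_all, 1)

  # nothing reported at all: every circle missed, no hallucinations
  # (the asymmetry coefficients are undefined here, hence the suppression)
  sh <- suppressWarnings(score_session(fixed_side_session(sch, "none")))
  expect_equal(c(sh$LSU, sh$LSB, sh$RSU, sh$RSB), c(21L, 33L, 21L, 33L))
  expect_equal(c(sh$RH, sh$LH), c(0L, 0L))

  # all-wrong digits split into NIR / NIL / NIB by trial kind
  sh <- suppressWarnings(
    score_session(fixed_side_session(sch, "none", digits_correct = FALSE)))
  expect_equal(c(sh$NIR, sh$NIL, sh$NIB), c(21L, 21L, 33L))
})

test_that("coefficient formulas reproduce hand arithmetic", {
  expect_equal(ka_bilateral(0, 0, 33), 0)
  expect_equal(ka_bilateral(33, 0, 33), 1)
  expect_equal(ka_bilateral(14, 0, 33), 14 / 52)
  expect_equal(ka_all(21, 33, 0, 0, 54), 1)
  expect_equal(ka_all(16, 29, 4, 6, 54), 35 / 53)
  expect_equal(kef_all(16, 29, 4, 6, 2, 0, 54), (53 - 2) / (53 + 2))
  # misses totalling 50 and two mislocalizations
  expect_equal(kef_all(20, 20, 5, 5, 1, 1, 54), (58 - 2) / (58 + 2))
  sheet <- list(LSB = 29, LSU = 16, RSB = 0, RSU = 0,
                constants = list(BP = 33, LP = 54))
  expect_equal(kpr("left", "all", sheet), 9 / 54)
  expect_equal(kpr("left", "bilateral", sheet), 4 / 33)
  sheet$LSB <- 33
  expect_equal(kpr("left", "bilateral", sheet), 0)
  expect_error(ka_bilateral(34, 0, 33), "out of range")
  expect_error(ka_all(30, 30, 0, 0, 54), "out of range")
})

test_that("zero-denominator coefficients return tagged NA with a warning", {
  expect_warning(v <- ka_bilateral(33, 33, 33), "undefined")
  expect_true(is.na(v))
  expect_warning(v <- ka_all(21, 33, 21, 33, 54), "undefined")
  expect_true(is.na(v))
  expect_warning(v <- kef_all(21, 33, 21, 33, 0, 0, 54), "undefined")
  expect_true(is.na(v))
  # a fully silent session scores end-to-end without crashing
  sch <- generate_main_schedule(4)
  w <- capture_warnings(sh <- score_session(fixed_side_session(sch, "none")))
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.na(sh$KA_all))
  expect_equal(sh$KPrL_all, 0)
})

test_that("omission percentages normalize by per-position presentation counts", {
  sch <- generate_main_schedule(2)
  sh <- suppressWarnings(score_session(fixed_side_session(sch, "none")))
  # everything missed: 100% everywhere despite 6 vs 9 presentations
  expect_equal(unname(omission_percentages(sh)), rep(100, 14))
  sh2 <- score_session(perfect_session(sch))
  sh2$position_omissions[["4"]] <- 3L
  sh2$position_omissions[["2"]] <- 6L
  pct <- omission_percentages(sh2)
  expect_equal(pct[["4"]], 100 * 3 / 9)
  expect_equal(pct[["2"]], 100)
})

test_that("scoring is invariant under trial-order permutation", {
  sch <- generate_main_schedule(5)
  ses <- simulate_session(profile_preset("vn"), sch, seed = 9)
  perm <- sample(75)
  shuf <- ses
  shuf$schedule$trials <- ses$schedule$trials[perm, ]
  shuf$responses <- ses$responses[perm, ]
  a <- score_session(ses)
  b <- score_session(shuf)
  expect_equal(a$position_omissions, b$position_omissions)
  expect_equal(scoresheet_row(a)[-1], scoresheet_row(b)[-1])
})

test_that("left/right antisymmetry and KPr consistency hold across random counts", {
  set.seed(42)
  for (i in 1:50) {
    LSU <- sample(0:21, 1); RSU <- sample(0:21, 1)
    LSB <- sample(0:32, 1); RSB <- sample(0:32, 1)
    # swapping all left and right counts negates both asymmetry coefficients
    expect_equal(ka_bilateral(LSB, RSB, 33), -ka_bilateral(RSB, LSB, 33))
    expect_equal(ka_all(LSU, LSB, RSU, RSB, 54),
                 -ka_all(RSU, RSB, LSU, LSB, 54))
    sheet <- list(LSU = LSU, RSU = RSU, LSB = LSB, RSB = RSB,
                  constants = list(BP = 33, LP = 54))
    swapped <- list(LSU = RSU, RSU = LSU, LSB = RSB, RSB = LSB,
                    constants = sheet$constants)
    expect_equal(kpr("left", "all", sheet), kpr("right", "all", swapped))
    # KPrL_bilateral = 1 - LSB/BP, and KA_all recomputed from KPr agrees
    expect_equal(kpr("left", "bilateral", sheet), 1 - LSB / 33,
                 tolerance = 1e-12)
    kl <- kpr("left", "all", sheet); kr <- kpr("right", "all", sheet)
    expect_equal(ka_all(LSU, LSB, RSU, RSB, 54), (kr - kl) / (kr + kl),
                 tolerance = 1e-12)
  }
})

test_that("KA_all is monotone in each miss count", {
  set.seed(7)
  for (i in 1:25) {
    LSU <- sample(0:20, 1); RSU <- sample(0:20, 1)
    LSB <- sample(0:31, 1); RSB <- sample(0:31, 1)
    base <- ka_all(LSU, LSB, RSU, RSB, 54)
    expect_gt(ka_all(LSU + 1, LSB, RSU, RSB, 54), base)
    expect_gt(ka_all(LSU, LSB + 1, RSU, RSB, 54), base)
    expect_lt(ka_all(LSU, LSB, RSU + 1, RSB, 54), base)
    expect_lt(ka_all(LSU, LSB, RSU, RSB + 1, 54), base)
  }
})

test_that("simulated sessions always satisfy the score-sheet invariants", {
  set.seed(99)
  sch <- generate_main_schedule(6)
  for (i in 1:12) {
    prof <- keen_profile(p_base_left = runif(1), p_base_right = runif(1),
                         vertical_penalty = runif(1),
                         extinction_penalty = runif(1),
                         h_right = runif(1, 0, 0.3), h_left = runif(1, 0, 0.3),
                         d_correct_uni = runif(1), d_correct_bi = runif(1))
    ses <- simulate_session(prof, sch, seed = i)
    expect_length(validate_session(ses), 0)
    sh <- suppressWarnings(score_session(ses))
    expect_true(all(c(sh$RSU, sh$LSU, sh$NIR, sh$NIL) <= 21))
    expect_true(all(c(sh$RSB, sh$LSB, sh$NIB) <= 33))
    expect_true(sh$RH <= 21 && sh$LH <= 21)
    expect_equal(sum(sh$position_omissions[as.character(1:7)]),
                 sh$LSU + sh$LSB)
    expect_equal(sum(sh$position_omissions[as.character(8:14)]),
                 sh$RSU + sh$RSB)
    expect_true(all(sh$position_omissions <= sh$position_max))
    for (k in c("KA_bilateral", "KA_all"))
      if (!is.na(sh[[k]])) expect_true(abs(sh[[k]]) <= 1)
    for (k in c("KPrL_bilateral", "KPrR_bilateral", "KPrL_all", "KPrR_all"))
      expect_true(sh[[k]] >= 0 && sh[[k]] <= 1)
  }
})
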