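test_that("stimulus thickness is calibrated to the acuity threshold", {
  mk <- function(thr, gradable = TRUE) {
    structure(list(threshold_logmar = thr, n_trials = 20L, n_reversals = 6L,
                   gradable = gradable), class = "acuity_result")
  }
  # same trig rule as optotype sizing: 330 * tan(5 * 10^logMAR arcmin)
  expect_equal(as.numeric(scale_stimulus(mk(0.2))), 0.760, tolerance = 1e-3)
  expect_equal(as.numeric(scale_stimulus(mk(1.0))), 4.800, tolerance = 1e-3)
  # floored at the base thickness for very good acuity
  cfg <- inattention_config(base_thickness_mm = 0.5)
  expect_equal(as.numeric(scale_stimulus(mk(0.0), cfg)), 0.5)
  # monotone non-decreasing in logMAR
  th <- vapply(seq(0, 1.2, by = 0.2),
               function(l) as.numeric(scale_stimulus(mk(l))), numeric(1))
  expect_true(all(diff(th) >= 0))
  # non-gradable acuity falls back to max thickness with a flag
  fb <- scale_stimulus(mk(NA, gradable = FALSE))
  expect_equal(as.numeric(fb), inattention_config()$max_thickness_mm)
  expect_true(attr(fb, "acuity_fallback"))
})

test_that("bisection deviation is a signed percent of the half-length", {
  expect_equal(bisection_deviation(0, 100), 0)
  expect_equal(bisection_deviation(50, 100), 100)  # right endpoint
  expect_equal(bisection_deviation(10, 100), 20)
  expect_true(is.na(bisection_deviation(NA, 100))) # omission
})

test_that("laterality index follows (R - L) / (R + L)", {
  b <- cancellation_board(seed = 1)
  all_ids <- b$targets$target_id
  expect_equal(laterality_index(b, all_ids), 0)
  right_ids <- b$targets$target_id[b$targets$side == "right"]
  left_ids <- b$targets$target_id[b$targets$side == "left"]
  expect_equal(laterality_index(b, right_ids), 1)
  expect_equal(laterality_index(b, c(left_ids[1:15], right_ids)),
               5 / 35) # L = 15, R = 20
  expect_true(is.na(laterality_index(b, integer(0))))
  expect_error(laterality_index(b, 999L), "unknown targets")
})

test_that("LI stays in [-1, 1] and negates under a left/right label swap", {
  b <- cancellation_board(seed = 7)
  swapped <- b
  swapped$targets$side <- ifelse(b$targets$side == "left", "right", "left")
  set.seed(31)
  for (i in 1:20) {
    marked <- sample(b$targets$target_id, sample(1:40, 1))
    li <- laterality_index(b, marked)
    expect_gte(li, -1); expect_lte(li, 1)
    expect_equal(laterality_index(swapped, marked), -li)
  }
})

test_that("mirror-reflecting bisection taps negates the mean deviation", {
  lines <- line_stimuli()
  taps <- c(5, -3, 10, NA, 2, -8)
  d1 <- mean(bisection_deviation(taps, lines$length_mm), na.rm = TRUE)
  d2 <- mean(bisection_deviation(-taps, lines$length_mm), na.rm = TRUE)
  expect_equal(d2, -d1)
})

test_that("the default board is balanced and off-midline", {
  b <- cancellation_board()
  expect_equal(b$n_left, 20L)
  expect_equal(b$n_right, 20L)
  expect_true(all(abs(b$targets$x_mm) >= 1))
})

test_that("either abnormal test flags inattention, with the correct side", {
  b <- cancellation_board(seed = 1)
  lines <- line_stimuli()
  mk_score <- function(marked, taps) inattention_score(b, marked, taps, lines)
  all_ids <- b$targets$target_id
  right_ids <- b$targets$target_id[b$targets$side == "right"]

  normal <- classify_inattention(mk_score(all_ids, rep(0, 6)))
  expect_equal(normal$grade, "within normal limits")

  # LI +0.5 via 20 right / ~6-7 left marks: left-sided inattention
  left_ids <- b$targets$target_id[b$targets$side == "left"]
  li_case <- classify_inattention(mk_score(c(right_ids, left_ids[1:6]),
                                           rep(0, 6)))
  expect_equal(li_case$grade, "consistent with inattention")
  expect_equal(li_case$side, "left")

  # rightward bisection deviation alone also flags left inattention
  dev_case <- classify_inattention(mk_score(all_ids, rep(15, 6)))
  expect_equal(dev_case$grade, "consistent with inattention")
  expect_equal(dev_case$side, "left")

  # leftward deviation flags the right side
  dev_r <- classify_inattention(mk_score(all_ids, rep(-15, 6)))
  expect_equal(dev_r$side, "right")

  none <- classify_inattention(mk_score(integer(0), rep(NA_real_, 6)))
  expect_equal(none$grade, "non-gradable")
})

test_that("a simulated left-neglect observer always yields positive LI", {
  pos <- 0
  for (i in 1:200) {
    prof <- observer_profile(neglect_lambda = 1, lapse_rate = 0,
                             seed = 6000 + i)
    b <- cancellation_board(seed = 6000 + i)
    s <- simulate_inattention_session(prof, b)
    if (laterality_index(b, s$marked) > 0) pos <- pos + 1
  }
  expect_equal(pos, 200)
})

test_that("bias and jitter flow through to bisection deviations exactly", {
  prof <- observer_profile(bisection_bias_pct = 20, motor_jitter_mm = 0,
                           lapse_rate = 0, seed = 5)
  s <- simulate_inattention_session(prof)
  devs <- bisection_deviation(s$bisection_taps_mm, line_stimuli()$length_mm)
  expect_equal(devs, rep(20, 6))
})
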