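test_that("default plan has 24 boundary trials and 4 catch trials per eye", {
  plan <- default_plan
  for (eye in c("left", "right")) {
    p <- plan[plan$eye == eye, ]
    expect_equal(sum(!p$is_catch_trial), 24L) # 4 quadrants x 3 meridians x 2
    expect_equal(sum(p$is_catch_trial), 4L)
  }
  # one meridian per quadrant, one repeat
  cfg1 <- perimetry_config(quadrant_offsets_deg = 45, repeats = 1)
  p1 <- plan_trials(default_screen, cfg1)
  expect_equal(sum(!p1$is_catch_trial & p1$eye == "left"), 4L)
})

test_that("planned start eccentricities are bounded by the screen edge", {
  plan <- default_plan
  scr <- default_screen
  # the largest possible extent is the full screen diagonal from a corner
  diag_deg <- atan(sqrt(scr$width_mm^2 + scr$height_mm^2) /
                     scr$viewing_distance_mm) * 180 / pi
  expect_true(all(plan$start_eccentricity_deg > 0))
  expect_true(all(plan$start_eccentricity_deg <= diag_deg + 1e-9))
})

test_that("config meridians outside the quadrant are a planning error", {
  expect_error(perimetry_config(quadrant_offsets_deg = c(15, 95)), "planning")
  expect_error(perimetry_config(quadrant_offsets_deg = 0), "planning")
})

test_that("target motion is linear inward and floors at fixation", {
  tr <- list(start_eccentricity_deg = 40, speed_deg_per_s = 3)
  expect_equal(target_position(tr, 0), 40)
  expect_equal(target_position(tr, 5), 25)
  expect_equal(target_position(tr, 40 / 3), 0)
  expect_equal(target_position(tr, 100), 0)
})

test_that("reaction-time correction shifts the boundary outward", {
  expect_equal(correct_reaction_time(20, 3, 0), 20)
  expect_equal(correct_reaction_time(20, 3, 0.5), 21.5)
  rts <- seq(0, 1, by = 0.1)
  expect_true(all(diff(correct_reaction_time(20, 3, rts)) > 0))
  expect_true(all(diff(correct_reaction_time(20, seq(1, 6), 0.5)) > 0))
  expect_error(correct_reaction_time(-1, 3, 0.5), "non-negative")
})

test_that("reaction time is the median catch latency, with documented fallback", {
  plan <- default_plan
  catches <- plan[plan$is_catch_trial & plan$eye == "left", ]
  ev <- detection_events(catches[1:3, ], c(0.4, 0.5, 0.6))
  rt <- estimate_reaction_time(ev)
  expect_equal(as.numeric(rt), 0.5)
  expect_false(attr(rt, "default_used"))

  ev1 <- detection_events(catches[1, ], 0.3)
  expect_equal(as.numeric(estimate_reaction_time(ev1)), 0.3)

  empty <- detection_events(catches, NA_real_)
  rt0 <- estimate_reaction_time(empty)
  expect_equal(as.numeric(rt0), 0.5) # configured default
  expect_true(attr(rt0, "default_used"))
})

test_that("field map scoring: latest valid repeat wins and deletes are audited", {
  plan <- default_plan
  one <- plan[!plan$is_catch_trial & plan$eye == "left", ][1:2, ] # same meridian
  stopifnot(one$meridian_deg[1] == one$meridian_deg[2])
  # first repeat deleted for fixation loss, retest detects later (smaller ecc)
  ev <- detection_events(one, c(1.0, 4.0), deleted = c(TRUE, FALSE))
  map <- build_field_map(ev, rt_s = 0, config = default_perim_config)
  i <- which(map$points$meridian_deg == one$meridian_deg[1])
  expect_equal(map$points$raw_ecc_deg[i],
               one$start_eccentricity_deg[1] - 3 * 4.0)
  expect_true(map$points$any_deleted[i])
  expect_equal(map$deleted_fraction, 0.5)
})

test_that("mixed-eye events are rejected", {
  expect_error(build_field_map(detection_events(default_plan[c(1, 30), ], 1),
                               rt_s = 0.5),
               "one eye")
})

test_that("a full field with zero RT maps to the screen-edge extent", {
  prof <- observer_profile(field = make_field_defect("normal"),
                           rt_lognormal_mu = log(1e-12),
                           rt_lognormal_sigma = 0, lapse_rate = 0, seed = 2)
  ev <- simulate_perimetry_session(prof, default_plan)
  evl <- ev[ev$eye == "left", ]
  map <- build_field_map(evl, 0, default_perim_config)
  expect_true(all(map$points$detected))
  expect_equal(map$points$corrected_ecc_deg, map$points$tested_extent_deg,
               tolerance = 1e-9)
})

test_that("both full maps grade within normal limits", {
  prof <- observer_profile(field = make_field_defect("normal"),
                           rt_lognormal_sigma = 0, lapse_rate = 0, seed = 2)
  cls <- classify_simulated(prof)
  expect_equal(cls$grade, "within normal limits")
  expect_null(cls$subtype)
})

test_that("a deleted fraction of one half is non-gradable by construction", {
  plan <- default_plan[default_plan$eye == "left", ]
  # every presentation deleted once and retested: deleted fraction exactly 0.5
  ev <- rbind(detection_events(plan, 0.5, deleted = TRUE),
              detection_events(plan, 0.5, deleted = FALSE))
  cfg <- default_perim_config
  map_l <- build_field_map(ev, 0.5, cfg)
  expect_equal(map_l$deleted_fraction, 0.5)
  ev_r <- detection_events(default_plan[default_plan$eye == "right", ], 0.5)
  map_r <- build_field_map(ev_r, 0.5, cfg)
  expect_equal(classify_field(map_l, map_r, cfg)$grade, "non-gradable")
})

test_that("a heavily deleted session is non-gradable", {
  prof <- observer_profile(field = make_field_defect("normal"),
                           rt_lognormal_sigma = 0, lapse_rate = 0,
                           fixation_loss_rate = 0.8, seed = 21)
  ev <- simulate_perimetry_session(prof, default_plan)
  cfg <- default_perim_config
  maps <- lapply(c(left = "left", right = "right"), function(eye) {
    e <- ev[ev$eye == eye, ]
    build_field_map(e, as.numeric(estimate_reaction_time(e, cfg)), cfg)
  })
  expect_gt(maps$left$deleted_fraction, 0.3)
  expect_equal(classify_field(maps$left, maps$right, cfg)$grade, "non-gradable")
})

test_that("raising defect_fraction never converts a complete defect to normal", {
  prof <- observer_profile(field = make_field_defect("hemianopia", side = "left"),
                           rt_lognormal_sigma = 0, lapse_rate = 0, seed = 5)
  ev <- simulate_perimetry_session(prof, default_plan)
  for (df in c(0.3, 0.5, 0.7, 0.9)) {
    cfg <- perimetry_config(defect_fraction = df)
    maps <- lapply(c(left = "left", right = "right"), function(eye) {
      e <- ev[ev$eye == eye, ]
      build_field_map(e, as.numeric(estimate_reaction_time(e, cfg)), cfg)
    })
    cls <- classify_field(maps$left, maps$right, cfg)
    expect_equal(cls$grade, "stroke-related defect")
  }
})

test_that("isopter CSV export carries the audited columns", {
  prof <- observer_profile(seed = 3)
  ev <- simulate_perimetry_session(prof, default_plan)
  evl <- ev[ev$eye == "left", ]
  map <- build_field_map(evl, 0.5, default_perim_config)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_isopter_csv(map, path)
  back <- read.csv(path)
  expect_equal(names(back), c("eye", "meridian_deg", "raw_ecc_deg",
                              "corrected_ecc_deg", "detected", "deleted"))
  expect_equal(nrow(back), 12L)
})
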