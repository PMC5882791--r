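#' Kinetic perimetry configuration
#'
#' Defaults for the tablet kinetic field test. The fixation anchor visits the
#' four screen corners; from each corner the target emerges at the screen edge
#' and travels inward along meridians that point into the opposite screen
#' quadrant. None of these values is normative — they are tunable test-battery
#' parameters reflecting standard kinetic-perimetry practice.
#'
#' @param quadrant_offsets_deg Meridian offsets within each tested quadrant,
#'   in degrees from the quadrant's lower edge; must lie strictly inside
#'   (0, 90).
#' @param repeats Boundary presentations per meridian; the latest valid repeat
#'   is scored (delete-and-retest semantics).
#' @param speed_deg_per_s Inward target speed in degrees of visual angle per
#'   second.
#' @param catch_meridians_deg Meridians of the centre-anchored catch trials
#'   used for reaction-time calibration and macula-sparing detection.
#' @param defect_fraction A meridian is scored defective when its corrected
#'   eccentricity falls below this fraction of the tested extent.
#' @param quadrant_majority A quadrant is defective when the fraction of its
#'   defective meridians strictly exceeds this value.
#' @param sparing_radius_deg Radius of the central island tested for macula
#'   sparing.
#' @param sparing_tolerance_deg Slack added to the sparing radius when judging
#'   whether a central catch detection indicates sparing.
#' @param max_deleted_fraction Above this deleted-event fraction in either eye
#'   the session is non-gradable.
#' @param max_unanswered_fraction Above this fraction of unanswered trials in
#'   expected-seen quadrants the session is non-gradable.
#' @param default_rt_s Fallback reaction time when no usable catch trial
#'   exists.
#' @param supra_fraction Catch detections with tap eccentricity below this
#'   fraction of the start eccentricity are excluded from reaction-time
#'   estimation (they reflect late entry into a seen region, not latency).
#' @return A list of class `perimetry_config`.
#' @export
perimetry_config <- function(quadrant_offsets_deg = c(15, 45, 75),
                             repeats = 2L,
                             speed_deg_per_s = 3,
                             catch_meridians_deg = c(45, 135, 225, 315),
                             defect_fraction = 0.5,
                             quadrant_majority = 0.5,
                             sparing_radius_deg = 5,
                             sparing_tolerance_deg = 2,
                             max_deleted_fraction = 0.3,
                             max_unanswered_fraction = 0.25,
                             default_rt_s = 0.5,
                             supra_fraction = 0.5) {
  if (any(quadrant_offsets_deg <= 0 | quadrant_offsets_deg >= 90)) {
    stop("planning error: quadrant meridian offsets must lie strictly inside (0, 90) degrees",
         call. = FALSE)
  }
  stopifnot(speed_deg_per_s > 0, repeats >= 1, defect_fraction > 0,
            defect_fraction <= 1, sparing_radius_deg > 0)
  structure(list(quadrant_offsets_deg = quadrant_offsets_deg,
                 repeats = as.integer(repeats),
                 speed_deg_per_s = speed_deg_per_s,
                 catch_meridians_deg = catch_meridians_deg,
                 defect_fraction = defect_fraction,
                 quadrant_majority = quadrant_majority,
                 sparing_radius_deg = sparing_radius_deg,
                 sparing_tolerance_deg = sparing_tolerance_deg,
                 max_deleted_fraction = max_deleted_fraction,
                 max_unanswered_fraction = max_unanswered_fraction,
                 default_rt_s = default_rt_s,
                 supra_fraction = supra_fraction),
            class = "perimetry_config")
}

# anchor positions in screen mm, patient-view axes (origin bottom-left, y up)
anchor_position_mm <- function(anchor, screen) {
  switch(anchor,
         "bottom-left"  = c(0, 0),
         "bottom-right" = c(screen$width_mm, 0),
         "top-right"    = c(screen$width_mm, screen$height_mm),
         "top-left"     = c(0, screen$height_mm),
         "centre"       = c(screen$width_mm / 2, screen$height_mm / 2),
         stop("unknown fixation anchor: ", anchor, call. = FALSE))
}

# visual quadrant tested from each corner anchor (targets come from the
# opposite region of the screen)
anchor_quadrant_base <- c("bottom-left" = 0, "bottom-right" = 90,
                          "top-right" = 180, "top-left" = 270)

# distance (mm) from an anchor to the screen edge along a meridian
edge_distance_mm <- function(origin_mm, meridian_deg, screen) {
  d <- c(cos(meridian_deg * pi / 180), sin(meridian_deg * pi / 180))
  ts <- c(
    if (d[1] > 1e-12) (screen$width_mm - origin_mm[1]) / d[1] else Inf,
    if (d[1] < -1e-12) (0 - origin_mm[1]) / d[1] else Inf,
    if (d[2] > 1e-12) (screen$height_mm - origin_mm[2]) / d[2] else Inf,
    if (d[2] < -1e-12) (0 - origin_mm[2]) / d[2] else Inf
  )
  min(ts)
}

#' Plan the kinetic field trials for a session
#'
#' For each eye, each of the four corner fixation anchors contributes
#' `length(quadrant_offsets_deg)` meridians pointing into the opposite screen
#' quadrant, each presented `repeats` times, plus one centre-anchored catch
#' trial per catch meridian. Targets start at the screen edge; the start
#' eccentricity is the visual angle subtended by the anchor-to-edge distance
#' along the meridian at the screen's viewing distance.
#'
#' @param screen A [screen_spec()].
#' @param config A [perimetry_config()].
#' @param eyes Eyes to plan (both by default; tested monocularly).
#' @return A data frame of trial specifications, one row per presentation,
#'   with class `trial_plan`.
#' @examples
#' plan <- plan_trials(screen_spec())
#' table(plan$eye, plan$is_catch_trial) # 24 boundary + 4 catch per eye
#' @export
plan_trials <- function(screen, config = perimetry_config(),
                        eyes = c("left", "right")) {
  stopifnot(inherits(screen, "screen_spec"), inherits(config, "perimetry_config"))
  rows <- list()
  for (eye in eyes) {
    for (anchor in names(anchor_quadrant_base)) {
      origin <- anchor_position_mm(anchor, screen)
      for (off in config$quadrant_offsets_deg) {
        mer <- (anchor_quadrant_base[[anchor]] + off) %% 360
        dist_mm <- edge_distance_mm(origin, mer, screen)
        start_ecc <- atan(dist_mm / screen$viewing_distance_mm) * 180 / pi
        for (rep_i in seq_len(config$repeats)) {
          rows[[length(rows) + 1L]] <- data.frame(
            eye = eye, fixation_anchor = anchor, meridian_deg = mer,
            start_eccentricity_deg = start_ecc,
            speed_deg_per_s = config$speed_deg_per_s,
            is_catch_trial = FALSE, repeat_index = rep_i,
            stringsAsFactors = FALSE)
        }
      }
    }
    origin <- anchor_position_mm("centre", screen)
    for (mer in config$catch_meridians_deg) {
      dist_mm <- edge_distance_mm(origin, mer %% 360, screen)
      start_ecc <- atan(dist_mm / screen$viewing_distance_mm) * 180 / pi
      rows[[length(rows) + 1L]] <- data.frame(
        eye = eye, fixation_anchor = "centre", meridian_deg = mer %% 360,
        start_eccentricity_deg = start_ecc,
        speed_deg_per_s = config$speed_deg_per_s,
        is_catch_trial = TRUE, repeat_index = 1L,
        stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, rows)
  plan$trial_id <- seq_len(nrow(plan))
  class(plan) <- c("trial_plan", class(plan))
  plan
}

#' Target eccentricity at a given time
#'
#' Linear inward motion along the trial's meridian, floored at fixation.
#'
#' @param trial One row of a [plan_trials()] data frame (or any list with
#'   `start_eccentricity_deg` and `speed_deg_per_s`).
#' @param t_s Time since target onset, seconds (>= 0).
#' @return Eccentricity in degrees.
#' @export
target_position <- function(trial, t_s) {
  stopifnot(all(t_s >= 0))
  pmax(0, trial$start_eccentricity_deg - trial$speed_deg_per_s * t_s)
}

#' Build detection events from trials and tap times
#'
#' @param trials A `trial_plan` (or subset of its rows).
#' @param tap_time_s Numeric vector of tap latencies from target onset, `NA`
#'   for no tap.
#' @param deleted Logical vector: event deleted after an observed fixation
#'   loss (swipe-to-delete); deleted events are excluded from scoring but kept
#'   in the log so the deleted fraction stays auditable.
#' @return A data frame of detection events.
#' @export
detection_events <- function(trials, tap_time_s, deleted = FALSE) {
  n <- nrow(trials)
  tap_time_s <- rep_len(tap_time_s, n)
  deleted <- rep_len(deleted, n)
  ev <- trials
  ev$tap_time_s <- tap_time_s
  ev$target_eccentricity_at_tap_deg <-
    ifelse(is.na(tap_time_s), NA_real_,
           pmax(0, trials$start_eccentricity_deg -
                  trials$speed_deg_per_s * tap_time_s))
  ev$deleted_for_fixation_loss <- deleted
  class(ev) <- "data.frame"
  ev
}

#' Reaction-time correction of a detection eccentricity
#'
#' During the tap latency the target keeps moving inward, so the perceptual
#' boundary lies further out than the tap position: the corrected
#' eccentricity is `raw + speed * reaction_time`.
#'
#' @param raw_ecc_deg Eccentricity at the tap, degrees.
#' @param speed_deg_per_s Target speed.
#' @param reaction_time_s Estimated tap latency, seconds.
#' @return Corrected eccentricity in degrees.
#' @export
correct_reaction_time <- function(raw_ecc_deg, speed_deg_per_s, reaction_time_s) {
  if (any(raw_ecc_deg < 0) || any(speed_deg_per_s < 0) || any(reaction_time_s < 0)) {
    stop("raw eccentricity, speed and reaction time must be non-negative",
         call. = FALSE)
  }
  raw_ecc_deg + speed_deg_per_s * reaction_time_s
}

#' Estimate the observer's reaction time from catch trials
#'
#' The median tap latency over centre-anchored catch trials at suprathreshold
#' locations. Detections whose tap eccentricity has fallen below
#' `supra_fraction` of the start eccentricity are excluded: such taps mark a
#' late entry into a seen region (e.g. a spared central island), not pure
#' latency. With no usable catch detection the configured default is returned
#' with attribute `default_used = TRUE`.
#'
#' @param events Detection events (any mix; catch trials are selected
#'   internally).
#' @param config A [perimetry_config()].
#' @return Reaction time in seconds, with attribute `default_used`.
#' @export
estimate_reaction_time <- function(events, config = perimetry_config()) {
  ok <- events$is_catch_trial & !events$deleted_for_fixation_loss &
    !is.na(events$tap_time_s) &
    events$target_eccentricity_at_tap_deg >=
      config$supra_fraction * events$start_eccentricity_deg
  if (!any(ok)) {
    return(structure(config$default_rt_s, default_used = TRUE))
  }
  structure(stats::median(events$tap_time_s[ok]), default_used = FALSE)
}

#' Construct a corrected field map for one eye
#'
#' Per meridian the latest valid (non-deleted) repeat wins, implementing the
#' swipe-to-delete-and-retest semantics. The raw detection eccentricity is
#' corrected for reaction time and clamped to the meridian's tested extent
#' (nothing can be inferred beyond the screen edge); meridians with no tap are
#' recorded as non-detections.
#'
#' @param events Detection events for a single eye.
#' @param rt_s Reaction time used for correction (seconds).
#' @param config A [perimetry_config()].
#' @return A `field_map` object: `eye`, per-meridian `points` (with
#'   `raw_ecc_deg`, `corrected_ecc_deg`, `detected`, `any_deleted`),
#'   `catch_points`, `tested_extent_deg` and `deleted_fraction`.
#' @export
build_field_map <- function(events, rt_s, config = perimetry_config()) {
  eyes <- unique(events$eye)
  if (length(eyes) != 1) {
    stop("events from more than one eye supplied to build_field_map", call. = FALSE)
  }
  deleted_fraction <- mean(events$deleted_for_fixation_loss)

  score_one <- function(ev) {
    valid <- ev[!ev$deleted_for_fixation_loss, , drop = FALSE]
    extent <- ev$start_eccentricity_deg[1]
    if (nrow(valid) == 0 || all(is.na(valid$tap_time_s))) {
      return(list(raw = NA_real_, corr = NA_real_, detected = FALSE,
                  extent = extent, any_deleted = any(ev$deleted_for_fixation_loss)))
    }
    last <- valid[nrow(valid), ]
    if (is.na(last$tap_time_s)) {
      return(list(raw = NA_real_, corr = NA_real_, detected = FALSE,
                  extent = extent, any_deleted = any(ev$deleted_for_fixation_loss)))
    }
    raw <- last$target_eccentricity_at_tap_deg
    corr <- min(extent, correct_reaction_time(raw, last$speed_deg_per_s, rt_s))
    list(raw = raw, corr = corr, detected = TRUE, extent = extent,
         any_deleted = any(ev$deleted_for_fixation_loss))
  }

  boundary <- events[!events$is_catch_trial, , drop = FALSE]
  mers <- unique(boundary$meridian_deg)
  pts <- lapply(mers, function(m) {
    s <- score_one(boundary[boundary$meridian_deg == m, , drop = FALSE])
    data.frame(meridian_deg = m, raw_ecc_deg = s$raw, corrected_ecc_deg = s$corr,
               detected = s$detected, tested_extent_deg = s$extent,
               any_deleted = s$any_deleted)
  })
  points <- do.call(rbind, pts)
  points <- points[order(points$meridian_deg), , drop = FALSE]
  rownames(points) <- NULL

  catches <- events[events$is_catch_trial, , drop = FALSE]
  catch_points <- if (nrow(catches) > 0) {
    cp <- lapply(unique(catches$meridian_deg), function(m) {
      s <- score_one(catches[catches$meridian_deg == m, , drop = FALSE])
      data.frame(meridian_deg = m, raw_ecc_deg = s$raw,
                 corrected_ecc_deg = s$corr, detected = s$detected,
                 tested_extent_deg = s$extent)
    })
    do.call(rbind, cp)
  } else {
    data.frame(meridian_deg = numeric(0), raw_ecc_deg = numeric(0),
               corrected_ecc_deg = numeric(0), detected = logical(0),
               tested_extent_deg = numeric(0))
  }

  # unanswered = valid presentation with no tap, tallied later per quadrant
  valid_ev <- events[!events$deleted_for_fixation_loss, , drop = FALSE]
  unanswered <- data.frame(meridian_deg = valid_ev$meridian_deg,
                           answered = !is.na(valid_ev$tap_time_s))

  structure(list(eye = eyes, points = points, catch_points = catch_points,
                 tested_extent_deg = stats::setNames(points$tested_extent_deg,
                                                     points$meridian_deg),
                 deleted_fraction = deleted_fraction,
                 unanswered_log = unanswered,
                 rt_s = as.numeric(rt_s)),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %s eye: %d meridians, %d detected, deleted fraction %.2f\n",
              x$eye, nrow(x$points), sum(x$points$detected), x$deleted_fraction))
  invisible(x)
}

quadrant_names <- c("upper-right", "upper-left", "lower-left", "lower-right")

meridian_quadrant <- function(meridian_deg) {
  quadrant_names[(floor((meridian_deg %% 360) / 90) %% 4) + 1]
}

defective_quadrants <- function(map, config) {
  pts <- map$points
  defective <- !pts$detected |
    pts$corrected_ecc_deg < config$defect_fraction * pts$tested_extent_deg
  q <- meridian_quadrant(pts$meridian_deg)
  vapply(quadrant_names, function(qn) {
    sel <- q == qn
    if (!any(sel)) return(FALSE)
    mean(defective[sel]) > config$quadrant_majority
  }, logical(1))
}

unanswered_fraction_seen <- function(map, defq, config) {
  log <- map$unanswered_log
  q <- meridian_quadrant(log$meridian_deg)
  seen <- !defq[q]
  if (!any(seen)) return(0)
  mean(!log$answered[seen])
}

sparing_detected <- function(map, defq, config) {
  cp <- map$catch_points
  if (nrow(cp) == 0) return(FALSE)
  q <- meridian_quadrant(cp$meridian_deg)
  into_defect <- defq[q]
  any(into_defect & cp$detected &
        cp$corrected_ecc_deg <= config$sparing_radius_deg +
          config$sparing_tolerance_deg, na.rm = TRUE)
}

#' Three-way grading of a pair of monocular field maps
#'
#' A quadrant is defective in one eye when the majority of its meridians are
#' either undetected or detected well inside the tested extent. A defect is
#' homonymous when the same visual-field quadrants are defective in both
#' eyes; two stacked quadrants on one side make a hemianopia, exactly one a
#' quadrantanopia. A hemianopia whose centre-anchored catch trials were still
#' detected within the sparing radius (both eyes) is the macula-sparing
#' variant. Sessions with too many deleted events, or too many unanswered
#' trials in quadrants expected to be seen, are non-gradable: in a complete
#' defect the blind-side trials are legitimately unanswered, so only
#' expected-seen quadrants count toward the unanswered-trial threshold.
#'
#' @param left,right `field_map` objects for the two eyes of one session.
#' @param config A [perimetry_config()].
#' @return A `field_classification`: `grade` in `stroke-related defect` /
#'   `within normal limits` / `non-gradable`; `subtype` (present iff a
#'   defect); per-eye diagnostic details.
#' @export
classify_field <- function(left, right, config = perimetry_config()) {
  stopifnot(inherits(left, "field_map"), inherits(right, "field_map"))
  if (!identical(sort(c(left$eye, right$eye)), c("left", "right"))) {
    stop("classify_field needs one left-eye and one right-eye map", call. = FALSE)
  }
  if (left$eye == "right") { tmp <- left; left <- right; right <- tmp }

  defq_l <- defective_quadrants(left, config)
  defq_r <- defective_quadrants(right, config)
  homonymous <- defq_l & defq_r

  unans_l <- unanswered_fraction_seen(left, defq_l, config)
  unans_r <- unanswered_fraction_seen(right, defq_r, config)

  details <- list(defective_quadrants_left = defq_l,
                  defective_quadrants_right = defq_r,
                  homonymous_quadrants = homonymous,
                  deleted_fraction = c(left = left$deleted_fraction,
                                       right = right$deleted_fraction),
                  unanswered_fraction_seen = c(left = unans_l, right = unans_r))

  if (left$deleted_fraction > config$max_deleted_fraction ||
      right$deleted_fraction > config$max_deleted_fraction ||
      unans_l > config$max_unanswered_fraction ||
      unans_r > config$max_unanswered_fraction) {
    return(structure(list(grade = "non-gradable", subtype = NULL,
                          details = details), class = "field_classification"))
  }

  if (!any(homonymous)) {
    return(structure(list(grade = "within normal limits", subtype = NULL,
                          details = details), class = "field_classification"))
  }

  left_side <- all(homonymous[c("upper-left", "lower-left")])
  right_side <- all(homonymous[c("upper-right", "lower-right")])
  n_def <- sum(homonymous)

  subtype <- if (left_side || right_side) {
    side <- if (left_side && right_side) {
      # near-total loss: report the side with the deeper defect
      sev <- function(map, quads) {
        pts <- map$points
        sel <- meridian_quadrant(pts$meridian_deg) %in% quads
        mean(!pts$detected[sel])
      }
      lq <- c("upper-left", "lower-left"); rq <- c("upper-right", "lower-right")
      if (sev(left, lq) + sev(right, lq) >= sev(left, rq) + sev(right, rq))
        "left" else "right"
    } else if (left_side) "left" else "right"
    sparing <- sparing_detected(left, defq_l, config) &&
      sparing_detected(right, defq_r, config)
    if (sparing) paste("macula-sparing hemianopia", side)
    else paste("homonymous hemianopia", side)
  } else if (n_def == 1) {
    paste("homonymous quadrantanopia", quadrant_names[which(homonymous)])
  } else {
    # non-stacked multi-quadrant pattern: name the most defective quadrant
    sev_q <- vapply(quadrant_names, function(qn) {
      f <- function(map) {
        sel <- meridian_quadrant(map$points$meridian_deg) == qn
        mean(!map$points$detected[sel])
      }
      f(left) + f(right)
    }, numeric(1))
    cand <- quadrant_names[homonymous]
    paste("homonymous quadrantanopia", cand[which.max(sev_q[cand])])
  }

  structure(list(grade = "stroke-related defect", subtype = subtype,
                 details = details), class = "field_classification")
}

#' @export
print.field_classification <- function(x, ...) {
  cat(sprintf("<field_classification> %s%s\n", x$grade,
              if (!is.null(x$subtype)) paste0(" (", x$subtype, ")") else ""))
  invisible(x)
}

#' Export an isopter as CSV
#'
#' @param map A `field_map`.
#' @param path Output file path.
#' @return The exported data frame, invisibly.
#' @export
write_isopter_csv <- function(map, path) {
  stopifnot(inherits(map, "field_map"))
  out <- data.frame(eye = map$eye,
                    meridian_deg = map$points$meridian_deg,
                    raw_ecc_deg = map$points$raw_ecc_deg,
                    corrected_ecc_deg = map$points$corrected_ecc_deg,
                    detected = map$points$detected,
                    deleted = map$points$any_deleted)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
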