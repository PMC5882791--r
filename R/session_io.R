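SESSION_SCHEMA_VERSION <- "1.0"

#' Simulate a complete screening session
#'
#' Runs the whole battery — adaptive acuity, monocular kinetic perimetry for
#' both eyes, and the inattention tests — for one simulated observer and
#' assembles a versioned session record holding the raw trial-level data,
#' the derived scores, and the configuration snapshot. Everything derived is
#' recomputable from the raw data (see [score_session()]), which is the
#' record's integrity contract.
#'
#' @param profile An [observer_profile()].
#' @param screen A [screen_spec()].
#' @param patient_pseudo_id Pseudonymised identifier string.
#' @param perim_config,stair_config,inatt_config Module configurations.
#' @return A `session_record` list.
#' @export
simulate_session <- function(profile, screen = screen_spec(),
                             patient_pseudo_id = "sim-0001",
                             perim_config = perimetry_config(),
                             stair_config = staircase_config(),
                             inatt_config = inattention_config()) {
  stopifnot(inherits(profile, "observer_profile"))

  stair <- simulate_acuity_session(profile, stair_config)
  acuity <- estimate_threshold(stair)

  plan <- plan_trials(screen, perim_config)
  events <- simulate_perimetry_session(profile, plan)
  scored <- score_perimetry(events, perim_config)

  board <- cancellation_board(seed = profile$seed + 3L)
  thickness <- scale_stimulus(acuity, inatt_config)
  lines <- line_stimuli(inatt_config, thickness_mm = as.numeric(thickness))
  inatt <- simulate_inattention_session(profile, board, lines)
  score <- inattention_score(board, inatt$marked, inatt$bisection_taps_mm, lines)
  inatt_cls <- classify_inattention(score, inatt_config)

  trials_df <- do.call(rbind, lapply(stair$trial_history, function(tr) {
    data.frame(level_logmar = tr$level_logmar,
               true_orientation = tr$true_orientation,
               response_orientation = tr$response_orientation,
               correct = tr$correct)
  }))

  record <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    patient_pseudo_id = patient_pseudo_id,
    device = screen[c("width_px", "height_px", "pixels_per_inch",
                      "viewing_distance_mm")],
    seeds = list(profile_seed = profile$seed, board_seed = profile$seed + 3L),
    config = list(perimetry = unclass(perim_config),
                  staircase = unclass(stair_config),
                  inattention = unclass(inatt_config)),
    acuity = list(result = unclass(acuity), trials = trials_df),
    perimetry = list(
      events = events,
      reaction_time_s = scored$rt,
      classification = list(grade = scored$classification$grade,
                            subtype = scored$classification$subtype)),
    inattention = list(
      board = board$targets,
      marked = inatt$marked,
      bisection_taps_mm = inatt$bisection_taps_mm,
      line_thickness_mm = as.numeric(thickness),
      score = unclass(score),
      classification = list(grade = inatt_cls$grade, side = inatt_cls$side))
  )
  class(record) <- "session_record"
  record
}

# score the perimetry arm from raw events: RT per eye, maps, classification
score_perimetry <- function(events, config = perimetry_config()) {
  maps <- list(); rt <- list()
  for (eye in unique(events$eye)) {
    ev <- events[events$eye == eye, , drop = FALSE]
    rt[[eye]] <- as.numeric(estimate_reaction_time(ev, config))
    maps[[eye]] <- build_field_map(ev, rt[[eye]], config)
  }
  cls <- classify_field(maps$left, maps$right, config)
  list(maps = maps, rt = rt, classification = cls)
}

session_required_fields <- c("schema_version", "patient_pseudo_id", "device",
                             "seeds", "config", "acuity", "perimetry",
                             "inattention")

#' Validate a session record
#'
#' @param record A `session_record` (or plain list read from JSON).
#' @return The record, invisibly; errors name every offending field.
#' @export
validate_session <- function(record) {
  missing <- setdiff(session_required_fields, names(record))
  if (length(missing) > 0) {
    stop("session record fails validation; missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(as.character(record$schema_version), SESSION_SCHEMA_VERSION)) {
    stop("unsupported schema_version: ", record$schema_version, call. = FALSE)
  }
  invisible(record)
}

#' Write / read a session record as JSON
#'
#' Round-trips losslessly at the level the scoring functions consume; unknown
#' fields present in the file are preserved on read.
#'
#' @param record A validated `session_record`.
#' @param path File path.
#' @return `read_session` returns the `session_record`.
#' @export
write_session <- function(record, path) {
  validate_session(record)
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  record <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
  validate_session(record)
  class(record) <- "session_record"
  record
}

#' Re-score a session record from its raw trial data
#'
#' Recomputes the acuity threshold (by replaying the staircase over the
#' stored trial history), the perimetry classification (from the stored
#' detection events) and the inattention classification (from the stored
#' marks and taps). Reports state both stored and recomputed values; a
#' mismatch indicates a corrupted or hand-edited record.
#'
#' @param record A `session_record`.
#' @return List with `acuity`, `perimetry` (maps, rt, classification) and
#'   `inattention` (score, classification).
#' @export
score_session <- function(record) {
  validate_session(record)
  cfg_p <- do.call(perimetry_config, record$config$perimetry)
  cfg_s <- do.call(staircase_config, record$config$staircase)
  cfg_i <- do.call(inattention_config, record$config$inattention)

  st <- staircase_new(cfg_s)
  tr <- record$acuity$trials
  for (i in seq_len(nrow(tr))) {
    st <- staircase_update(st, optotype_trial(tr$level_logmar[i],
                                              tr$true_orientation[i],
                                              tr$response_orientation[i]))
  }
  acuity <- estimate_threshold(st)

  perim <- score_perimetry(as.data.frame(record$perimetry$events), cfg_p)

  board <- cancellation_board(seed = record$seeds$board_seed)
  lines <- line_stimuli(cfg_i,
                        thickness_mm = record$inattention$line_thickness_mm)
  score <- inattention_score(board, record$inattention$marked,
                             record$inattention$bisection_taps_mm, lines)
  inatt_cls <- classify_inattention(score, cfg_i)

  list(acuity = acuity, perimetry = perim,
       inattention = list(score = score, classification = inatt_cls))
}

#' Render a human-readable session report
#'
#' Deterministic plain-text summary of one session: the three-way grades
#' with defect subtype and inattention side, the quantitative scores, and
#' the stored-versus-recomputed agreement check.
#'
#' @param record A `session_record`.
#' @return Character vector of report lines.
#' @export
render_report <- function(record) {
  validate_session(record)
  re <- score_session(record)
  fmt_num <- function(x, d = 3) ifelse(is.na(x), "NA", sprintf(paste0("%.", d, "f"), x))
  stored_grade <- record$perimetry$classification$grade
  stored_sub <- record$perimetry$classification$subtype
  lines <- c(
    sprintf("Visual screening report - session %s (schema %s)",
            record$patient_pseudo_id, record$schema_version),
    "",
    "== Acuity ==",
    if (re$acuity$gradable) {
      sprintf("Threshold: %s logMAR (%d trials, %d reversals)",
              fmt_num(re$acuity$threshold_logmar, 2), re$acuity$n_trials,
              re$acuity$n_reversals)
    } else "Threshold: non-gradable",
    "",
    "== Visual fields ==",
    sprintf("Grade: %s%s", re$perimetry$classification$grade,
            if (!is.null(re$perimetry$classification$subtype))
              paste0(" - ", re$perimetry$classification$subtype) else ""),
    sprintf("Reaction time (s): left %s, right %s",
            fmt_num(re$perimetry$rt$left), fmt_num(re$perimetry$rt$right)),
    sprintf("Stored grade agrees with recomputation: %s",
            identical(stored_grade, re$perimetry$classification$grade) &&
              identical(stored_sub, re$perimetry$classification$subtype)),
    "",
    "== Inattention ==",
    sprintf("Grade: %s%s", re$inattention$classification$grade,
            if (!is.null(re$inattention$classification$side))
              paste0(" - ", re$inattention$classification$side, "-sided") else ""),
    sprintf("Laterality index: %s", fmt_num(re$inattention$score$laterality_index)),
    sprintf("Mean bisection deviation: %s%%",
            fmt_num(re$inattention$score$mean_bisection_deviation_pct, 1)),
    sprintf("Omissions left/right: %d/%d",
            re$inattention$score$omissions_left,
            re$inattention$score$omissions_right)
  )
  lines
}
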