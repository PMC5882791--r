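#' Physical optotype height for a logMAR level
#'
#' A letter at `level_logmar` has limbs of `10^logMAR` arcmin and an overall
#' height of five limb widths, i.e. `5 * 10^logMAR` arcmin. The height is
#' computed by the exact tangent at the working distance, not the small-angle
#' approximation, so sizing stays correct at large letters and short
#' distances.
#'
#' @param level_logmar Acuity level in logMAR (0.0 is normal vision).
#' @param distance_mm Working distance in millimetres (near-test default 330).
#' @return Letter height in millimetres.
#' @examples
#' optotype_height_mm(0.0)  # ~0.480 mm at 330 mm
#' optotype_height_mm(1.0)  # ~4.80 mm
#' @export
optotype_height_mm <- function(level_logmar, distance_mm = 330) {
  stopifnot(distance_mm > 0)
  arcmin <- 5 * 10^level_logmar
  distance_mm * tan(arcmin / 60 * pi / 180)
}

#' Staircase configuration
#'
#' Parameters of the adaptive 2-down-1-up acuity staircase. The level drops
#' one step after two consecutive correct responses and rises one step after
#' any incorrect response (a missing response counts as incorrect). Stepping
#' is coarse until the second reversal, fine thereafter; the run terminates
#' after a fixed number of reversals or a trial cap, whichever comes first.
#'
#' @param start_logmar Initial presentation level.
#' @param coarse_step,fine_step Step sizes in logMAR; the fine step applies
#'   from the second reversal onward.
#' @param n_reversals_stop Terminate after this many reversals.
#' @param max_trials Hard trial cap.
#' @param floor_logmar,ceiling_logmar Clamp bounds for the presentation level.
#' @param n_reversals_average Number of final reversal levels averaged into
#'   the threshold; fewer recorded reversals makes the run non-gradable.
#' @return A list of class `staircase_config`.
#' @export
staircase_config <- function(start_logmar = 0.8, coarse_step = 0.2,
                             fine_step = 0.1, n_reversals_stop = 6L,
                             max_trials = 30L, floor_logmar = -0.3,
                             ceiling_logmar = 1.4, n_reversals_average = 4L) {
  stopifnot(coarse_step > 0, fine_step > 0, n_reversals_stop >= 2,
            max_trials >= 1, floor_logmar < ceiling_logmar,
            start_logmar >= floor_logmar, start_logmar <= ceiling_logmar)
  structure(list(start_logmar = start_logmar, coarse_step = coarse_step,
                 fine_step = fine_step, n_reversals_stop = as.integer(n_reversals_stop),
                 max_trials = as.integer(max_trials), floor_logmar = floor_logmar,
                 ceiling_logmar = ceiling_logmar,
                 n_reversals_average = as.integer(n_reversals_average)),
            class = "staircase_config")
}

#' Single tumbling-E trial record
#'
#' @param level_logmar Presentation level.
#' @param true_orientation One of `"up"`, `"down"`, `"left"`, `"right"`.
#' @param response_orientation Same domain, or `"no-response"`; a missing
#'   response is scored incorrect.
#' @return A list of class `optotype_trial` with the derived `correct` flag.
#' @export
optotype_trial <- function(level_logmar, true_orientation, response_orientation) {
  orientations <- c("up", "down", "left", "right")
  true_orientation <- match.arg(true_orientation, orientations)
  response_orientation <- match.arg(response_orientation,
                                    c(orientations, "no-response"))
  structure(list(level_logmar = level_logmar,
                 true_orientation = true_orientation,
                 response_orientation = response_orientation,
                 correct = identical(true_orientation, response_orientation)),
            class = "optotype_trial")
}

#' Initialise a staircase
#'
#' @param config A [staircase_config()].
#' @return A `staircase_state` at the starting level with empty history.
#' @export
staircase_new <- function(config = staircase_config()) {
  stopifnot(inherits(config, "staircase_config"))
  structure(
    list(config = config,
         current_level_logmar = config$start_logmar,
         step_logmar = config$coarse_step,
         trial_history = list(),
         reversal_levels = numeric(0),
         n_consecutive_correct = 0L,
         last_move = 0L,     # -1 down, +1 up, 0 none yet
         terminated = FALSE),
    class = "staircase_state"
  )
}

#' Advance the staircase by one trial
#'
#' Applies the 2-down-1-up rule: an incorrect (or absent) response moves the
#' level up one step immediately; the second consecutive correct response
#' moves it down one step. A reversal is recorded, at the level of the trial
#' on which it occurred, whenever the direction of movement changes. After
#' the second reversal the step size switches from coarse to fine. The state
#' terminates once the configured reversal count or trial cap is reached.
#'
#' @param state A non-terminated `staircase_state`.
#' @param trial An [optotype_trial()] presented at the state's current level.
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, trial) {
  stopifnot(inherits(state, "staircase_state"), inherits(trial, "optotype_trial"))
  if (state$terminated) {
    stop("staircase already terminated; no further trials accepted", call. = FALSE)
  }
  cfg <- state$config
  state$trial_history[[length(state$trial_history) + 1L]] <- trial

  move <- 0L
  if (trial$correct) {
    state$n_consecutive_correct <- state$n_consecutive_correct + 1L
    if (state$n_consecutive_correct >= 2L) {
      move <- -1L
      state$n_consecutive_correct <- 0L
    }
  } else {
    move <- 1L
    state$n_consecutive_correct <- 0L
  }

  if (move != 0L) {
    if (state$last_move != 0L && move != state$last_move) {
      state$reversal_levels <- c(state$reversal_levels, state$current_level_logmar)
      if (length(state$reversal_levels) >= 2L) state$step_logmar <- cfg$fine_step
    }
    state$last_move <- move
    state$current_level_logmar <- min(cfg$ceiling_logmar,
                                      max(cfg$floor_logmar,
                                          state$current_level_logmar +
                                            move * state$step_logmar))
  }

  if (length(state$reversal_levels) >= cfg$n_reversals_stop ||
      length(state$trial_history) >= cfg$max_trials) {
    state$terminated <- TRUE
  }
  state
}

#' Estimate the acuity threshold from a terminated staircase
#'
#' The threshold is the mean of the last `n_reversals_average` reversal
#' levels (default 4). Runs with fewer recorded reversals — e.g. a patient
#' who never produced a stable oscillation within the trial cap — are marked
#' non-gradable and carry `NA` as the threshold.
#'
#' @param state A terminated `staircase_state`.
#' @return An `acuity_result` with `threshold_logmar`, `n_trials`,
#'   `n_reversals` and `gradable`.
#' @export
estimate_threshold <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  if (!state$terminated) {
    stop("staircase has not terminated; cannot estimate threshold", call. = FALSE)
  }
  k <- state$config$n_reversals_average
  revs <- state$reversal_levels
  gradable <- length(revs) >= k
  thr <- if (gradable) mean(utils::tail(revs, k)) else NA_real_
  structure(list(threshold_logmar = thr,
                 n_trials = length(state$trial_history),
                 n_reversals = length(revs),
                 gradable = gradable),
            class = "acuity_result")
}

#' @export
print.acuity_result <- function(x, ...) {
  if (x$gradable) {
    cat(sprintf("<acuity_result> threshold %.2f logMAR (%d trials, %d reversals)\n",
                x$threshold_logmar, x$n_trials, x$n_reversals))
  } else {
    cat(sprintf("<acuity_result> non-gradable (%d trials, %d reversals)\n",
                x$n_trials, x$n_reversals))
  }
  invisible(x)
}
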