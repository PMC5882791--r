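# run code under a temporary RNG state so simulations are reproducible
# without clobbering the caller's random stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Field-defect archetypes
#'
#' Builds the pair of monocular visibility predicates for a named defect
#' archetype. All defects are homonymous (post-chiasmal): the same
#' visual-field region is unseen in both eyes. Predicates are vectorised
#' functions of `(x_deg, y_deg)` in patient-view field coordinates returning
#' `TRUE` where the stimulus is seen; the macula-sparing variant carves a
#' seen disc of the given radius out of the blind hemifield.
#'
#' @param archetype One of `"normal"`, `"hemianopia"`, `"quadrantanopia"`,
#'   `"macula-sparing hemianopia"`.
#' @param side `"left"` or `"right"` (hemianopia variants).
#' @param quadrant One of `"upper-right"`, `"upper-left"`, `"lower-left"`,
#'   `"lower-right"` (quadrantanopia).
#' @param sparing_radius_deg Radius of the spared central island.
#' @return A list with elements `left`, `right` (predicates), `label` (the
#'   expected classification subtype, or `"within normal limits"`).
#' @examples
#' fd <- make_field_defect("hemianopia", side = "left")
#' fd$left(-10, 5)  # FALSE: unseen
#' fd$left(10, 5)   # TRUE
#' @export
make_field_defect <- function(archetype = c("normal", "hemianopia",
                                            "quadrantanopia",
                                            "macula-sparing hemianopia"),
                              side = NULL, quadrant = NULL,
                              sparing_radius_deg = 5) {
  archetype <- match.arg(archetype)
  seen <- switch(
    archetype,
    "normal" = function(x, y) rep(TRUE, length(x)),
    "hemianopia" = {
      side <- match.arg(side, c("left", "right"))
      if (side == "left") function(x, y) x >= 0 else function(x, y) x <= 0
    },
    "quadrantanopia" = {
      quadrant <- match.arg(quadrant, quadrant_names)
      blind <- switch(quadrant,
                      "upper-right" = function(x, y) x > 0 & y > 0,
                      "upper-left"  = function(x, y) x < 0 & y > 0,
                      "lower-left"  = function(x, y) x < 0 & y < 0,
                      "lower-right" = function(x, y) x > 0 & y < 0)
      function(x, y) !blind(x, y)
    },
    "macula-sparing hemianopia" = {
      side <- match.arg(side, c("left", "right"))
      hemi <- if (side == "left") function(x, y) x >= 0 else function(x, y) x <= 0
      r2 <- sparing_radius_deg^2
      function(x, y) hemi(x, y) | (x^2 + y^2 <= r2)
    }
  )
  label <- switch(archetype,
                  "normal" = "within normal limits",
                  "hemianopia" = paste("homonymous hemianopia", side),
                  "quadrantanopia" = paste("homonymous quadrantanopia", quadrant),
                  "macula-sparing hemianopia" =
                    paste("macula-sparing hemianopia", side))
  list(left = seen, right = seen, label = label, archetype = archetype)
}

#' Generative model of a simulated patient
#'
#' Bundles everything needed to simulate the full battery: visibility
#' predicates per eye, a lognormal reaction-time distribution, lapse and
#' guess rates, acuity threshold, a lateralised neglect gradient, and a
#' bisection bias. Defaults are plausible psychophysics values: median RT
#' 0.5 s with lognormal sigma 0.2 (RT sd about 0.1 s), lapse 2%, guess 25%
#' (4AFC).
#'
#' @param field A [make_field_defect()] result (or any list with `left`,
#'   `right`, `label`).
#' @param acuity_logmar True acuity threshold.
#' @param rt_lognormal_mu,rt_lognormal_sigma Log-scale RT parameters.
#' @param lapse_rate,guess_rate Probabilities in `[0, 1]`.
#' @param neglect_lambda Signed gradient strength: positive = left-sided
#'   neglect (left targets missed), negative = right-sided; magnitude 1 makes
#'   the most peripheral target on the neglected side undetectable.
#' @param bisection_bias_pct Systematic bisection error, percent of
#'   half-length (positive = rightward).
#' @param motor_jitter_mm SD of bisection tap noise.
#' @param fixation_loss_rate Probability a perimetry presentation is deleted
#'   and retested.
#' @param seed Integer seed driving every simulated session of this profile.
#' @return An `observer_profile`.
#' @export
observer_profile <- function(field = make_field_defect("normal"),
                             acuity_logmar = 0.2,
                             rt_lognormal_mu = log(0.5),
                             rt_lognormal_sigma = 0.2,
                             lapse_rate = 0.02,
                             guess_rate = 0.25,
                             neglect_lambda = 0,
                             bisection_bias_pct = 0,
                             motor_jitter_mm = 1,
                             fixation_loss_rate = 0,
                             seed = 1L) {
  stopifnot(lapse_rate >= 0, lapse_rate <= 1, guess_rate >= 0, guess_rate <= 1,
            fixation_loss_rate >= 0, fixation_loss_rate <= 1,
            rt_lognormal_sigma >= 0, motor_jitter_mm >= 0)
  structure(list(field_left = field$left, field_right = field$right,
                 archetype_label = field$label,
                 acuity_logmar = acuity_logmar,
                 rt_lognormal_mu = rt_lognormal_mu,
                 rt_lognormal_sigma = rt_lognormal_sigma,
                 lapse_rate = lapse_rate, guess_rate = guess_rate,
                 neglect_lambda = neglect_lambda,
                 bisection_bias_pct = bisection_bias_pct,
                 motor_jitter_mm = motor_jitter_mm,
                 fixation_loss_rate = fixation_loss_rate,
                 seed = as.integer(seed)),
            class = "observer_profile")
}

draw_rt <- function(profile, n = 1L) {
  stats::rlnorm(n, profile$rt_lognormal_mu, profile$rt_lognormal_sigma)
}

# largest eccentricity B on the ray at which the target is seen, assuming the
# seen set along an inward ray has the form {ecc <= B}; NA when the target is
# seen only at fixation itself (or never)
entry_eccentricity <- function(seen, meridian_deg, start_ecc) {
  cm <- cos(meridian_deg * pi / 180); sm <- sin(meridian_deg * pi / 180)
  at <- function(e) seen(e * cm, e * sm)
  if (at(start_ecc)) return(start_ecc)
  eps <- 1e-9
  if (!at(eps)) return(NA_real_)
  lo <- eps; hi <- start_ecc
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (at(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Simulate one eye-by-eye kinetic perimetry session
#'
#' For every planned presentation the observer taps when the target first
#' enters the seen region, after a reaction-time latency drawn from the
#' profile's lognormal distribution — unless a lapse occurs (no tap). A
#' target whose ray never crosses into the seen region before fixation is
#' never answered. Fixation losses (at `fixation_loss_rate`) flag the event
#' deleted and insert an immediate retest, mirroring the tester's
#' swipe-to-delete. Fully seeded and reproducible.
#'
#' @param profile An [observer_profile()].
#' @param trials A [plan_trials()] plan (both eyes or one).
#' @return A detection-event data frame (see [detection_events()]).
#' @export
simulate_perimetry_session <- function(profile, trials) {
  stopifnot(inherits(profile, "observer_profile"))
  with_seed(profile$seed, {
    out <- vector("list", nrow(trials) * 2L)
    k <- 0L
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      seen <- if (tr$eye == "left") profile$field_left else profile$field_right
      B <- entry_eccentricity(seen, tr$meridian_deg, tr$start_eccentricity_deg)
      sim_once <- function() {
        if (is.na(B) || stats::runif(1) < profile$lapse_rate) return(NA_real_)
        (tr$start_eccentricity_deg - B) / tr$speed_deg_per_s + draw_rt(profile)
      }
      tap <- sim_once()
      lost <- stats::runif(1) < profile$fixation_loss_rate
      k <- k + 1L
      out[[k]] <- detection_events(tr, tap, deleted = lost)
      if (lost) { # immediate retest, kept valid
        k <- k + 1L
        out[[k]] <- detection_events(tr, sim_once(), deleted = FALSE)
      }
    }
    do.call(rbind, out[seq_len(k)])
  })
}

#' Simulate an adaptive acuity session
#'
#' Trial correctness follows the high-threshold psychometric rule
#' `P(correct) = guess + (1 - guess - lapse) * [level >= threshold]`; the
#' orientation shown is sampled uniformly over the four alternatives.
#'
#' @param profile An [observer_profile()].
#' @param config A [staircase_config()].
#' @return A terminated `staircase_state`.
#' @export
simulate_acuity_session <- function(profile, config = staircase_config()) {
  stopifnot(inherits(profile, "observer_profile"))
  orientations <- c("up", "down", "left", "right")
  with_seed(profile$seed + 1L, {
    st <- staircase_new(config)
    while (!st$terminated) {
      truth <- sample(orientations, 1)
      p <- profile$guess_rate +
        (1 - profile$guess_rate - profile$lapse_rate) *
          (st$current_level_logmar >= profile$acuity_logmar - 1e-9)
      correct <- stats::runif(1) < p
      resp <- if (correct) truth else sample(setdiff(orientations, truth), 1)
      st <- staircase_update(st, optotype_trial(st$current_level_logmar, truth, resp))
    }
    st
  })
}

#' Simulate the inattention battery
#'
#' Cancellation: each target is marked with probability
#' `(1 - lapse) * g(x)` where `g` is a clamped linear gradient on the
#' neglected side (slope `neglect_lambda`, normalised to the most peripheral
#' target) and 1 elsewhere. Bisection: the tap lands at the true centre plus
#' the systematic bias plus seeded Gaussian motor jitter.
#'
#' @param profile An [observer_profile()].
#' @param board A [cancellation_board()].
#' @param lines A [line_stimuli()] data frame.
#' @return List with `marked` (target ids) and `bisection_taps_mm` (tap
#'   offsets from line centres, `NA` for omissions).
#' @export
simulate_inattention_session <- function(profile, board = cancellation_board(),
                                         lines = line_stimuli()) {
  stopifnot(inherits(profile, "observer_profile"),
            inherits(board, "cancellation_board"))
  with_seed(profile$seed + 2L, {
    tg <- board$targets
    lam <- profile$neglect_lambda
    g <- rep(1, nrow(tg))
    if (lam > 0) { # left-sided neglect
      xmax <- max(abs(tg$x_mm[tg$side == "left"]))
      sel <- tg$side == "left"
      g[sel] <- pmin(1, pmax(0, 1 - lam * abs(tg$x_mm[sel]) / xmax))
    } else if (lam < 0) {
      xmax <- max(abs(tg$x_mm[tg$side == "right"]))
      sel <- tg$side == "right"
      g[sel] <- pmin(1, pmax(0, 1 + lam * abs(tg$x_mm[sel]) / xmax))
    }
    p <- (1 - profile$lapse_rate) * g
    marked <- tg$target_id[stats::runif(nrow(tg)) < p]
    taps <- profile$bisection_bias_pct * (lines$length_mm / 2) / 100 +
      stats::rnorm(nrow(lines), 0, profile$motor_jitter_mm)
    lapsed <- stats::runif(nrow(lines)) < profile$lapse_rate
    taps[lapsed] <- NA_real_
    list(marked = marked, bisection_taps_mm = taps)
  })
}

#' Cohort specification for test-accuracy simulation
#'
#' Each patient has a latent binary condition drawn at the stated prevalence;
#' each instrument then reports positive/negative according to its
#' truth-conditional sensitivity and specificity, or "unable" with its
#' untestable rate (drawn independently of the truth).
#'
#' @param n Number of patients.
#' @param prevalence Probability of the condition.
#' @param instruments Data frame with columns `name`, `sensitivity`,
#'   `specificity`, `untestable_rate`.
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n = 48L, prevalence = 0.40,
                        instruments = data.frame(
                          name = c("app", "confrontation", "gold"),
                          sensitivity = c(0.79, 0.79, 1.0),
                          specificity = c(0.88, 0.82, 1.0),
                          untestable_rate = c(0.04, 0.04, 0.0)),
                        seed = 1L) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1,
            all(c("name", "sensitivity", "specificity", "untestable_rate")
                %in% names(instruments)))
  structure(list(n = as.integer(n), prevalence = prevalence,
                 instruments = instruments, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a test-accuracy study cohort
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with the latent `truth` and one categorical column per
#'   instrument, levels `positive` / `negative` / `unable`.
#' @export
simulate_study_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    truth <- stats::runif(spec$n) < spec$prevalence
    out <- data.frame(truth = ifelse(truth, "positive", "negative"),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(spec$instruments))) {
      ins <- spec$instruments[i, ]
      pos_prob <- ifelse(truth, ins$sensitivity, 1 - ins$specificity)
      res <- ifelse(stats::runif(spec$n) < pos_prob, "positive", "negative")
      res[stats::runif(spec$n) < ins$untestable_rate] <- "unable"
      out[[ins$name]] <- res
    }
    out
  })
}
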