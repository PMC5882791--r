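# shared fixtures: archetype profiles and a one-call perimetry scorer

all_archetypes <- function(sparing = 5) {
  list(
    make_field_defect("normal"),
    make_field_defect("hemianopia", side = "left"),
    make_field_defect("hemianopia", side = "right"),
    make_field_defect("quadrantanopia", quadrant = "upper-right"),
    make_field_defect("quadrantanopia", quadrant = "upper-left"),
    make_field_defect("quadrantanopia", quadrant = "lower-left"),
    make_field_defect("quadrantanopia", quadrant = "lower-right"),
    make_field_defect("macula-sparing hemianopia", side = "left",
                      sparing_radius_deg = sparing),
    make_field_defect("macula-sparing hemianopia", side = "right",
                      sparing_radius_deg = sparing)
  )
}

# simulate + score one perimetry session; returns the classification
classify_simulated <- function(profile, plan = default_plan,
                               config = default_perim_config) {
  events <- simulate_perimetry_session(profile, plan)
  maps <- lapply(c(left = "left", right = "right"), function(eye) {
    ev <- events[events$eye == eye, , drop = FALSE]
    build_field_map(ev, as.numeric(estimate_reaction_time(ev, config)), config)
  })
  classify_field(maps$left, maps$right, config)
}

# grade-or-subtype string, comparable to make_field_defect()$label
classification_label <- function(cls) {
  if (is.null(cls$subtype)) cls$grade else cls$subtype
}

default_screen <- screen_spec()
default_perim_config <- perimetry_config()
default_plan <- plan_trials(default_screen, default_perim_config)

# published screening counts (app vs confrontation, fields), as shipped CSV
published_table <- function() screening_field_table()

# noiseless perimetry maps for a given archetype
maps_for <- function(field, seed = 5) {
  prof <- observer_profile(field = field, rt_lognormal_sigma = 0,
                           lapse_rate = 0, seed = seed)
  ev <- simulate_perimetry_session(prof, default_plan)
  cfg <- default_perim_config
  lapply(c(left = "left", right = "right"), function(eye) {
    e <- ev[ev$eye == eye, ]
    build_field_map(e, as.numeric(estimate_reaction_time(e, cfg)), cfg)
  })
}

# independent Clopper-Pearson oracle: direct inversion of the binomial tails
cp_oracle <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else
    stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (x == n) 1 else
    stats::uniroot(function(p) stats::pbinom(x, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}
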