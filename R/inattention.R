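#' Inattention test configuration
#'
#' Geometry of the six-line bisection screen and the cancellation board,
#' plus the classification cutoffs. The cutoffs are package defaults, not
#' normative values: in clinical use grading is adjudicated by an expert, and
#' both cutoffs are exposed precisely so they can be tuned.
#'
#' @param line_length_mm Length of each bisection line.
#' @param line_offsets_mm Signed horizontal offsets of the six line centres
#'   from the screen centre (must include both signs).
#' @param base_thickness_mm Minimum stroke thickness (floor for the
#'   acuity-calibrated scaling).
#' @param max_thickness_mm Thickness used when acuity is non-gradable.
#' @param li_cutoff Laterality-index magnitude above which cancellation is
#'   abnormal.
#' @param dev_cutoff_pct Mean bisection deviation magnitude (percent of
#'   half-length) above which bisection is abnormal.
#' @return A list of class `inattention_config`.
#' @export
inattention_config <- function(line_length_mm = 100,
                               line_offsets_mm = c(-30, 20, -10, 25, -25, 15),
                               base_thickness_mm = 0.5,
                               max_thickness_mm = 5,
                               li_cutoff = 0.14,
                               dev_cutoff_pct = 10) {
  stopifnot(length(line_offsets_mm) == 6,
            any(line_offsets_mm < 0), any(line_offsets_mm > 0),
            line_length_mm > 0, li_cutoff >= 0, dev_cutoff_pct >= 0)
  structure(list(line_length_mm = line_length_mm,
                 line_offsets_mm = line_offsets_mm,
                 base_thickness_mm = base_thickness_mm,
                 max_thickness_mm = max_thickness_mm,
                 li_cutoff = li_cutoff,
                 dev_cutoff_pct = dev_cutoff_pct),
            class = "inattention_config")
}

#' Six-line bisection stimulus set
#'
#' @param config An [inattention_config()].
#' @param thickness_mm Stroke thickness (normally from [scale_stimulus()]).
#' @return Data frame of line stimuli: `index`, `center_offset_mm`,
#'   `length_mm`, `thickness_mm`.
#' @export
line_stimuli <- function(config = inattention_config(),
                         thickness_mm = config$base_thickness_mm) {
  data.frame(index = 1:6,
             center_offset_mm = config$line_offsets_mm,
             length_mm = config$line_length_mm,
             thickness_mm = thickness_mm)
}

#' Calibrate stimulus stroke thickness against the acuity result
#'
#' So that low acuity does not preclude field or inattention testing, the
#' stroke thickness is scaled to subtend the threshold letter height —
#' `5 * 10^threshold` arcmin at the working distance — floored at the base
#' thickness. A non-gradable acuity result falls back to the configured
#' maximum thickness, flagged via attribute `acuity_fallback = TRUE`.
#'
#' @param acuity An `acuity_result` from [estimate_threshold()].
#' @param config An [inattention_config()].
#' @param distance_mm Working distance.
#' @return Thickness in millimetres (with fallback attribute when used).
#' @export
scale_stimulus <- function(acuity, config = inattention_config(),
                           distance_mm = 330) {
  stopifnot(inherits(acuity, "acuity_result"))
  if (!acuity$gradable) {
    return(structure(config$max_thickness_mm, acuity_fallback = TRUE))
  }
  structure(max(config$base_thickness_mm,
                optotype_height_mm(acuity$threshold_logmar, distance_mm)),
            acuity_fallback = FALSE)
}

#' Deviation of a bisection tap from the true centre
#'
#' Expressed as a signed percentage of the half-length: +100 is the right
#' endpoint, -100 the left. Missing taps are omissions, excluded from the
#' mean deviation.
#'
#' @param tap_x_mm Tap position relative to the line centre (mm), `NA` for no
#'   tap.
#' @param length_mm Line length.
#' @return Signed percent deviation (`NA` for an omission).
#' @export
bisection_deviation <- function(tap_x_mm, length_mm) {
  stopifnot(all(length_mm > 0))
  100 * tap_x_mm / (length_mm / 2)
}

#' Cancellation board
#'
#' A balanced board of small targets (faces) with equal counts left and right
#' of the vertical midline and none exactly on it; balance is required for
#' the laterality index to be interpretable.
#'
#' @param n_per_side Targets on each side.
#' @param width_mm,height_mm Board extent.
#' @param seed Seed for the jittered grid layout.
#' @return A `cancellation_board`: data frame of `target_id`, `x_mm`, `y_mm`,
#'   `side`, plus counts.
#' @export
cancellation_board <- function(n_per_side = 20L, width_mm = 200,
                               height_mm = 140, seed = 1L) {
  n <- 2L * n_per_side
  # jittered grid: 8 columns (4 per side) x rows as needed
  rng <- local({ set.seed(seed); list(jx = stats::runif(n, -0.3, 0.3),
                                      jy = stats::runif(n, -0.3, 0.3)) })
  ncol_side <- 4L
  nrow_grid <- ceiling(n_per_side / ncol_side)
  cell_w <- (width_mm / 2) / ncol_side
  cell_h <- height_mm / nrow_grid
  one_side <- function(sign, jxs, jys) {
    idx <- seq_len(n_per_side) - 1L
    col <- idx %% ncol_side
    row <- idx %/% ncol_side
    x <- sign * (cell_w * (col + 0.5 + jxs))
    # keep strictly off the midline
    x <- sign * pmax(abs(x), 1)
    y <- cell_h * (row + 0.5 + jys) - height_mm / 2
    data.frame(x_mm = x, y_mm = y, side = if (sign < 0) "left" else "right",
               stringsAsFactors = FALSE)
  }
  tgt <- rbind(one_side(-1, rng$jx[1:n_per_side], rng$jy[1:n_per_side]),
               one_side(+1, rng$jx[(n_per_side + 1):n], rng$jy[(n_per_side + 1):n]))
  tgt$target_id <- seq_len(nrow(tgt))
  structure(list(targets = tgt, n_left = n_per_side, n_right = n_per_side),
            class = "cancellation_board")
}

#' Laterality index of a cancellation response
#'
#' `LI = (R - L) / (R + L)` over the marked targets; positive values mean
#' left-sided omissions (fewer left marks). Undefined (`NA`) when nothing
#' was marked.
#'
#' @param board A [cancellation_board()].
#' @param marked Integer vector of marked `target_id`s.
#' @return Laterality index in `[-1, 1]`, or `NA`.
#' @export
laterality_index <- function(board, marked) {
  stopifnot(inherits(board, "cancellation_board"))
  marked <- unique(marked)
  if (length(marked) > 0 && !all(marked %in% board$targets$target_id)) {
    stop("marked ids reference unknown targets", call. = FALSE)
  }
  if (length(marked) == 0) return(NA_real_)
  side <- board$targets$side[match(marked, board$targets$target_id)]
  r <- sum(side == "right"); l <- sum(side == "left")
  (r - l) / (r + l)
}

#' Combined inattention score
#'
#' @param board A [cancellation_board()].
#' @param marked Marked target ids.
#' @param bisection_taps_mm Tap offsets from line centres (`NA` = omission),
#'   one per line.
#' @param lines A [line_stimuli()] data frame.
#' @return An `inattention_score`: `laterality_index`,
#'   `mean_bisection_deviation_pct`, omission counts, response counts.
#' @export
inattention_score <- function(board, marked, bisection_taps_mm,
                              lines = line_stimuli()) {
  li <- laterality_index(board, marked)
  devs <- bisection_deviation(bisection_taps_mm, lines$length_mm)
  mean_dev <- if (all(is.na(devs))) NA_real_ else mean(devs, na.rm = TRUE)
  side <- board$targets$side[match(unique(marked), board$targets$target_id)]
  structure(list(laterality_index = li,
                 mean_bisection_deviation_pct = mean_dev,
                 omissions_left = board$n_left - sum(side == "left"),
                 omissions_right = board$n_right - sum(side == "right"),
                 n_marked = length(unique(marked)),
                 n_bisection_responses = sum(!is.na(bisection_taps_mm))),
            class = "inattention_score")
}

#' Three-way grading of the inattention battery
#'
#' Either test suffices to flag inattention (a two-test screen maximises
#' screening sensitivity): cancellation is abnormal when `|LI|` exceeds the
#' cutoff, bisection when the mean deviation magnitude exceeds its cutoff.
#' The side is the side of the omissions (positive LI or rightward deviation
#' both indicate left-sided inattention). With no usable response on either
#' test the battery is non-gradable.
#'
#' @param score An [inattention_score()].
#' @param config An [inattention_config()].
#' @return An `inattention_classification` with `grade` and (for flagged
#'   cases) `side`.
#' @export
classify_inattention <- function(score, config = inattention_config()) {
  stopifnot(inherits(score, "inattention_score"))
  no_cancel <- score$n_marked == 0
  no_bisect <- score$n_bisection_responses == 0
  if (no_cancel && no_bisect) {
    return(structure(list(grade = "non-gradable", side = NULL),
                     class = "inattention_classification"))
  }
  li_abn <- !no_cancel && !is.na(score$laterality_index) &&
    abs(score$laterality_index) > config$li_cutoff
  dev_abn <- !no_bisect && !is.na(score$mean_bisection_deviation_pct) &&
    abs(score$mean_bisection_deviation_pct) > config$dev_cutoff_pct
  if (!li_abn && !dev_abn) {
    return(structure(list(grade = "within normal limits", side = NULL),
                     class = "inattention_classification"))
  }
  side <- if (li_abn) {
    if (score$laterality_index > 0) "left" else "right"
  } else {
    if (score$mean_bisection_deviation_pct > 0) "left" else "right"
  }
  structure(list(grade = "consistent with inattention", side = side),
            class = "inattention_classification")
}

#' @export
print.inattention_classification <- function(x, ...) {
  cat(sprintf("<inattention_classification> %s%s\n", x$grade,
              if (!is.null(x$side)) paste0(" (", x$side, "-sided)") else ""))
  invisible(x)
}
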