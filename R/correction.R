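# Kinematic label correction: post-hoc veto rules that revise a movement
# label when the back point's speed and the bout duration contradict it. The
# canonical rule relabels slow, long "sniffing" bouts as "pausing": sniffing
# at under 15 mm/s sustained for over 3 s is indistinguishable from a pause.

#' Construct a correction rule
#'
#' A rule relabels every bout of `source` whose mean back speed is strictly
#' below `max_speed_mm_s` and whose duration is strictly above
#' `min_duration_s`. Boundary cases (speed exactly at the threshold, duration
#' exactly at the threshold) are not corrected.
#'
#' @param source,target Movement names (must differ).
#' @param max_speed_mm_s Speed threshold, mm/s (> 0).
#' @param min_duration_s Duration threshold, seconds (> 0).
#' @return Object of class `correction_rule`.
#' @export
correction_rule <- function(source, max_speed_mm_s, min_duration_s, target) {
  source <- normalize_label(source); target <- normalize_label(target)
  check_movement_labels(c(source, target), where = "rule movement")
  stopifnot(max_speed_mm_s > 0, min_duration_s > 0)
  if (source == target) stop("rule source must differ from target", call. = FALSE)
  structure(list(source = source, max_speed_mm_s = max_speed_mm_s,
                 min_duration_s = min_duration_s, target = target),
            class = "correction_rule")
}

#' The default correction rule set
#'
#' Sniffing slower than 15 mm/s lasting more than 3 seconds is revised to
#' pausing.
#'
#' @return List of [correction_rule()]s.
#' @export
default_rules <- function() {
  list(correction_rule("sniffing", 15, 3, "pausing"))
}

#' Read correction rules from YAML
#'
#' The file holds a list of `{source, max_speed_mm_s, min_duration_s,
#' target}` entries.
#'
#' @param path YAML file path.
#' @return List of [correction_rule()]s.
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r)
    correction_rule(r$source, r$max_speed_mm_s, r$min_duration_s, r$target))
}

#' Smooth a trajectory with a centered moving average
#'
#' @param trajectory A [trajectory()].
#' @param window_s Window length in seconds; rounded to an odd number of
#'   frames. `0` disables smoothing. Edges use partial windows.
#' @return A [trajectory()] with smoothed coordinates.
#' @export
smooth_trajectory <- function(trajectory, window_s = 0.33) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (window_s <= 0) return(trajectory)
  k <- max(1L, 2L * floor(window_s * trajectory$frame_rate / 2) + 1L)
  if (k == 1L || trajectory$n_frames < 2L) return(trajectory)
  h <- (k - 1L) %/% 2L
  n <- trajectory$n_frames
  # centered moving average with partial windows at the edges, via the
  # cumulative sum (O(n))
  sm <- function(v) {
    cs <- c(0, cumsum(v))
    hi <- pmin(n, seq_len(n) + h)
    lo <- pmax(1L, seq_len(n) - h)
    # clamp: cumulative-sum round-off must not push wall-hugging points
    # outside the arena
    pmin(200, pmax(-200, (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)))
  }
  trajectory(sm(trajectory$x), sm(trajectory$y),
             trajectory$frame_rate, trajectory$animal_id)
}

#' Mean horizontal speed over a bout
#'
#' Mean back-point speed across the frames of a bout, computed from
#' moving-average-smoothed positions: path length within the bout divided by
#' the bout's step time. A single-frame bout has speed 0.
#'
#' @param trajectory A [trajectory()] paired with the bout's ethogram.
#' @param bout One row of [bouts_of()] (or any list with `start_frame`,
#'   `end_frame`).
#' @param smooth_window_s Smoothing window, seconds (default 0.33; 0 = raw).
#' @return Speed in mm/s.
#' @export
bout_speed <- function(trajectory, bout, smooth_window_s = 0.33) {
  sm <- smooth_trajectory(trajectory, smooth_window_s)
  idx <- (bout$start_frame + 1L):bout$end_frame  # 1-based frame rows
  if (length(idx) < 2L) return(0)
  dx <- diff(sm$x[idx]); dy <- diff(sm$y[idx])
  sum(sqrt(dx^2 + dy^2)) * trajectory$frame_rate / (length(idx) - 1L)
}

#' Apply kinematic correction rules to an ethogram
#'
#' Scans the ethogram's bouts once, in rule order: every bout matching a
#' rule's source movement with speed strictly below and duration strictly
#' above the thresholds has all its frames relabeled to the rule's target.
#' Bouts are re-derived afterwards (adjacent same-label runs merge), so the
#' operation is idempotent for the default rule set.
#'
#' @param ethogram An [ethogram()].
#' @param trajectory The paired [trajectory()] (equal length).
#' @param rules List of [correction_rule()]s; default [default_rules()].
#' @param smooth_window_s Smoothing window for [bout_speed()].
#' @return A corrected [ethogram()].
#' @export
apply_corrections <- function(ethogram, trajectory, rules = default_rules(),
                              smooth_window_s = 0.33) {
  stopifnot(inherits(ethogram, "ethogram"), inherits(trajectory, "trajectory"))
  if (ethogram$n_frames != trajectory$n_frames)
    stop("ethogram and trajectory must have equal length", call. = FALSE)
  if (!length(rules)) return(ethogram)
  lab <- as.character(ethogram$labels)
  sm <- smooth_trajectory(trajectory, smooth_window_s)
  bouts <- bouts_of(ethogram)
  for (rule in rules) {
    if (!inherits(rule, "correction_rule"))
      stop("rules must be correction_rule objects", call. = FALSE)
    for (b in seq_len(nrow(bouts))) {
      if (bouts$movement[b] != rule$source) next
      if (bouts$duration_s[b] <= rule$min_duration_s) next
      sp <- bout_speed(sm, bouts[b, ], smooth_window_s = 0)  # already smoothed
      if (sp < rule$max_speed_mm_s)
        lab[(bouts$start_frame[b] + 1L):bouts$end_frame[b]] <- rule$target
    }
  }
  ethogram(lab, ethogram$frame_rate, ethogram$animal_id)
}

#' Apply corrections across a cohort
#'
#' @param cohort A [cohort()].
#' @inheritParams apply_corrections
#' @return The [cohort()] with corrected ethograms.
#' @export
correct_cohort <- function(cohort, rules = default_rules(),
                           smooth_window_s = 0.33) {
  stopifnot(inherits(cohort, "cohort"))
  for (id in cohort$subjects$animal_id)
    cohort$ethograms[[id]] <- apply_corrections(
      cohort$ethograms[[id]], cohort$trajectories[[id]], rules,
      smooth_window_s)
  cohort
}
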