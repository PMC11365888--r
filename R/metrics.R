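# Time budgets and temporal dynamics. The session time fraction of label i
# is T_i = M_i / M_Total, where M_i counts the frames carrying label i and
# M_Total the frames of the session (or of one time bin for the binned
# profiles). "Frequency" is standardized to bouts per minute; whole-session
# bout counts are recoverable as frequency * duration_min.

#' @keywords internal
labels_for_unit <- function(unit) {
  if (unit == "movement") movements() else clusters()
}

#' @keywords internal
cluster_labels <- function(ethogram, map) {
  assert_cluster_map(map)
  unname(map[as.character(ethogram$labels)])
}

#' Session time budget
#'
#' Per-label time fractions and bout frequencies for one session, at the
#' movement level or — when a cluster map is supplied — at the cluster level
#' (frames are mapped to clusters first and bouts re-derived, so consecutive
#' bouts of same-cluster movements merge into one cluster bout).
#'
#' @param ethogram An [ethogram()].
#' @param map Optional cluster map ([cluster_map()]) for cluster-level
#'   budgets; `NULL` for movement level.
#' @return Object of class `time_budget`: list with `unit`, `fractions`
#'   (named, sums to 1) and `frequencies` (bouts per minute).
#' @export
#' @examples
#' e <- ethogram(rep(c("walking", "pausing"), each = 54000), 30)  # 30 + 30 min
#' time_budget(e)$fractions[["walking"]]  # 0.5
time_budget <- function(ethogram, map = NULL) {
  stopifnot(inherits(ethogram, "ethogram"))
  unit <- if (is.null(map)) "movement" else "cluster"
  labs <- labels_for_unit(unit)
  seq_lab <- if (is.null(map)) as.character(ethogram$labels)
             else cluster_labels(ethogram, map)
  f <- factor(seq_lab, levels = labs)
  fractions <- as.numeric(table(f)) / ethogram$n_frames
  r <- rle(seq_lab)
  counts <- as.numeric(table(factor(r$values, levels = labs)))
  structure(list(unit = unit,
                 fractions = stats::setNames(fractions, labs),
                 frequencies = stats::setNames(
                   counts / (ethogram$duration_s / 60), labs),
                 bout_counts = stats::setNames(counts, labs)),
            class = "time_budget")
}

#' Binned temporal profile
#'
#' Time fractions and bout frequencies within consecutive time bins
#' (60 s bins for the per-minute profile, 600 s for 10-minute segments).
#' Fractions are computed within each bin; a bout's count is attributed to
#' the bin containing its start frame. A trailing partial bin is dropped
#' with a warning.
#'
#' @inheritParams time_budget
#' @param bin_s Bin length in seconds (> 0).
#' @return Object of class `temporal_profile`: list with `unit`, `bin_s`,
#'   `fractions` and `frequencies` (bins x labels matrices) and
#'   `bin_frames` (frames per bin).
#' @export
temporal_profile <- function(ethogram, bin_s = 60, map = NULL) {
  stopifnot(inherits(ethogram, "ethogram"))
  if (bin_s <= 0) stop("bin_s must be positive", call. = FALSE)
  fpb <- round(bin_s * ethogram$frame_rate)
  n_bins <- ethogram$n_frames %/% fpb
  if (n_bins < 1L) stop("session shorter than one bin", call. = FALSE)
  if (n_bins * fpb < ethogram$n_frames)
    warning("dropping trailing partial bin (",
            ethogram$n_frames - n_bins * fpb, " frames)", call. = FALSE)
  unit <- if (is.null(map)) "movement" else "cluster"
  labs <- labels_for_unit(unit)
  seq_lab <- if (is.null(map)) as.character(ethogram$labels)
             else cluster_labels(ethogram, map)
  bin_of <- rep(seq_len(n_bins), each = fpb)
  used <- seq_len(n_bins * fpb)
  tab <- table(factor(bin_of, levels = seq_len(n_bins)),
               factor(seq_lab[used], levels = labs))
  fractions <- unclass(tab) / fpb
  # bout starts (on the full-session run-length encoding, restricted to
  # complete bins)
  r <- rle(seq_lab)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  in_bin <- starts <= n_bins * fpb
  bstart <- (starts[in_bin] - 1L) %/% fpb + 1L
  freq <- unclass(table(factor(bstart, levels = seq_len(n_bins)),
                        factor(r$values[in_bin], levels = labs))) / (bin_s / 60)
  dimnames(fractions) <- dimnames(freq) <- list(NULL, labs)
  structure(list(unit = unit, bin_s = bin_s, n_bins = n_bins,
                 fractions = fractions, frequencies = freq,
                 bin_frames = rep(fpb, n_bins)),
            class = "temporal_profile")
}

#' Group-averaged temporal profile
#'
#' Unweighted per-animal mean of binned fractions and frequencies over the
#' animals matching a genotype/sex selector.
#'
#' @param cohort A [cohort()].
#' @param genotype,sex Selectors (`NULL` = all).
#' @param bin_s Bin length, seconds.
#' @param map Optional cluster map for cluster-level profiles.
#' @return A `temporal_profile` whose matrices are group means, with an
#'   `n_animals` element.
#' @export
group_profile <- function(cohort, genotype = NULL, sex = NULL, bin_s = 60,
                          map = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  keep <- rep(TRUE, nrow(cohort$subjects))
  if (!is.null(genotype)) keep <- keep & cohort$subjects$genotype %in% genotype
  if (!is.null(sex)) keep <- keep & cohort$subjects$sex %in% sex
  ids <- cohort$subjects$animal_id[keep]
  if (!length(ids)) stop("no animals match the selector", call. = FALSE)
  profs <- lapply(ids, function(id)
    temporal_profile(cohort$ethograms[[id]], bin_s, map))
  out <- profs[[1]]
  out$fractions <- Reduce(`+`, lapply(profs, `[[`, "fractions")) / length(ids)
  out$frequencies <- Reduce(`+`, lapply(profs, `[[`, "frequencies")) /
    length(ids)
  out$n_animals <- length(ids)
  out
}

#' Total travel distance
#'
#' Sum of Euclidean step lengths of the (optionally smoothed) back
#' trajectory, in mm; optionally also per time bin (a step is attributed to
#' the bin of its first frame; only complete bins are reported).
#'
#' @param trajectory A [trajectory()].
#' @param smooth_window_s Moving-average window, seconds (0 = raw steps).
#' @param bin_s Optional bin length for per-segment distances.
#' @return Total distance in mm; if `bin_s` is given, a list with `total_mm`
#'   and `per_bin_mm`.
#' @export
total_distance <- function(trajectory, smooth_window_s = 0.33, bin_s = NULL) {
  stopifnot(inherits(trajectory, "trajectory"), trajectory$n_frames >= 2L)
  sm <- smooth_trajectory(trajectory, smooth_window_s)
  steps <- sqrt(diff(sm$x)^2 + diff(sm$y)^2)
  if (is.null(bin_s)) return(sum(steps))
  fpb <- round(bin_s * trajectory$frame_rate)
  n_bins <- trajectory$n_frames %/% fpb
  bin_of <- (seq_along(steps) - 1L) %/% fpb + 1L
  per_bin <- vapply(seq_len(n_bins),
                    function(b) sum(steps[bin_of == b]), numeric(1))
  list(total_mm = sum(steps), per_bin_mm = per_bin)
}

#' Long-format cohort metrics table
#'
#' Per-animal time budgets (and total distance) in a tidy table suitable for
#' export and for downstream statistics.
#'
#' @param cohort A [cohort()].
#' @param map Optional cluster map for cluster-level rows.
#' @param smooth_window_s Smoothing for the distance column.
#' @return Data.frame: `animal_id`, `genotype`, `sex`, `label`, `fraction`,
#'   `frequency`, `total_distance_mm`.
#' @export
cohort_metrics <- function(cohort, map = NULL, smooth_window_s = 0.33) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(seq_len(nrow(cohort$subjects)), function(i) {
    id <- cohort$subjects$animal_id[i]
    tb <- time_budget(cohort$ethograms[[id]], map)
    data.frame(animal_id = id,
               genotype = cohort$subjects$genotype[i],
               sex = cohort$subjects$sex[i],
               label = names(tb$fractions),
               fraction = unname(tb$fractions),
               frequency = unname(tb$frequencies),
               total_distance_mm = total_distance(
                 cohort$trajectories[[id]], smooth_window_s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
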