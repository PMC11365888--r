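# Data-driven center/perimeter division of the open-field arena. The
# occupancy growth curve counts residence frames of the back point inside a
# centered square frame of half-width a as a expands from the center to the
# wall; its annular density has a thigmotaxis peak near the wall, and the
# center/perimeter boundary is placed where the rising flank of that peak
# first comes within a stated fraction of its topographic prominence.

#' Calibrate a raw trajectory to arena coordinates
#'
#' Maps the four recorded corner points of the arena floor onto
#' `(-200,-200), (-200,200), (200,200), (200,-200)` (mm, center origin) by
#' the projective transform determined by the correspondence, and applies it
#' to every point. Corners must be supplied in that target order.
#'
#' @param x,y Raw coordinates (any units).
#' @param corners 4x2 matrix of observed corner coordinates, rows
#'   corresponding to the targets above.
#' @param frame_rate,animal_id Passed to [trajectory()].
#' @return A calibrated [trajectory()].
#' @export
calibrate <- function(x, y, corners, frame_rate = 30, animal_id = "animal") {
  corners <- as.matrix(corners)
  stopifnot(all(dim(corners) == c(4L, 2L)))
  if (anyDuplicated(corners) || abs(convex_area(corners)) < 1e-9)
    stop("corner points must be 4 distinct points forming a convex quadrilateral",
         call. = FALSE)
  target <- matrix(c(-200, -200, -200, 200, 200, 200, 200, -200),
                   ncol = 2, byrow = TRUE)
  H <- homography(corners, target)
  p <- H %*% rbind(x, y, 1)
  trajectory(p[1, ] / p[3, ], p[2, ] / p[3, ], frame_rate, animal_id)
}

# signed area via the shoelace formula (degeneracy check)
convex_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# 3x3 projective transform from 4 point correspondences (direct linear
# transform, h33 fixed to 1)
homography <- function(from, to) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- from[i, 1]; y <- from[i, 2]; u <- to[i, 1]; v <- to[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Occupancy growth curve
#'
#' For each half-width `a` on a regular grid up to 200 mm, counts the frames
#' whose back point lies in the centered square `[-a, a]^2` (Chebyshev
#' distance at most `a`), and the annular density: the increment of the
#' count between consecutive squares divided by the area of the annular
#' frame between them (frames per mm^2).
#'
#' @param trajectory A calibrated [trajectory()].
#' @param step_mm Grid step in mm (default 1).
#' @return Object of class `growth_curve`: data.frame-backed list with
#'   `a_mm`, `count`, `density`.
#' @export
growth_curve <- function(trajectory, step_mm = 1) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (step_mm <= 0) stop("step_mm must be positive", call. = FALSE)
  a_grid <- seq(step_mm, 200, by = step_mm)
  if (a_grid[length(a_grid)] < 200) a_grid <- c(a_grid, 200)
  cheb <- pmax(abs(trajectory$x), abs(trajectory$y))
  # smallest grid index k with cheb <= a_k, counted in one pass
  bin <- findInterval(cheb, a_grid, left.open = TRUE) + 1L
  counts <- cumsum(tabulate(bin, nbins = length(a_grid)))
  prev_a <- c(0, a_grid[-length(a_grid)])
  area <- (2 * a_grid)^2 - (2 * prev_a)^2
  structure(list(a_mm = a_grid, count = counts,
                 density = c(counts[1], diff(counts)) / area),
            class = "growth_curve")
}

#' Pooled growth curve over several trajectories
#'
#' @param trajectories List of calibrated [trajectory()]s.
#' @inheritParams growth_curve
#' @return A `growth_curve` of the pooled frames.
#' @export
pooled_growth_curve <- function(trajectories, step_mm = 1) {
  curves <- lapply(trajectories, growth_curve, step_mm = step_mm)
  out <- curves[[1]]
  out$count <- Reduce(`+`, lapply(curves, `[[`, "count"))
  prev_a <- c(0, out$a_mm[-length(out$a_mm)])
  out$density <- c(out$count[1], diff(out$count)) /
    ((2 * out$a_mm)^2 - (2 * prev_a)^2)
  out
}

# Topographic prominence of the local maxima of y. Plateaus collapse to
# their first index (the smallest half-width attaining the height); a
# maximum that starts at the center (index 1) is not a candidate, while a
# plateau running into the wall (the last grid point) is measured against
# its left side only. For each candidate: walk outward on each side until
# strictly higher terrain; the side's base is the minimum over that
# stretch; prominence = height - max(left base, right base).
density_peaks <- function(y) {
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vals <- r$values
  k <- length(vals)
  cand <- which(vapply(seq_len(k), function(j)
    (j > 1L && vals[j - 1L] < vals[j]) &&
      (j == k || vals[j + 1L] < vals[j]), logical(1)))
  if (!length(cand)) return(NULL)
  prom <- numeric(length(cand)); lbase <- integer(length(cand))
  for (m in seq_along(cand)) {
    j <- cand[m]; h <- vals[j]
    # left side: runs strictly between the peak and the nearest higher run
    i <- j - 1L
    while (i > 1L && vals[i] <= h) i <- i - 1L
    left_runs <- if (vals[i] > h) (i + 1L):(j - 1L) else i:(j - 1L)
    left_min <- min(vals[left_runs])
    lbase[m] <- starts[left_runs[which.min(vals[left_runs])]]
    # right side: -Inf when the peak plateau runs into the wall
    if (j == k) {
      right_min <- -Inf
    } else {
      i <- j + 1L
      while (i < k && vals[i] <= h) i <- i + 1L
      right_runs <- if (vals[i] > h) (j + 1L):(i - 1L) else (j + 1L):i
      right_min <- min(vals[right_runs])
    }
    prom[m] <- h - max(left_min, right_min)
  }
  list(idx = starts[cand], height = vals[cand], prominence = prom,
       left_base = lbase)
}

#' Locate the center/perimeter boundary on a growth curve
#'
#' Finds the most prominent peak of the annular occupancy density (the
#' thigmotaxis peak near the wall) and returns the smallest half-width `a`,
#' scanning outward from the peak's left base along its rising flank, at
#' which the density is within `prominence_fraction` of the peak height
#' (density >= height - prominence_fraction * prominence) — the starting
#' point of the (1 - prominence_fraction) prominence region.
#'
#' @param curve A [growth_curve()].
#' @param prominence_fraction Fraction of the peak prominence (default 0.10).
#' @return Boundary half-width `a` in mm, snapped to the curve's grid.
#' @export
find_boundary <- function(curve, prominence_fraction = 0.10) {
  stopifnot(inherits(curve, "growth_curve"),
            prominence_fraction > 0, prominence_fraction <= 1)
  y <- curve$density
  pk <- density_peaks(y)
  if (is.null(pk) || all(pk$prominence <= 0))
    stop("no occupancy peak; cannot divide arena", call. = FALSE)
  m <- which.max(pk$prominence)
  p <- pk$idx[m]
  thr <- pk$height[m] - prominence_fraction * pk$prominence[m]
  scan <- pk$left_base[m]:p
  hit <- scan[which(y[scan] >= thr)[1]]
  curve$a_mm[hit]
}

#' Define a center/perimeter zone division
#'
#' The center is the square `[-a, a]^2`; the perimeter is the rest of the
#' 400 x 400 mm floor. The traditional division takes the center as half the
#' arena length (a = 100 mm); the data-driven division uses a boundary found
#' on occupancy growth curves, standardized at a = 135 mm by default.
#'
#' @param method `"data_driven"` or `"traditional"`.
#' @param a_boundary Boundary length in mm; default 135 for data-driven,
#'   100 for traditional (both as half-widths).
#' @param a_semantics Whether `a_boundary` is the half-width of the center
#'   square (`"half"`, default: the square spans `[-a, a]^2`) or its full
#'   side length (`"full"`: the square spans `[-a/2, a/2]^2`).
#' @return Object of class `zone_division` with `method`, `a_boundary`
#'   (always stored as a half-width), `center_area`, `perimeter_area`
#'   (mm^2).
#' @export
zone_division <- function(method = c("data_driven", "traditional"),
                          a_boundary = NULL,
                          a_semantics = c("half", "full")) {
  method <- match.arg(method)
  a_semantics <- match.arg(a_semantics)
  if (is.null(a_boundary))
    a_boundary <- if (method == "traditional") 100 else 135
  if (a_semantics == "full") a_boundary <- a_boundary / 2
  stopifnot(a_boundary > 0, a_boundary < 200)
  structure(list(method = method, a_boundary = a_boundary,
                 center_area = (2 * a_boundary)^2,
                 perimeter_area = 400^2 - (2 * a_boundary)^2),
            class = "zone_division")
}

#' Per-frame zone labels
#'
#' A frame is in the center iff the Chebyshev distance of the back point
#' from the origin is at most the boundary half-width (boundary inclusive).
#'
#' @param trajectory A calibrated [trajectory()].
#' @param division A [zone_division()].
#' @return Character vector (`"center"`/`"perimeter"`), one per frame.
#' @export
assign_zones <- function(trajectory, division) {
  stopifnot(inherits(trajectory, "trajectory"),
            inherits(division, "zone_division"))
  ifelse(pmax(abs(trajectory$x), abs(trajectory$y)) <= division$a_boundary,
         "center", "perimeter")
}

#' Per-zone occupancy and movement budgets
#'
#' Zone time fractions, per-unit-area time fractions (fraction divided by
#' zone area, 1/mm^2), and the movement budget conditioned on each zone
#' (frame fractions renormalized within the zone; bout frequencies counted
#' by bout start frame). An unvisited zone yields an empty budget and is
#' flagged in `empty_zones`.
#'
#' @param ethogram An [ethogram()] paired with `trajectory`.
#' @param trajectory A calibrated [trajectory()].
#' @param division A [zone_division()].
#' @return List with `fractions`, `per_unit_area`, `budgets` (per-zone named
#'   fraction vectors), `frequencies` and `empty_zones`.
#' @export
zone_metrics <- function(ethogram, trajectory, division) {
  stopifnot(inherits(ethogram, "ethogram"),
            ethogram$n_frames == trajectory$n_frames)
  zone <- assign_zones(trajectory, division)
  zones <- c("center", "perimeter")
  frac <- vapply(zones, function(z) mean(zone == z), numeric(1))
  area <- c(center = division$center_area, perimeter = division$perimeter_area)
  lab <- as.character(ethogram$labels)
  budgets <- lapply(zones, function(z) {
    in_z <- zone == z
    if (!any(in_z)) return(stats::setNames(numeric(0), character(0)))
    tab <- table(factor(lab[in_z], levels = movements()))
    stats::setNames(as.numeric(tab) / sum(in_z), movements())
  })
  names(budgets) <- zones
  bouts <- bouts_of(ethogram)
  start_zone <- zone[bouts$start_frame + 1L]
  freqs <- lapply(zones, function(z) {
    tab <- table(factor(bouts$movement[start_zone == z], levels = movements()))
    stats::setNames(as.numeric(tab) / (ethogram$duration_s / 60), movements())
  })
  names(freqs) <- zones
  list(fractions = frac,
       per_unit_area = frac / area,
       budgets = budgets,
       frequencies = freqs,
       empty_zones = zones[vapply(budgets, length, 1L) == 0])
}
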