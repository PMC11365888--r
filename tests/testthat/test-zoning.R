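corners_std <- matrix(c(-200, -200, -200, 200, 200, 200, 200, -200),
                      ncol = 2, byrow = TRUE)

test_that("calibration maps recorded corners onto the standard arena", {
  x <- c(0, 50, -120); y <- c(0, -30, 80)
  # corners already standard -> identity
  t1 <- calibrate(x, y, corners_std)
  expect_equal(t1$x, x, tolerance = 1e-9)
  expect_equal(t1$y, y, tolerance = 1e-9)

  # arena recorded in cm -> uniform x10
  t2 <- calibrate(x / 10, y / 10, corners_std / 10)
  expect_equal(t2$x, x, tolerance = 1e-9)

  # translated recording: offset removed, origin maps to center.
  # oracle: the affine map is p -> p - (50, -30), solved directly from the
  # corner correspondence
  t3 <- calibrate(x + 50, y - 30, sweep(corners_std, 2, c(-50, 30), `-`))
  expect_equal(t3$x, x, tolerance = 1e-9)
  expect_equal(t3$y, y, tolerance = 1e-9)

  bad <- corners_std; bad[2, ] <- bad[1, ]
  expect_error(calibrate(x, y, bad), "distinct")
})

test_that("growth curve counts residence frames in expanding squares", {
  fps <- 30
  t0 <- trajectory(rep(0, 100), rep(0, 100), fps)
  g0 <- growth_curve(t0)
  expect_equal(g0$count, rep(100, 200))
  expect_equal(which.max(g0$density), 1L)
  expect_equal(g0$count[length(g0$count)], t0$n_frames)  # conservation

  t1 <- trajectory(150, 0, fps)
  g1 <- growth_curve(t1)
  expect_equal(g1$count[149], 0)
  expect_equal(g1$count[150], 1)

  # uniform occupancy -> near-constant density (brute-force grid of points)
  gr <- as.matrix(expand.grid(x = seq(-199.5, 199.5, by = 2),
                              y = seq(-199.5, 199.5, by = 2)))
  tu <- trajectory(gr[, 1], gr[, 2], fps)
  gu <- growth_curve(tu, step_mm = 10)
  expect_lt(stats::sd(gu$density) / mean(gu$density), 0.05)

  expect_error(growth_curve(t0, step_mm = 0), "positive")
})

# trajectory whose Chebyshev-annulus occupancy density is exactly uniform at
# mult(a) * 0.25 frames/mm^2: on a unit grid the annulus at half-width a has
# area 4(2a - 1), so mult(a) * (2a - 1) frames at radius a - 0.5 give an
# exactly flat (noise-free) density profile within each regime
step_occupancy_traj <- function(mult, step_mm = 1, fps = 30) {
  a <- seq(step_mm, 200, by = step_mm)
  counts <- mult(a) * (2 * (a / step_mm) - 1)
  trajectory(rep(a - step_mm / 2, counts), rep(0, sum(counts)), fps)
}

test_that("boundary detection finds the thigmotaxis step and ramp", {
  # sharp occupancy step at half-width 135: sparse center, dense band
  t <- step_occupancy_traj(function(a) ifelse(a <= 135, 1, 12))
  a <- find_boundary(growth_curve(t, step_mm = 1))
  expect_lte(abs(a - 135), 1)

  # ramped density: zero until 150, linear to the peak at 190, plateau to
  # the wall; the 90%-of-prominence level is crossed at 186
  h <- 5
  dens <- c(rep(0, 149), h * (seq(150, 190) - 150) / 40, rep(h, 10))
  curve <- structure(list(a_mm = 1:200, count = cumsum(dens),
                          density = dens), class = "growth_curve")
  expect_equal(find_boundary(curve), 186)

  # prominence_fraction = 1 degenerates to the peak's left base
  expect_equal(find_boundary(curve, prominence_fraction = 1), 1)

  # no peak -> explicit error
  flat <- structure(list(a_mm = 1:200, count = cumsum(rep(1, 200)),
                         density = rep(1, 200)), class = "growth_curve")
  expect_error(find_boundary(flat), "no occupancy peak")
  mono <- structure(list(a_mm = 1:200, count = cumsum(seq(200, 1)),
                         density = seq(200, 1)), class = "growth_curve")
  expect_error(find_boundary(mono), "no occupancy peak")
})

test_that("boundary detection is scale-equivariant", {
  t <- step_occupancy_traj(function(a) ifelse(a <= 140, 1, 8), step_mm = 2)
  a1 <- find_boundary(growth_curve(t, step_mm = 2))
  t2 <- trajectory(t$x / 2, t$y / 2, 30)
  a2 <- find_boundary(growth_curve(t2, step_mm = 1))
  expect_equal(a2, a1 / 2, tolerance = 2 / a1)
})

test_that("zone assignment and division geometry follow the conventions", {
  dv <- zone_division("data_driven")  # standardized 135 mm
  expect_equal(dv$a_boundary, 135)
  expect_equal(dv$center_area, 270^2)
  expect_equal(dv$center_area + dv$perimeter_area, 400^2)
  tr <- zone_division("traditional")
  expect_equal(tr$a_boundary, 100)
  # the boundary can also be given as a full side length
  full <- zone_division("data_driven", 270, a_semantics = "full")
  expect_equal(full$a_boundary, 135)

  t <- trajectory(c(0, 190, 135), c(0, 190, 0), 30)
  z <- assign_zones(t, dv)
  expect_equal(z, c("center", "perimeter", "center"))  # boundary inclusive
})

test_that("zone metrics split time, area-normalize and condition budgets", {
  fps <- 30
  dv <- zone_division("traditional")  # a = 100
  # all frames in the center
  e <- make_eth(rep("sniffing", 100), fps)
  t <- trajectory(rep(0, 100), rep(0, 100), fps)
  zm <- zone_metrics(e, t, dv)
  expect_equal(unname(zm$fractions["center"]), 1)
  expect_equal(unname(zm$per_unit_area["center"]), 1 / dv$center_area)
  expect_equal(zm$empty_zones, "perimeter")

  # 50/50 split: per-unit-area ratio = perimeter_area / center_area = 3
  e2 <- make_eth(rep(c("walking", "pausing"), each = 50), fps)
  t2 <- trajectory(c(rep(0, 50), rep(150, 50)), rep(0, 100), fps)
  zm2 <- zone_metrics(e2, t2, dv)
  expect_equal(sum(zm2$fractions), 1)
  expect_equal(unname(zm2$per_unit_area["center"] /
                        zm2$per_unit_area["perimeter"]), 3)
  # walking only in the center: absent from the perimeter budget
  expect_equal(unname(zm2$budgets$perimeter["walking"]), 0)
  expect_equal(unname(zm2$budgets$center["walking"]), 1)
  expect_equal(sum(zm2$budgets$perimeter), 1)
})
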