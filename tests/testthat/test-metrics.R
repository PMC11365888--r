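test_that("time budget fractions and bout frequencies match hand counts", {
  fps <- 10
  # 30 min walking then 30 min pausing
  e <- make_eth(rep(c("walking", "pausing"), each = 1800 * fps), fps = fps)
  tb <- time_budget(e)
  expect_equal(unname(tb$fractions["walking"]), 0.5)
  expect_equal(unname(tb$fractions["pausing"]), 0.5)
  expect_equal(unname(tb$frequencies["walking"]), 1 / 60)
  expect_equal(unname(tb$frequencies["pausing"]), 1 / 60)
  expect_equal(sum(tb$fractions), 1)

  e2 <- make_eth(rep("grooming", 600 * fps), fps = fps)
  tb2 <- time_budget(e2)
  expect_equal(unname(tb2$fractions["grooming"]), 1)
  expect_equal(unname(tb2$frequencies["grooming"]), 1 / 10)
})

test_that("cluster budgets sum member movements exactly", {
  for (seed in 1:3) {
    e <- random_session(2000, seed = seed)$ethogram
    tbm <- time_budget(e)
    tbc <- time_budget(e, cluster_map())
    map <- cluster_map()
    for (cl in clusters()) {
      members <- names(map)[map == cl]
      expect_equal(unname(tbc$fractions[cl]),
                   sum(tbm$fractions[members]), tolerance = 1e-12)
    }
    expect_equal(sum(tbc$fractions), 1)
    # merged cluster bouts can never outnumber movement bouts
    expect_lte(sum(tbc$bout_counts), sum(tbm$bout_counts))
  }
})

test_that("temporal profile bins fractions and bout starts", {
  fps <- 5
  e <- make_eth(rep("pausing", 3600 * fps), fps = fps)
  p <- temporal_profile(e, bin_s = 60)
  expect_equal(p$n_bins, 60L)
  expect_equal(unname(p$fractions[, "pausing"]), rep(1, 60))
  expect_equal(rowSums(p$fractions), rep(1, 60))

  # walking minutes 1-30, pausing 31-60; 10-min segments
  e2 <- make_eth(rep(c("walking", "pausing"), each = 1800 * fps), fps = fps)
  p2 <- temporal_profile(e2, bin_s = 600)
  expect_equal(unname(p2$fractions[, "walking"]), c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(p2$fractions[, "pausing"]), c(0, 0, 0, 1, 1, 1))

  expect_error(temporal_profile(e, bin_s = 0), "positive")
  expect_warning(temporal_profile(make_eth(rep("walking", 70), fps = 1),
                                  bin_s = 60), "partial bin")
})

test_that("bin-weighted fraction averages reproduce whole-session fractions", {
  fps <- 10
  e <- random_session(1200 * fps, fps = fps, seed = 9)$ethogram  # 20 min
  p <- temporal_profile(e, bin_s = 60)
  # equal-length bins: the frame-weighted mean is the plain mean
  recovered <- colMeans(p$fractions)
  whole <- time_budget(e)$fractions
  expect_equal(recovered, whole[colnames(p$fractions)], tolerance = 1e-12)
  # brute-force recount of one bin
  bin3 <- as.character(e$labels)[(2 * 600 + 1):(3 * 600)]
  expect_equal(unname(p$fractions[3, "sniffing"]),
               mean(bin3 == "sniffing"))
})

test_that("group profiles average animals without weighting", {
  fps <- 5
  e1 <- make_eth(rep(c("walking", "pausing"), c(120 * fps, 480 * fps)),
                 fps = fps, id = "a1")
  e2 <- make_eth(rep(c("walking", "pausing"), c(240 * fps, 360 * fps)),
                 fps = fps, id = "a2")
  t <- trajectory(rep(0, 600 * fps), rep(0, 600 * fps), fps)
  co <- cohort(data.frame(animal_id = c("a1", "a2"),
                          genotype = c("WT", "WT"), sex = c("M", "M")),
               list(a1 = e1, a2 = e2), list(a1 = t, a2 = t))
  g <- group_profile(co, genotype = "WT", bin_s = 600)
  expect_equal(g$n_animals, 2L)
  expect_equal(unname(g$fractions[1, "walking"]), 0.3)  # mean of 0.2, 0.4
  single <- group_profile(co, genotype = "WT", bin_s = 600, sex = "M")
  expect_equal(dim(single$fractions), dim(g$fractions))
  expect_error(group_profile(co, genotype = "KO"), "no animals")
})

test_that("travel distance matches closed forms and symmetries", {
  # straight path in uniform steps
  t <- trajectory(seq(0, 100, length.out = 11), rep(0, 11), 30)
  expect_equal(total_distance(t, smooth_window_s = 0), 100)

  t0 <- trajectory(rep(3, 50), rep(-7, 50), 30)
  expect_equal(total_distance(t0, smooth_window_s = 0), 0)

  # circle of radius r sampled at n points: n * 2r * sin(pi/n)
  r <- 80
  for (n in c(12, 60, 360)) {
    th <- 2 * pi * seq_len(n + 1) / n
    tc <- trajectory(r * cos(th), r * sin(th), 30)
    expect_equal(total_distance(tc, smooth_window_s = 0),
                 n * 2 * r * sin(pi / n), tolerance = 1e-9)
  }

  # rigid rotation invariance
  set.seed(4)
  x <- cumsum(rnorm(200)); y <- cumsum(rnorm(200))
  a <- 0.7
  tr <- trajectory(x, y, 30)
  trot <- trajectory(cos(a) * x - sin(a) * y, sin(a) * x + cos(a) * y, 30)
  expect_equal(total_distance(trot, 0), total_distance(tr, 0),
               tolerance = 1e-9)

  # additivity under concatenation (shared junction point)
  t1 <- trajectory(x[1:100], y[1:100], 30)
  t2 <- trajectory(x[100:200], y[100:200], 30)
  expect_equal(total_distance(t1, 0) + total_distance(t2, 0),
               total_distance(tr, 0), tolerance = 1e-9)

  # per-bin distances sum to the total over complete bins
  d <- total_distance(trajectory(x, y, frame_rate = 1), 0, bin_s = 50)
  expect_equal(sum(d$per_bin_mm), d$total_mm, tolerance = 1e-9)
})

test_that("cohort metrics table is tidy and consistent", {
  co <- simulate_cohort(cohort_design(
    sizes = data.frame(genotype = c("WT", "KO"), sex = "M", n = c(2L, 2L)),
    duration_s = 30, seed = 1))
  tab <- cohort_metrics(co)
  expect_equal(nrow(tab), 4L * 13L)
  expect_equal(sort(unique(tab$label)), sort(movements()))
  agg <- tapply(tab$fraction, tab$animal_id, sum)
  expect_equal(as.numeric(agg), rep(1, 4), tolerance = 1e-9)
})
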