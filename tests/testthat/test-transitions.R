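test_that("cluster events merge same-cluster movement runs", {
  e <- make_eth(c(rep("walking", 5), rep("stepping", 3), rep("grooming", 4)))
  ev <- to_events(e)
  expect_equal(ev$cluster, c("locomotion", "maintenance"))
  expect_equal(ev$start_frame, c(0L, 8L))
  expect_equal(ev$end_frame, c(8L, 12L))

  expect_equal(to_events(make_eth(rep("pausing", 9)))$cluster, "nap")

  alt <- make_eth(rep(c(rep("walking", 3), rep("rearing", 2)), 4))
  expect_equal(to_events(alt)$cluster,
               rep(c("locomotion", "exploration"), 4))

  # events can never outnumber movement bouts
  for (seed in 1:3) {
    e <- random_session(1000, seed = seed)$ethogram
    expect_lte(nrow(to_events(e)), nrow(bouts_of(e)))
  }
})

test_that("transition graph counts states, transitions and self-loops", {
  ev <- event_sequence(c("locomotion", "exploration", "locomotion"))
  tg <- transition_graph(ev)
  expect_equal(unname(tg$state_prob["locomotion"]), 2 / 3)
  expect_equal(unname(tg$state_prob["exploration"]), 1 / 3)
  expect_equal(sum(tg$state_prob), 1)
  expect_equal(unname(tg$trans_prob["locomotion", "exploration"]), 1)
  expect_equal(unname(tg$trans_prob["exploration", "locomotion"]), 1)
  # observed rows sum to 1
  rs <- rowSums(tg$trans_prob, na.rm = FALSE)
  expect_equal(unname(rs[!is.na(rs)]), rep(1, 2))

  # single event: state probabilities still defined, transitions flagged
  expect_warning(tg1 <- transition_graph(event_sequence("nap")),
                 "single event")
  expect_equal(unname(tg1$state_prob["nap"]), 1)

  # movement-level self-transitions within a cluster
  e <- make_eth(c(rep("walking", 3), rep("stepping", 3), rep("rearing", 3)))
  tg2 <- transition_graph(to_events(e), bouts_of(e))
  # walking->stepping is a locomotion self-transition; stepping->rearing
  # leaves locomotion
  expect_equal(unname(tg2$self_loop["locomotion"]), 0.5)
})

test_that("pruning drops transition probabilities below the threshold", {
  # 100 transitions out of locomotion: 4 to exploration (0.04),
  # 5 to forced_posture (0.05), 91 to nap (0.91)
  ev <- c(rbind(rep("locomotion", 100),
                c(rep("exploration", 4), rep("forced_posture", 5),
                  rep("nap", 91))))
  tg <- transition_graph(event_sequence(ev, seq_along(ev) - 1L,
                                        seq_along(ev)))
  expect_equal(unname(tg$trans_prob["locomotion", "exploration"]), 0.04)
  pe <- tg$pruned_edges
  expect_false(any(pe$from == "locomotion" & pe$to == "exploration"))
  expect_true(any(pe$from == "locomotion" & pe$to == "forced_posture"))
  expect_true(all(pe$probability >= 0.05))
  # pruning never alters the stored matrix
  expect_equal(sum(tg$trans_prob["locomotion", ]), 1)
})

test_that("estimated transition matrices converge with event count", {
  P <- test_chain()
  err <- sapply(c(500, 5000), function(n) {
    ev <- simulate_markov_events(P, n, seed = 13)
    tg <- transition_graph(event_sequence(ev, seq_along(ev) - 1L,
                                          seq_along(ev)))
    max(abs(tg$trans_prob - P))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("betweenness centrality matches hand-enumerated path counts", {
  # directed path A -> B -> C: only B lies on a shortest path (A to C);
  # normalized by (n-1)(n-2) = 2 -> B = 0.5
  edges <- data.frame(from = c("locomotion", "exploration"),
                      to = c("exploration", "nap"),
                      probability = c(1, 1))
  b <- betweenness_centrality(edges,
                              states = c("locomotion", "exploration", "nap"))
  expect_equal(unname(b["exploration"]), 0.5)
  expect_equal(unname(b[c("locomotion", "nap")]), c(0, 0))

  # 5-node star through the hub: all 12 ordered leaf pairs route through
  # it -> hub = 12 / ((5-1)(5-2)) = 1, leaves = 0
  st <- clusters()
  leaves <- setdiff(st, "locomotion")
  star <- data.frame(from = c(rep("locomotion", 4), leaves),
                     to = c(leaves, rep("locomotion", 4)),
                     probability = 0.25)
  bs <- betweenness_centrality(star, states = st)
  expect_equal(unname(bs["locomotion"]), 1)
  expect_equal(unname(bs[leaves]), rep(0, 4))

  # complete symmetric graph: no pair needs an intermediary
  cmpl <- expand.grid(from = st, to = st, stringsAsFactors = FALSE)
  cmpl <- cmpl[cmpl$from != cmpl$to, ]
  cmpl$probability <- 0.25
  bc <- betweenness_centrality(cmpl, states = st)
  expect_equal(unname(bc), rep(0, 5))
})

test_that("half-session similarity behaves as a correlation", {
  fps <- 10
  half <- c(rep("walking", 100), rep("sniffing", 60), rep("grooming", 40))
  e <- ethogram(c(half, half), fps)
  expect_equal(half_similarity(e, split_s = 20), 1)

  # disjoint one-hot halves: oracle = direct Pearson formula on the two
  # 13-long fraction vectors
  e2 <- ethogram(c(rep("walking", 200), rep("pausing", 200)), fps)
  a <- as.numeric(movements() == "walking")
  b <- as.numeric(movements() == "pausing")
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  s2 <- half_similarity(e2, split_s = 20)
  expect_lt(s2, 0)
  expect_equal(s2, oracle)

  # constant behavior in both halves -> similarity 1 regardless of label
  e3 <- ethogram(rep("grooming", 400), fps)
  expect_equal(half_similarity(e3, split_s = 20), 1)

  # uniform occupancy of all 13 movements has zero variance -> undefined
  e4 <- ethogram(rep(rep(movements(), each = 10), 2), fps)
  expect_warning(s4 <- half_similarity(e4, split_s = 13), "zero-variance")
  expect_true(is.na(s4))

  expect_error(half_similarity(e2, split_s = 40), "longer than")

  # cluster-level and cosine variants stay in range
  e5 <- random_session(1200, seed = 3)$ethogram
  expect_gte(half_similarity(e5, cluster_map(), split_s = 20), -1)
  expect_lte(half_similarity(e5, split_s = 20, method = "cosine"), 1)
})

test_that("group similarity matrices cross animals and timeframes", {
  fps <- 10
  half <- c(rep("walking", 100), rep("sniffing", 60), rep("grooming", 40))
  e1 <- ethogram(c(half, half), fps, "a1")
  e2 <- ethogram(c(half, half), fps, "a2")
  t <- trajectory(rep(0, 400), rep(0, 400), fps)
  co <- cohort(data.frame(animal_id = c("a1", "a2"), genotype = "WT",
                          sex = "M"),
               list(a1 = e1, a2 = e2), list(a1 = t, a2 = t))
  g <- group_half_similarity(co, split_s = 20)
  expect_equal(dim(g$matrix), c(2L, 2L))
  # identical sessions: every cross-pair is a perfect correlation
  expect_equal(unname(g$matrix), matrix(1, 2, 2))
  expect_equal(g$mean, 1)
  expect_equal(unname(g$per_animal["a1"]), half_similarity(e1, split_s = 20))
})

test_that("group transition graphs average or pool per-animal estimates", {
  co <- simulate_cohort(cohort_design(
    sizes = data.frame(genotype = c("WT", "KO"), sex = "M", n = c(3L, 3L)),
    duration_s = 120, seed = 4))
  g1 <- group_transition_graph(co, genotype = "WT", pool = "animals")
  g2 <- group_transition_graph(co, genotype = "WT", pool = "events")
  expect_equal(sum(g1$state_prob), 1)
  expect_equal(sum(g2$state_prob), 1)
  expect_equal(g1$n_animals, 3L)
  rs <- rowSums(g2$trans_prob)
  expect_equal(unname(rs[!is.na(rs)]), rep(1, sum(!is.na(rs))),
               tolerance = 1e-9)
  expect_error(group_transition_graph(co, genotype = "HE"), "no animals")

  # restricting to a window shortens the event record
  g3 <- group_transition_graph(co, genotype = "WT", window_s = c(0, 60))
  expect_lt(g3$n_events, g1$n_events)
})
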