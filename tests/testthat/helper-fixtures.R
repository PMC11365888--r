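# Shared fixtures built in code: small ethograms/trajectories with known
# structure, and a straight-line trajectory generator for speed fixtures.

make_eth <- function(labels, fps = 30, id = "a1") {
  ethogram(labels, frame_rate = fps, animal_id = id)
}

# trajectory moving at a constant speed (mm/s) along +x, starting at x0
straight_traj <- function(n, speed_mm_s, fps = 30, x0 = -190, y = 0,
                          id = "a1") {
  step <- speed_mm_s / fps
  trajectory(x0 + step * (seq_len(n) - 1L), rep(y, n), frame_rate = fps,
             animal_id = id)
}

# random ethogram + matching random in-arena trajectory, for property tests
random_session <- function(n, fps = 30, seed = 1) {
  set.seed(seed)
  lab <- sample(movements(), n, replace = TRUE,
                prob = c(1, 1, 4, 2, 2, 3, 2, 1, 1, 1, 5, 2, 3))
  e <- ethogram(lab, fps)
  t <- trajectory(cumsum(rnorm(n, 0, 2)) %% 150 - 75,
                  cumsum(rnorm(n, 0, 2)) %% 150 - 75, fps)
  list(ethogram = e, trajectory = t)
}

# a small 5-state zero-diagonal row-stochastic matrix over the clusters
test_chain <- function() {
  st <- clusters()
  P <- matrix(c(0.0, 0.4, 0.2, 0.2, 0.2,
                0.5, 0.0, 0.1, 0.2, 0.2,
                0.3, 0.3, 0.0, 0.2, 0.2,
                0.2, 0.2, 0.2, 0.0, 0.4,
                0.1, 0.2, 0.3, 0.4, 0.0),
              5, 5, byrow = TRUE, dimnames = list(st, st))
  P
}

# feature table with 3 Gaussian classes; `informative` columns of the
# KO/HE means are shifted by `shift` within-class SDs
gaussian_features <- function(n_per_class = 15, p = 26, informative = 4,
                              shift = 10, seed = 1, sd = 1) {
  set.seed(seed)
  lev <- c("WT", "HE", "KO")
  X <- matrix(rnorm(3 * n_per_class * p, sd = sd), 3 * n_per_class, p)
  y <- rep(lev, each = n_per_class)
  if (informative > 0) {
    cols <- seq_len(informative)
    X[y == "HE", cols] <- X[y == "HE", cols] + shift * sd
    X[y == "KO", cols] <- X[y == "KO", cols] + 2 * shift * sd
  }
  colnames(X) <- paste0("f", seq_len(p))
  structure(cbind(data.frame(animal_id = sprintf("m%02d", seq_along(y)),
                             genotype = y, sex = "M",
                             stringsAsFactors = FALSE),
                  as.data.frame(X)),
            feature_set = "synthetic",
            class = c("feature_table", "data.frame"))
}
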