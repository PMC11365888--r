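# Synthetic cohorts: a semi-Markov bout process for the ethogram paired with
# a target-seeking random walk for the back trajectory. The generator is a
# stand-in for real recordings: it reproduces the qualitative genotype/sex
# structure the analyses assume (orderings of time budgets, transition
# coupling, thigmotaxis), not any particular animal's dynamics.

#' Construct a behavior model
#'
#' Parameters of the semi-Markov generative model for one genotype-by-sex
#' group: a bout-to-bout movement transition chain, lognormal bout dwell
#' times, per-movement locomotion speeds, and spatial preference parameters
#' controlling thigmotaxis.
#'
#' @param transition 13x13 row-stochastic matrix with zero diagonal
#'   (probability that a bout of movement i is followed by a bout of j).
#'   Rows/columns ordered as [movements()].
#' @param dwell_meanlog,dwell_sdlog Per-movement lognormal parameters of bout
#'   duration in seconds (log scale), named by movement.
#' @param speed_mm_s Per-movement mean horizontal speed of the back point
#'   (mm/s), named by movement.
#' @param wall_affinity Probability that a bout's spatial attractor lies in
#'   the perimeter band rather than the center region; the long-run fraction
#'   of occupancy near the walls increases with it.
#' @param center_halfwidth_mm Half-width of the preferred central square for
#'   non-wall bouts (mm).
#' @param wall_ring_mm Chebyshev radius of the wall attractor ring (mm).
#' @return Object of class `behavior_model`.
#' @export
behavior_model <- function(transition, dwell_meanlog, dwell_sdlog,
                           speed_mm_s, wall_affinity,
                           center_halfwidth_mm = 100, wall_ring_mm = 170) {
  mv <- movements()
  transition <- as.matrix(transition)
  stopifnot(all(dim(transition) == c(13L, 13L)))
  dimnames(transition) <- list(mv, mv)
  if (any(abs(diag(transition)) > 1e-12))
    stop("transition matrix must have zero diagonal (bout-to-bout chain)",
         call. = FALSE)
  rs <- rowSums(transition)
  if (any(abs(rs - 1) > 1e-9))
    stop("transition rows must sum to 1", call. = FALSE)
  stopifnot(all(dwell_sdlog[mv] >= 0), all(speed_mm_s[mv] >= 0),
            wall_affinity >= 0, wall_affinity <= 1,
            center_halfwidth_mm > 0, center_halfwidth_mm < 200,
            wall_ring_mm > 0, wall_ring_mm < 200)
  structure(list(transition = transition,
                 dwell_meanlog = dwell_meanlog[mv],
                 dwell_sdlog = dwell_sdlog[mv],
                 speed_mm_s = speed_mm_s[mv],
                 wall_affinity = wall_affinity,
                 center_halfwidth_mm = center_halfwidth_mm,
                 wall_ring_mm = wall_ring_mm),
            class = "behavior_model")
}

#' @export
print.behavior_model <- function(x, ...) {
  sf <- stationary_budget(x)
  cat(sprintf("<behavior_model> wall_affinity=%.2f; top movements: %s\n",
              x$wall_affinity,
              paste(names(sort(sf, decreasing = TRUE))[1:3], collapse = ", ")))
  invisible(x)
}

# Base parameters of the wild-type model: relative bout propensities, mean
# bout durations (s) and mean speeds (mm/s) per movement. Values are chosen
# as realistic for a mouse in a 40 cm open field (bouts of order 1 s, long
# grooming/pausing bouts, gait speeds from ~40 mm/s stepping to ~250 mm/s
# running); they are stand-ins, not measurements.
base_behavior_params <- function() {
  mv <- movements()
  w <- c(running = 0.04, trotting = 0.06, walking = 0.14,
         right_turning = 0.08, left_turning = 0.08, stepping = 0.10,
         rearing = 0.07, climbing = 0.05, rising = 0.06, sniffing = 0.16,
         hunching = 0.04, grooming = 0.05, pausing = 0.07)
  dwell <- c(running = 1.0, trotting = 1.2, walking = 1.5,
             right_turning = 0.8, left_turning = 0.8, stepping = 0.9,
             rearing = 1.5, climbing = 2.0, rising = 1.0, sniffing = 2.0,
             hunching = 2.0, grooming = 4.0, pausing = 3.0)
  speed <- c(running = 250, trotting = 150, walking = 80,
             right_turning = 30, left_turning = 30, stepping = 40,
             rearing = 10, climbing = 15, rising = 8, sniffing = 20,
             hunching = 5, grooming = 4, pausing = 4)
  list(weights = w[mv], dwell_mean = dwell[mv], speed = speed[mv])
}

# Build a zero-diagonal row-stochastic transition matrix from bout
# propensities, with an explicit grooming<->pausing coupling factor that
# scales the maintenance<->nap exchange before renormalization.
propensity_transition <- function(weights, mn_coupling = 1) {
  mv <- names(weights)
  P <- matrix(rep(weights, each = length(weights)), nrow = length(weights),
              dimnames = list(mv, mv))
  diag(P) <- 0
  P["grooming", "pausing"] <- P["grooming", "pausing"] * mn_coupling
  P["pausing", "grooming"] <- P["pausing", "grooming"] * mn_coupling
  P / rowSums(P)
}

#' Default genotype-by-sex behavior models
#'
#' Six [behavior_model()]s (WT/HE/KO crossed with M/F) engineered so that,
#' relative to same-sex wild types, heterozygous and knockout groups have
#' reduced walking/stepping/trotting/turning/climbing/rising/sniffing bout
#' mass, elevated pausing/grooming/hunching mass and dwell, stronger
#' grooming-pausing (maintenance-nap) coupling, and higher wall affinity —
#' knockouts more extreme than heterozygotes. Sex effects are deliberately
#' mild and do not reverse any genotype ordering.
#'
#' @return Named list `WT_M`, `HE_M`, `KO_M`, `WT_F`, `HE_F`, `KO_F`.
#' @export
#' @examples
#' m <- default_models()
#' stationary_budget(m$KO_M)[["grooming"]] > stationary_budget(m$WT_M)[["grooming"]]
default_models <- function() {
  base <- base_behavior_params()
  geno_w <- list(
    WT = NULL,
    HE = c(walking = 0.80, stepping = 0.80, trotting = 0.85,
           right_turning = 0.85, climbing = 0.85, rising = 0.85,
           sniffing = 0.90, pausing = 1.25, grooming = 1.35, hunching = 1.15),
    KO = c(walking = 0.55, stepping = 0.60, trotting = 0.65,
           right_turning = 0.65, climbing = 0.65, rising = 0.70,
           sniffing = 0.75, pausing = 1.60, grooming = 1.90, hunching = 1.40))
  geno_dwell <- list(WT = NULL,
                     HE = c(grooming = 1.15, pausing = 1.10),
                     KO = c(grooming = 1.40, pausing = 1.25))
  coupling <- c(WT = 1.0, HE = 1.6, KO = 2.6)
  wall <- c(WT = 0.74, HE = 0.82, KO = 0.90)
  sdlog <- 0.6  # common lognormal shape; right-skewed bout durations

  out <- list()
  for (sex in c("M", "F")) {
    for (g in c("WT", "HE", "KO")) {
      w <- base$weights
      if (!is.null(geno_w[[g]])) w[names(geno_w[[g]])] <-
          w[names(geno_w[[g]])] * geno_w[[g]]
      dm <- base$dwell_mean
      if (!is.null(geno_dwell[[g]])) dm[names(geno_dwell[[g]])] <-
          dm[names(geno_dwell[[g]])] * geno_dwell[[g]]
      sp <- base$speed
      if (sex == "F") {  # mild, order-preserving sex effect
        sp <- sp * 0.97
        w[["sniffing"]] <- w[["sniffing"]] * 1.03
      }
      out[[paste(g, sex, sep = "_")]] <- behavior_model(
        transition = propensity_transition(w / sum(w), coupling[[g]]),
        dwell_meanlog = log(dm) - sdlog^2 / 2,  # so E[dwell] = dm
        dwell_sdlog = stats::setNames(rep(sdlog, 13), movements()),
        speed_mm_s = sp,
        wall_affinity = wall[[g]])
    }
  }
  out
}

#' Closed-form stationary time budget of a behavior model
#'
#' The embedded bout chain has stationary distribution `pi` (left eigenvector
#' of the transition matrix); the long-run fraction of session time spent in
#' movement i under the semi-Markov process is
#' `pi_i * E[dwell_i] / sum_j pi_j * E[dwell_j]`.
#'
#' @param model A [behavior_model()].
#' @return Named numeric vector of expected time fractions (sums to 1).
#' @export
stationary_budget <- function(model) {
  pi <- chain_stationary(model$transition)
  mean_dwell <- exp(model$dwell_meanlog + model$dwell_sdlog^2 / 2)
  f <- pi * mean_dwell
  f / sum(f)
}

#' Stationary distribution of a finite Markov chain
#'
#' Left eigenvector of a row-stochastic matrix, normalized to sum to 1.
#'
#' @param P Row-stochastic matrix.
#' @return Named numeric vector.
#' @export
chain_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(P))
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample an event chain
#'
#' Draws `n` consecutive states from a finite row-stochastic transition
#' chain, starting from its stationary distribution. Used both by the
#' session simulator and as a generic fixture for transition-estimation
#' checks.
#'
#' @param P Row-stochastic transition matrix with named rows/columns.
#' @param n Number of events.
#' @param seed Integer RNG seed.
#' @return Character vector of `n` state names.
#' @export
simulate_markov_events <- function(P, n, seed) {
  states <- rownames(P)
  with_seed(seed, {
    idx <- integer(n)
    idx[1] <- sample.int(nrow(P), 1, prob = pmax(chain_stationary(P), 0))
    for (k in seq_len(n - 1L))
      idx[k + 1L] <- sample.int(nrow(P), 1, prob = P[idx[k], ])
    states[idx]
  })
}

# Sample the bout process (movement sequence + continuous dwell seconds)
# until either n_bouts bouts or total dwell >= duration_s. RNG state is the
# caller's responsibility.
sample_bouts <- function(model, n_bouts = NULL, duration_s = NULL) {
  P <- model$transition
  pi0 <- pmax(chain_stationary(P), 0)
  cap <- n_bouts %||%
    max(64L, ceiling(4 * duration_s /
                       exp(min(model$dwell_meanlog))))
  mv_idx <- integer(cap); dw <- numeric(cap)
  cur <- sample.int(13L, 1, prob = pi0)
  total <- 0; k <- 0L
  repeat {
    if (!is.null(n_bouts) && k >= n_bouts) break
    if (!is.null(duration_s) && total >= duration_s) break
    if (k >= cap) break
    k <- k + 1L
    mv_idx[k] <- cur
    d <- stats::rlnorm(1, model$dwell_meanlog[cur], model$dwell_sdlog[cur])
    dw[k] <- d
    total <- total + d
    cur <- sample.int(13L, 1, prob = P[cur, ])
  }
  data.frame(movement = movements()[mv_idx[seq_len(k)]],
             dwell_s = dw[seq_len(k)], stringsAsFactors = FALSE)
}

# Fold real coordinates into [-200, 200] as specular reflection at the walls
# (triangle wave of period 800 mm).
reflect_arena <- function(v) {
  u <- (v + 200) %% 800
  ifelse(u <= 400, u, 800 - u) - 200
}

#' Simulate one open-field session
#'
#' Generates a paired ethogram and back trajectory from a
#' [behavior_model()]. The ethogram is a semi-Markov bout process: movements
#' follow the model's bout-to-bout transition chain and dwell times are
#' lognormal, truncated at the session end (every bout occupies at least one
#' frame). The trajectory is a target-seeking random walk: each bout draws a
#' spatial attractor — with probability `wall_affinity` a point on the wall
#' ring, otherwise a point in the central square — and the back point travels
#' toward it at the movement's mean speed with isotropic jitter, reflecting
#' off the walls, then dwells near the attractor.
#'
#' @param model A [behavior_model()].
#' @param duration_s Session length in seconds (default 3600).
#' @param frame_rate Frames per second (default 30).
#' @param seed Integer seed; identical seeds give identical output.
#' @param animal_id Identifier for the generated animal.
#' @return List with elements `ethogram` and `trajectory`.
#' @export
#' @examples
#' s <- simulate_session(default_models()$WT_M, duration_s = 30, seed = 1)
#' s$ethogram$n_frames  # 900
simulate_session <- function(model, duration_s = 3600, frame_rate = 30,
                             seed = 1, animal_id = "animal") {
  stopifnot(duration_s > 0)
  n_frames <- round(duration_s * frame_rate)
  with_seed(seed, {
    bouts <- sample_bouts(model, duration_s = duration_s + 1)
    frames <- pmax(1L, as.integer(round(bouts$dwell_s * frame_rate)))
    # truncate the bout list at the session end
    keep <- which(cumsum(frames) >= n_frames)[1]
    if (is.na(keep)) { # dwell rounding fell short; pad the last bout
      keep <- nrow(bouts)
      frames[keep] <- frames[keep] + (n_frames - sum(frames))
    }
    frames <- frames[seq_len(keep)]
    frames[keep] <- frames[keep] - (sum(frames) - n_frames)
    mv <- bouts$movement[seq_len(keep)]
    nz <- frames > 0L
    labels <- rep(mv[nz], frames[nz])

    # trajectory: a spatial attractor (wall band with probability
    # wall_affinity, else center region) persists until the animal reaches
    # it — travel toward it proceeds at each movement's speed, so slow bouts
    # only creep — and is redrawn with a fixed per-bout probability once
    # reached. While dwelling, the attractor itself drifts slowly, so
    # residence mass spreads into a blob rather than a point, and the
    # deviation around it is AR(1) with innovation equal to the per-frame
    # step, keeping apparent speeds near the movement's nominal speed.
    step <- model$speed_mm_s[mv] / frame_rate
    pos <- stats::runif(2, -150, 150)
    target <- pos
    redraw_p <- 0.08; phi <- 0.97; arrive_mm <- 20
    xs <- vector("list", sum(nz)); ys <- xs
    bi <- 0L
    first <- TRUE
    arrived <- TRUE
    for (b in which(nz)) {
      bi <- bi + 1L
      n <- frames[b]
      st <- step[b]
      if (first || (arrived && stats::runif(1) < redraw_p)) {
        first <- FALSE
        arrived <- FALSE
        if (stats::runif(1) < model$wall_affinity) {
          r <- stats::runif(1, model$wall_ring_mm - 12, model$wall_ring_mm + 12)
          side <- sample.int(4L, 1); off <- stats::runif(1, -r, r)
          target <- switch(side, c(r, off), c(-r, off), c(off, r), c(off, -r))
        } else {
          cw <- model$center_halfwidth_mm
          target <- stats::runif(2, -cw, cw)
        }
      } else if (arrived) {
        # slow drift of the attractor while dwelling, so residence mass
        # spreads over a blob instead of accumulating at a point
        target <- pmin(195, pmax(-195, target + stats::rnorm(2, 0, 5)))
      }
      if (st == 0) {                       # stationary movement
        xs[[bi]] <- rep(pos[1], n); ys[[bi]] <- rep(pos[2], n)
        next
      }
      delta <- target - pos
      D <- sqrt(sum(delta^2))
      n1 <- min(n, max(1L, as.integer(ceiling(D / st))))
      dir <- if (D > 0) delta / D else c(0, 0)
      jx <- stats::rnorm(n1, 0, 0.3 * st); jy <- stats::rnorm(n1, 0, 0.3 * st)
      px <- reflect_arena(pos[1] + cumsum(dir[1] * st + jx))
      py <- reflect_arena(pos[2] + cumsum(dir[2] * st + jy))
      if (n1 < n) {                        # AR(1) wander around the attractor
        n2 <- n - n1
        dx <- stats::filter(stats::rnorm(n2, 0, st), phi,
                            method = "recursive", init = px[n1] - target[1])
        dy <- stats::filter(stats::rnorm(n2, 0, st), phi,
                            method = "recursive", init = py[n1] - target[2])
        px <- c(px, pmin(200, pmax(-200, target[1] + as.numeric(dx))))
        py <- c(py, pmin(200, pmax(-200, target[2] + as.numeric(dy))))
      }
      pos <- c(px[n], py[n])
      if (!arrived && sqrt(sum((target - pos)^2)) <= arrive_mm) arrived <- TRUE
      xs[[bi]] <- px; ys[[bi]] <- py
    }
    list(ethogram = ethogram(labels, frame_rate, animal_id),
         trajectory = trajectory(unlist(xs), unlist(ys), frame_rate, animal_id))
  })
}

#' Cohort design
#'
#' Group sizes and session parameters for a simulated cohort. The default
#' sizes reproduce the study layout this pipeline targets: males
#' KO 20 / HE 15 / WT 19 and females KO 21 / HE 12 / WT 17 (114 animals),
#' 60-minute sessions.
#'
#' @param sizes Data.frame with columns `genotype`, `sex`, `n`.
#' @param duration_s Session length, seconds.
#' @param frame_rate Frames per second.
#' @param seed Master seed; per-animal seeds are derived from it.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(sizes = NULL, duration_s = 3600, frame_rate = 30,
                          seed = 1) {
  if (is.null(sizes))
    sizes <- data.frame(
      genotype = rep(c("KO", "HE", "WT"), 2),
      sex = rep(c("M", "F"), each = 3),
      n = c(20L, 15L, 19L, 21L, 12L, 17L))
  stopifnot(all(c("genotype", "sex", "n") %in% names(sizes)),
            all(sizes$n >= 0), duration_s > 0)
  structure(list(sizes = sizes, duration_s = duration_s,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Derive a per-animal seed
#'
#' Stable 32-bit FNV-1a hash of `"<seed>/<animal_id>"`, reduced modulo
#' 2^31 - 1, so cohorts are reproducible animal by animal.
#'
#' @param seed Integer master seed.
#' @param animal_id Identifier string.
#' @return Integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, animal_id) {
  bytes <- utf8ToInt(paste0(seed, "/", animal_id))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- mul_mod32(h, 16777619)
  }
  as.integer(h %% 2147483647)
}

# xor of a 32-bit value held in a double with a byte
bitwXor_dbl <- function(h, b) {
  lo <- h %% 2^16; hi <- (h - lo) / 2^16
  hi * 2^16 + bitwXor(as.integer(lo), as.integer(b))
}

# (h * m) mod 2^32 without losing precision in doubles
mul_mod32 <- function(h, m) {
  lo <- h %% 2^16; hi <- (h - lo) / 2^16
  (lo * m + ((hi * m) %% 2^16) * 2^16) %% 2^32
}

#' Simulate a cohort
#'
#' One session per animal, with per-animal seeds derived deterministically
#' from the design seed via [derive_seed()]. Animal ids are
#' `<genotype>_<sex>_<index>`.
#'
#' @param design A [cohort_design()].
#' @param models Named list of [behavior_model()]s keyed `<genotype>_<sex>`;
#'   default [default_models()].
#' @return A [cohort()].
#' @export
simulate_cohort <- function(design = cohort_design(),
                            models = default_models()) {
  stopifnot(inherits(design, "cohort_design"))
  subs <- list(); eth <- list(); trj <- list()
  for (r in seq_len(nrow(design$sizes))) {
    g <- design$sizes$genotype[r]; s <- design$sizes$sex[r]
    n <- design$sizes$n[r]
    if (n == 0) next
    model <- models[[paste(g, s, sep = "_")]]
    if (is.null(model)) stop("no model for group ", g, "_", s, call. = FALSE)
    for (k in seq_len(n)) {
      id <- sprintf("%s_%s_%02d", g, s, k)
      sess <- simulate_session(model, design$duration_s, design$frame_rate,
                               seed = derive_seed(design$seed, id),
                               animal_id = id)
      subs[[id]] <- data.frame(animal_id = id, genotype = g, sex = s,
                               stringsAsFactors = FALSE)
      eth[[id]] <- sess$ethogram
      trj[[id]] <- sess$trajectory
    }
  }
  if (!length(subs))
    return(structure(list(subjects = data.frame(animal_id = character(),
                                                genotype = character(),
                                                sex = character()),
                          ethograms = list(), trajectories = list()),
                     class = "cohort"))
  cohort(do.call(rbind, subs), eth, trj)
}
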