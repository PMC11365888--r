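# Cluster-level behavioral transition networks. Frames are mapped to the 5
# clusters and maximal runs merged into events; each event is one state
# visit regardless of its duration. State probabilities and the event-level
# transition matrix are empirical counts; because merged fragments cannot
# repeat, the event matrix has a structurally zero diagonal, and
# self-transition is instead defined at movement-bout level within a cluster
# (e.g. walking -> stepping is a self-transition of locomotion).

#' Cluster event sequence of an ethogram
#'
#' @param ethogram An [ethogram()].
#' @param map Cluster map; default [cluster_map()].
#' @return Object of class `event_sequence`: data.frame with `cluster`,
#'   `start_frame`, `end_frame` (half-open), plus attribute `states`.
#' @export
to_events <- function(ethogram, map = cluster_map()) {
  stopifnot(inherits(ethogram, "ethogram"))
  seq_lab <- cluster_labels(ethogram, map)
  r <- rle(seq_lab)
  end <- cumsum(r$lengths)
  event_sequence(r$values, start_frame = end - r$lengths, end_frame = end)
}

#' Construct an event sequence directly
#'
#' @param cluster Character vector of cluster labels (adjacent duplicates
#'   are merged).
#' @param start_frame,end_frame Optional frame bounds; synthesized as unit
#'   intervals when omitted.
#' @return An `event_sequence`.
#' @export
event_sequence <- function(cluster, start_frame = NULL, end_frame = NULL) {
  cluster <- as.character(cluster)
  bad <- setdiff(unique(cluster), clusters())
  if (length(bad))
    stop("unknown clusters: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(start_frame)) {
    keep <- c(TRUE, cluster[-1] != cluster[-length(cluster)])
    cluster <- cluster[keep]
    start_frame <- seq_along(cluster) - 1L
    end_frame <- seq_along(cluster)
  }
  if (length(cluster) > 1L &&
      any(cluster[-1] == cluster[-length(cluster)]))
    stop("adjacent events must differ in cluster", call. = FALSE)
  structure(data.frame(cluster = cluster, start_frame = start_frame,
                       end_frame = end_frame, stringsAsFactors = FALSE),
            class = c("event_sequence", "data.frame"))
}

#' Estimate a cluster transition graph
#'
#' State probabilities (share of events per cluster), the event-level
#' transition matrix (rows normalized over observed transitions; zero
#' diagonal by construction), the movement-level self-transition probability
#' per cluster, and the pruned edge list retaining transitions with
#' probability at least `threshold`.
#'
#' @param events An [event_sequence()].
#' @param movement_bouts Optional [bouts_of()] table of the same session,
#'   used for within-cluster self-transitions; `NULL` leaves them `NA`.
#' @param threshold Pruning threshold on transition probability
#'   (default 0.05): edges with probability strictly below it are omitted
#'   from `pruned_edges`.
#' @param map Cluster map used for self-transitions.
#' @return Object of class `transition_graph` with `states`, `state_prob`,
#'   `counts`, `trans_prob`, `self_loop`, `pruned_edges`, `n_events`.
#' @export
transition_graph <- function(events, movement_bouts = NULL, threshold = 0.05,
                             map = cluster_map()) {
  stopifnot(inherits(events, "event_sequence"))
  st <- clusters()
  ev <- events$cluster
  n <- length(ev)
  if (n < 1L) stop("need at least one event", call. = FALSE)
  state_prob <- as.numeric(table(factor(ev, levels = st))) / n
  names(state_prob) <- st
  counts <- matrix(0, 5, 5, dimnames = list(st, st))
  single <- n < 2L
  if (!single) {
    tab <- table(factor(ev[-n], levels = st), factor(ev[-1], levels = st))
    counts <- unclass(tab)
    dimnames(counts) <- list(st, st)
  } else {
    warning("single event: transition probabilities undefined", call. = FALSE)
  }
  rs <- rowSums(counts)
  trans_prob <- counts / ifelse(rs > 0, rs, 1)
  trans_prob[rs == 0, ] <- NA_real_
  self_loop <- stats::setNames(rep(NA_real_, 5), st)
  if (!is.null(movement_bouts) && nrow(movement_bouts) > 1L) {
    bc <- unname(map[movement_bouts$movement])
    from <- bc[-length(bc)]; to <- bc[-1]
    for (s in st) {
      leaving <- from == s
      if (any(leaving)) self_loop[s] <- mean(to[leaving] == s)
    }
  }
  edges <- NULL
  if (!single) {
    idx <- which(!is.na(trans_prob) & trans_prob >= threshold, arr.ind = TRUE)
    edges <- data.frame(from = st[idx[, 1]], to = st[idx[, 2]],
                        probability = trans_prob[idx],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(states = st, state_prob = state_prob, counts = counts,
                 trans_prob = trans_prob, self_loop = self_loop,
                 threshold = threshold, pruned_edges = edges, n_events = n),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition_graph> %d events, %d edges >= %.2f\n",
              x$n_events, NROW(x$pruned_edges), x$threshold))
  print(round(x$state_prob, 3))
  invisible(x)
}

#' Group-level half-session similarity matrix
#'
#' Cross-animal similarity between timeframes: entry (i, j) correlates the
#' first-half fraction vector of animal i with the second-half vector of
#' animal j; the group similarity is the mean over all pairs, and the
#' diagonal holds each animal's own [half_similarity()].
#'
#' @inheritParams half_similarity
#' @param cohort A [cohort()].
#' @param genotype,sex Selectors (`NULL` = all).
#' @return List with `matrix` (animals x animals), `per_animal` (its
#'   diagonal) and `mean`.
#' @export
group_half_similarity <- function(cohort, genotype = NULL, sex = NULL,
                                  map = NULL, split_s = 1800,
                                  method = c("pearson", "cosine")) {
  method <- match.arg(method)
  keep <- rep(TRUE, nrow(cohort$subjects))
  if (!is.null(genotype)) keep <- keep & cohort$subjects$genotype %in% genotype
  if (!is.null(sex)) keep <- keep & cohort$subjects$sex %in% sex
  ids <- cohort$subjects$animal_id[keep]
  if (!length(ids)) stop("no animals match the selector", call. = FALSE)
  halves <- lapply(ids, function(id) {
    e <- cohort$ethograms[[id]]
    list(first = time_budget(window_ethogram(e, 0, split_s), map)$fractions,
         second = time_budget(window_ethogram(e, split_s, e$duration_s),
                              map)$fractions)
  })
  simil <- function(a, b) {
    if (method == "cosine") return(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  m <- outer(seq_along(ids), seq_along(ids),
             Vectorize(function(i, j) simil(halves[[i]]$first,
                                            halves[[j]]$second)))
  dimnames(m) <- list(ids, ids)
  list(matrix = m, per_animal = stats::setNames(diag(m), ids),
       mean = mean(m, na.rm = TRUE))
}

#' Group-mean transition graph
#'
#' Per-animal transition graphs averaged entry-wise (state probabilities,
#' transition matrices and self-loops), or estimated from events pooled
#' across animals.
#'
#' @param cohort A [cohort()].
#' @param genotype,sex Selectors (`NULL` = all).
#' @param window_s Optional `c(start, end)` seconds restricting each session.
#' @param threshold Pruning threshold.
#' @param pool `"animals"` (average per-animal estimates; default) or
#'   `"events"` (concatenate counts before normalizing).
#' @param map Cluster map.
#' @return A `transition_graph` (averaged matrices re-pruned at `threshold`).
#' @export
group_transition_graph <- function(cohort, genotype = NULL, sex = NULL,
                                   window_s = NULL, threshold = 0.05,
                                   pool = c("animals", "events"),
                                   map = cluster_map()) {
  pool <- match.arg(pool)
  keep <- rep(TRUE, nrow(cohort$subjects))
  if (!is.null(genotype)) keep <- keep & cohort$subjects$genotype %in% genotype
  if (!is.null(sex)) keep <- keep & cohort$subjects$sex %in% sex
  ids <- cohort$subjects$animal_id[keep]
  if (!length(ids)) stop("no animals match the selector", call. = FALSE)
  graphs <- lapply(ids, function(id) {
    e <- cohort$ethograms[[id]]
    if (!is.null(window_s)) e <- window_ethogram(e, window_s[1], window_s[2])
    transition_graph(to_events(e, map), bouts_of(e), threshold, map)
  })
  st <- clusters()
  if (pool == "events") {
    counts <- Reduce(`+`, lapply(graphs, `[[`, "counts"))
    rs <- rowSums(counts)
    trans_prob <- counts / ifelse(rs > 0, rs, 1)
    trans_prob[rs == 0, ] <- NA_real_
    state_prob <- Reduce(`+`, lapply(graphs, function(g)
      g$state_prob * g$n_events))
    state_prob <- state_prob / sum(state_prob)
    self_loop <- colMeans(do.call(rbind, lapply(graphs, `[[`, "self_loop")),
                          na.rm = TRUE)
  } else {
    state_prob <- colMeans(do.call(rbind, lapply(graphs, `[[`, "state_prob")))
    trans_prob <- Reduce(`+`, lapply(graphs, function(g) {
      m <- g$trans_prob; m[is.na(m)] <- 0; m
    })) / length(graphs)
    counts <- Reduce(`+`, lapply(graphs, `[[`, "counts"))
    self_loop <- colMeans(do.call(rbind, lapply(graphs, `[[`, "self_loop")),
                          na.rm = TRUE)
  }
  idx <- which(!is.na(trans_prob) & trans_prob >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = st[idx[, 1]], to = st[idx[, 2]],
                      probability = trans_prob[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(states = st, state_prob = state_prob, counts = counts,
                 trans_prob = trans_prob, self_loop = self_loop,
                 threshold = threshold, pruned_edges = edges,
                 n_events = sum(vapply(graphs, `[[`, 1, "n_events")),
                 n_animals = length(ids)),
            class = "transition_graph")
}

#' Restrict an ethogram to a time window
#'
#' @param ethogram An [ethogram()].
#' @param start_s,end_s Window bounds in seconds (half-open).
#' @return The windowed [ethogram()].
#' @export
window_ethogram <- function(ethogram, start_s, end_s) {
  i0 <- floor(start_s * ethogram$frame_rate) + 1L
  i1 <- min(ethogram$n_frames, floor(end_s * ethogram$frame_rate))
  if (i0 > i1) stop("empty window", call. = FALSE)
  ethogram(as.character(ethogram$labels)[i0:i1], ethogram$frame_rate,
           ethogram$animal_id)
}

#' Betweenness centrality of a transition graph
#'
#' Directed betweenness centrality on the pruned network, normalized by
#' `(n-1)(n-2)`. By default edges are weighted with distance
#' `-log(probability)`, so high-probability transitions are short paths; an
#' unweighted variant treats every retained edge as length 1. States with no
#' retained edges score 0.
#'
#' @param graph A [transition_graph()], or a data.frame of edges
#'   (`from`, `to`, `probability`).
#' @param states Vertex set; defaults to the graph's states (or the states
#'   present in the edge list).
#' @param weighted Use `-log(probability)` edge lengths (default `TRUE`).
#' @return Named numeric vector of normalized centralities.
#' @export
betweenness_centrality <- function(graph, states = NULL, weighted = TRUE) {
  edges <- if (inherits(graph, "transition_graph")) graph$pruned_edges
           else graph
  if (is.null(states))
    states <- if (inherits(graph, "transition_graph")) graph$states
              else unique(c(edges$from, edges$to))
  if (is.null(edges) || nrow(edges) == 0)
    return(stats::setNames(rep(0, length(states)), states))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = states)
  # igraph needs strictly positive weights; a certain transition (p = 1)
  # gets a vanishingly short edge rather than length 0
  w <- if (weighted) pmax(-log(edges$probability), 1e-6) else NULL
  b <- igraph::betweenness(g, directed = TRUE, weights = w,
                           normalized = TRUE)
  stats::setNames(as.numeric(b[states]), states)
}

#' First-half vs second-half behavioral similarity
#'
#' Pearson correlation (or cosine similarity) between the movement-fraction
#' vectors of the session's two halves; a cluster map switches to the
#' 5-cluster vectors. If either half has zero variance across labels the
#' similarity is undefined and `NA` is returned with a warning.
#'
#' @param ethogram An [ethogram()].
#' @param map Optional cluster map for cluster-level similarity.
#' @param split_s Split point in seconds (default 1800).
#' @param method `"pearson"` (default) or `"cosine"`.
#' @return Similarity in `[-1, 1]`, or `NA` when undefined.
#' @export
half_similarity <- function(ethogram, map = NULL, split_s = 1800,
                            method = c("pearson", "cosine")) {
  method <- match.arg(method)
  stopifnot(inherits(ethogram, "ethogram"))
  if (ethogram$duration_s <= split_s)
    stop("session must be longer than split_s", call. = FALSE)
  a <- time_budget(window_ethogram(ethogram, 0, split_s), map)$fractions
  b <- time_budget(window_ethogram(ethogram, split_s, ethogram$duration_s),
                   map)$fractions
  if (method == "cosine")
    return(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance fraction vector; similarity undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}
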