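#' The 13-movement open-field vocabulary
#'
#' The closed set of spontaneous movement labels recognized by the pipeline.
#' Six locomotor gaits/turns, four exploratory postures, hunching, grooming
#' and pausing. Extension requires an explicit override of the cluster map,
#' because the downstream cluster ontology is defined as a total partition of
#' exactly these labels.
#'
#' @return Character vector of the 13 movement names, in canonical order.
#' @seealso [clusters()], [cluster_map()]
#' @export
#' @examples
#' movements()
movements <- function() {
  c("running", "trotting", "walking", "right_turning", "left_turning",
    "stepping", "rearing", "climbing", "hunching", "rising", "sniffing",
    "grooming", "pausing")
}

#' The 5 behavioral clusters
#'
#' Functional groupings of the 13 movements: `locomotion`, `exploration`,
#' `forced_posture` (hunching), `maintenance` (grooming) and `nap` (pausing).
#'
#' @return Character vector of the 5 cluster names.
#' @export
clusters <- function() {
  c("locomotion", "exploration", "forced_posture", "maintenance", "nap")
}

#' The movement-to-cluster map
#'
#' The fixed total mapping from each of the 13 movements to one of the 5
#' clusters. This partition is the package default and is treated as
#' immutable; pass a modified copy explicitly to override it.
#'
#' @return Named character vector: `names` are movements, values are clusters.
#' @export
#' @examples
#' cluster_map()[["grooming"]]  # "maintenance"
cluster_map <- function() {
  c(running = "locomotion", trotting = "locomotion", walking = "locomotion",
    right_turning = "locomotion", left_turning = "locomotion",
    stepping = "locomotion",
    rearing = "exploration", climbing = "exploration",
    rising = "exploration", sniffing = "exploration",
    hunching = "forced_posture",
    grooming = "maintenance",
    pausing = "nap")
}

#' Read / write a cluster map as YAML
#'
#' The YAML file maps each cluster to the list of movements it contains.
#' The shipped default ([cluster_map()]) is the reference ontology; reading
#' a custom file allows an explicit override.
#'
#' @param map Named character vector (movement -> cluster).
#' @param path YAML file path.
#' @return `write_cluster_map()` returns `path` invisibly;
#'   `read_cluster_map()` returns a validated named character vector.
#' @export
write_cluster_map <- function(map = cluster_map(), path) {
  assert_cluster_map(map)
  by_cluster <- lapply(stats::setNames(nm = clusters()),
                       function(cl) as.list(names(map)[map == cl]))
  yaml::write_yaml(by_cluster, path)
  invisible(path)
}

#' @rdname write_cluster_map
#' @export
read_cluster_map <- function(path) {
  raw <- yaml::read_yaml(path)
  map <- unlist(lapply(names(raw), function(cl)
    stats::setNames(rep(cl, length(raw[[cl]])),
                    normalize_label(unlist(raw[[cl]])))))
  assert_cluster_map(map)
  map[movements()]
}

#' @keywords internal
assert_cluster_map <- function(map) {
  if (!is.character(map) || is.null(names(map)))
    stop("cluster map must be a named character vector", call. = FALSE)
  missing <- setdiff(movements(), names(map))
  if (length(missing))
    stop("cluster map is missing movements: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unname(map), clusters())
  if (length(bad))
    stop("unknown clusters in map: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  invisible(map)
}

# Normalize a raw label string to the canonical lower_snake_case form.
# Accepts case variants, surrounding whitespace, and space/hyphen separators.
#' @keywords internal
normalize_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ -]+", "_", x)
}

#' @keywords internal
check_movement_labels <- function(labels, where = "label") {
  bad <- which(!(labels %in% movements()))
  if (length(bad))
    stop("unknown movement '", labels[bad[1]], "' (", where, " ", bad[1], ")",
         call. = FALSE)
  invisible(labels)
}
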