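#' Construct an ethogram
#'
#' An ethogram is the frame-wise record of an animal's behavior: one movement
#' label per video frame at a constant frame rate. It is the central object of
#' the pipeline; every time-budget, transition and discrimination analysis
#' starts from it.
#'
#' @param labels Character vector (or factor) of movement labels, one per
#'   frame, drawn from [movements()]. Labels are normalized (case, whitespace,
#'   space/hyphen separators) before validation.
#' @param frame_rate Acquisition rate in frames per second (> 0). Default 30.
#' @param animal_id Identifier string for the animal.
#' @return An object of class `ethogram`: list with `animal_id`, `frame_rate`,
#'   `labels` (factor over the 13 movements), `n_frames` and `duration_s`.
#' @export
#' @examples
#' e <- ethogram(c("walking", "walking", "pausing"), frame_rate = 30)
#' e$duration_s  # 0.1
ethogram <- function(labels, frame_rate = 30, animal_id = "animal") {
  if (length(labels) == 0L) stop("ethogram must be non-empty", call. = FALSE)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a single positive number", call. = FALSE)
  lab <- normalize_label(as.character(labels))
  check_movement_labels(lab, where = "frame")
  structure(
    list(animal_id = as.character(animal_id),
         frame_rate = as.numeric(frame_rate),
         labels = factor(lab, levels = movements()),
         n_frames = length(lab),
         duration_s = length(lab) / frame_rate),
    class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> %s: %d frames @ %g fps (%.1f s), %d bouts\n",
              x$animal_id, x$n_frames, x$frame_rate, x$duration_s,
              nrow(bouts_of(x))))
  invisible(x)
}

#' Construct a trajectory
#'
#' Back-keypoint positions in millimetres in a center-origin arena frame
#' (x rightward, y toward the far wall). The arena floor is the 400 x 400 mm
#' square `[-200, 200]^2`; calibrated coordinates must lie inside it.
#'
#' @param x,y Numeric vectors of coordinates in mm, one per frame.
#' @param frame_rate Frames per second. Default 30.
#' @param animal_id Identifier string.
#' @return An object of class `trajectory`: list with `animal_id`,
#'   `frame_rate`, `x`, `y`, `n_frames`, `duration_s`.
#' @export
trajectory <- function(x, y, frame_rate = 30, animal_id = "animal") {
  if (length(x) == 0L || length(x) != length(y))
    stop("x and y must be non-empty and of equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y)) {
    i <- which(is.na(x) | is.na(y))[1]
    stop("missing coordinate at frame ", i - 1L, call. = FALSE)
  }
  out <- which(abs(x) > 200 | abs(y) > 200)
  if (length(out))
    stop("coordinate outside the calibrated arena (|x|,|y| <= 200 mm) at frame ",
         out[1] - 1L, call. = FALSE)
  structure(
    list(animal_id = as.character(animal_id),
         frame_rate = as.numeric(frame_rate),
         x = as.numeric(x), y = as.numeric(y),
         n_frames = length(x),
         duration_s = length(x) / frame_rate),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d frames @ %g fps (%.1f s)\n",
              x$animal_id, x$n_frames, x$frame_rate, x$duration_s))
  invisible(x)
}

#' Movement bouts of an ethogram
#'
#' A bout is a maximal run of consecutive frames sharing one movement label.
#' Bouts tile the ethogram exactly; frame intervals are half-open
#' `[start_frame, end_frame)` with 0-based frame indices.
#'
#' @param ethogram An [ethogram()].
#' @return A data.frame with columns `movement`, `start_frame`, `end_frame`
#'   (half-open), `n_frames`, `duration_s`.
#' @export
#' @examples
#' bouts_of(ethogram(c("walking", "walking", "pausing"), 30))
bouts_of <- function(ethogram) {
  stopifnot(inherits(ethogram, "ethogram"))
  r <- rle(as.character(ethogram$labels))
  end <- cumsum(r$lengths)
  data.frame(movement = r$values,
             start_frame = end - r$lengths,
             end_frame = end,
             n_frames = r$lengths,
             duration_s = r$lengths / ethogram$frame_rate,
             stringsAsFactors = FALSE)
}

#' Rebuild an ethogram from a bout table
#'
#' Inverse of [bouts_of()]: expands the run-length encoded bout table back to
#' a frame-wise ethogram.
#'
#' @param bouts Data.frame as returned by [bouts_of()].
#' @inheritParams ethogram
#' @return An [ethogram()].
#' @export
ethogram_from_bouts <- function(bouts, frame_rate = 30, animal_id = "animal") {
  ethogram(rep(bouts$movement, bouts$end_frame - bouts$start_frame),
           frame_rate = frame_rate, animal_id = animal_id)
}

# ---- file I/O ---------------------------------------------------------------

# CSV formats are comma-delimited UTF-8 with optional '#'-prefixed comment
# lines; the writer records the frame rate as '# frame_rate=<fps>' which the
# reader honors when no explicit frame_rate argument is given.

#' @keywords internal
read_commented_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  comments <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  m <- regmatches(comments, regexec("frame_rate\\s*=\\s*([0-9.]+)", comments))
  fr <- vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_, "")
  fr <- fr[!is.na(fr)]
  if (length(fr)) meta$frame_rate <- as.numeric(fr[1])
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, strip.white = TRUE)
  list(data = df, meta = meta)
}

#' Read an ethogram CSV
#'
#' Expects a header `frame,label` (an optional `time_s` column is ignored) and
#' frame indices that are contiguous. Labels are normalized and validated
#' against the 13-movement vocabulary; frames are re-indexed from 0.
#'
#' @param path Path to the CSV file.
#' @param frame_rate Frames per second; if `NULL`, taken from a
#'   `# frame_rate=` comment line in the file, else defaults to 30.
#' @param animal_id Identifier; defaults to the file name without extension.
#' @return An [ethogram()].
#' @export
read_ethogram <- function(path, frame_rate = NULL, animal_id = NULL) {
  parsed <- read_commented_csv(path)
  df <- parsed$data
  if (!all(c("frame", "label") %in% names(df)))
    stop("ethogram CSV must have columns 'frame' and 'label'", call. = FALSE)
  fr <- df$frame
  if (length(fr) && any(diff(fr) != 1L))
    stop("non-contiguous frame indices in ", path, call. = FALSE)
  if (is.null(frame_rate)) frame_rate <- parsed$meta$frame_rate %||% 30
  if (is.null(animal_id))
    animal_id <- sub("\\.[^.]*$", "", basename(path))
  lab <- normalize_label(df$label)
  bad <- which(!(lab %in% movements()))
  if (length(bad))
    stop("unknown movement '", df$label[bad[1]], "' at row ", bad[1],
         " of ", path, call. = FALSE)
  ethogram(lab, frame_rate = frame_rate, animal_id = animal_id)
}

#' Read a trajectory CSV
#'
#' Expects a header `frame,x_mm,y_mm` with calibrated center-origin
#' coordinates in mm.
#'
#' @inheritParams read_ethogram
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, frame_rate = NULL, animal_id = NULL) {
  parsed <- read_commented_csv(path)
  df <- parsed$data
  if (!all(c("frame", "x_mm", "y_mm") %in% names(df)))
    stop("trajectory CSV must have columns 'frame', 'x_mm', 'y_mm'",
         call. = FALSE)
  if (length(df$frame) && any(diff(df$frame) != 1L))
    stop("non-contiguous frame indices in ", path, call. = FALSE)
  if (is.null(frame_rate)) frame_rate <- parsed$meta$frame_rate %||% 30
  if (is.null(animal_id))
    animal_id <- sub("\\.[^.]*$", "", basename(path))
  trajectory(df$x_mm, df$y_mm, frame_rate = frame_rate, animal_id = animal_id)
}

#' Write an ethogram / trajectory CSV
#'
#' Writers for the package's plain-text formats. A `# frame_rate=` comment
#' line carries the frame rate so that a read/write round-trip is lossless.
#'
#' @param x An [ethogram()] or [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ethogram <- function(x, path) {
  stopifnot(inherits(x, "ethogram"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%g", x$frame_rate), con)
  utils::write.csv(
    data.frame(frame = seq_len(x$n_frames) - 1L,
               label = as.character(x$labels)),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ethogram
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "trajectory"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%g", x$frame_rate), con)
  utils::write.csv(
    data.frame(frame = seq_len(x$n_frames) - 1L, x_mm = x$x, y_mm = x$y),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- cohort -----------------------------------------------------------------

#' Construct a cohort
#'
#' A cohort bundles subject metadata with one ethogram and one paired
#' trajectory per animal.
#'
#' @param subjects Data.frame with columns `animal_id`, `genotype`
#'   (`WT`/`HE`/`KO`) and `sex` (`M`/`F`).
#' @param ethograms,trajectories Named lists keyed by `animal_id`.
#' @return An object of class `cohort`.
#' @export
cohort <- function(subjects, ethograms, trajectories) {
  stopifnot(is.data.frame(subjects),
            all(c("animal_id", "genotype", "sex") %in% names(subjects)))
  if (anyDuplicated(subjects$animal_id))
    stop("duplicate animal_id in subjects table", call. = FALSE)
  if (!all(subjects$genotype %in% c("WT", "HE", "KO")))
    stop("genotype must be one of WT, HE, KO", call. = FALSE)
  if (!all(subjects$sex %in% c("M", "F")))
    stop("sex must be M or F", call. = FALSE)
  ids <- subjects$animal_id
  for (id in ids) {
    if (is.null(ethograms[[id]]))
      stop("missing ethogram for ", id, call. = FALSE)
    if (is.null(trajectories[[id]]))
      stop("missing trajectory for ", id, call. = FALSE)
    if (ethograms[[id]]$n_frames != trajectories[[id]]$n_frames)
      stop("ethogram/trajectory length mismatch for ", id, call. = FALSE)
  }
  structure(list(subjects = subjects,
                 ethograms = ethograms[ids],
                 trajectories = trajectories[ids]),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$subjects$genotype, x$subjects$sex)
  cat(sprintf("<cohort> %d animals\n", nrow(x$subjects)))
  print(tab)
  invisible(x)
}

#' Number of animals in a cohort
#' @param cohort A [cohort()].
#' @return Integer count.
#' @export
n_animals <- function(cohort) nrow(cohort$subjects)

#' Write / read a cohort directory
#'
#' A cohort directory holds `subjects.csv` plus `ethograms/<id>.csv` and
#' `trajectories/<id>.csv` in the package's plain-text formats.
#'
#' @param x A [cohort()].
#' @param dir Directory path (created if needed).
#' @return The directory (write) or a [cohort()] (read).
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(file.path(dir, "ethograms"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "trajectories"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE, quote = FALSE)
  for (id in x$subjects$animal_id) {
    write_ethogram(x$ethograms[[id]],
                   file.path(dir, "ethograms", paste0(id, ".csv")))
    write_trajectory(x$trajectories[[id]],
                     file.path(dir, "trajectories", paste0(id, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  eth <- list(); trj <- list()
  for (id in subjects$animal_id) {
    eth[[id]] <- read_ethogram(file.path(dir, "ethograms", paste0(id, ".csv")),
                               animal_id = id)
    trj[[id]] <- read_trajectory(
      file.path(dir, "trajectories", paste0(id, ".csv")), animal_id = id)
  }
  cohort(subjects, eth, trj)
}
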