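#' Construct a trajectory object
#'
#' A trajectory is one individual's regularly sampled 2-D path: positions are
#' observed every \code{frame_interval} seconds with no missing frames, so
#' position \code{i} corresponds to time \code{(i - 1) * frame_interval}.
#'
#' @param id Single string identifying the individual.
#' @param positions Two-column numeric matrix (or data frame) of x, y
#'   coordinates, one row per frame, in a single length unit.
#' @param frame_interval Sampling interval in seconds (> 0); the study design
#'   this package targets used 30 s time-lapse frames.
#' @param treatment Optional single string with the treatment label.
#' @param unit Length unit of the coordinates (informational), e.g.
#'   \code{"px"} or \code{"cm"}.
#'
#' @return An object of class \code{"trajectory"}: a list with elements
#'   \code{id}, \code{treatment}, \code{frame_interval}, \code{positions}
#'   (n x 2 matrix), \code{unit}.
#' @examples
#' tr <- trajectory("u1", cbind(0:5, 0), frame_interval = 30)
#' n_steps(tr)
#' @export
trajectory <- function(id, positions, frame_interval = 30,
                       treatment = NA_character_, unit = "px") {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 2L)
    stop("`positions` must be a two-column numeric matrix", call. = FALSE)
  if (nrow(positions) < 2L)
    stop("a trajectory needs at least 2 positions", call. = FALSE)
  if (!all(is.finite(positions)))
    stop("all coordinates must be finite", call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be a single positive number", call. = FALSE)
  dimnames(positions) <- list(NULL, c("x", "y"))
  structure(
    list(id = as.character(id), treatment = as.character(treatment),
         frame_interval = as.numeric(frame_interval),
         positions = positions, unit = as.character(unit)),
    class = "trajectory")
}

#' Number of steps (displacements) in a trajectory
#' @param traj A \code{\link{trajectory}}.
#' @return Integer, \code{nrow(positions) - 1}.
#' @export
n_steps <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nrow(traj$positions) - 1L
}

# Step displacement vectors (n_steps x 2).
step_vectors <- function(traj) {
  p <- traj$positions
  p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
}

# Euclidean step lengths.
step_lengths <- function(traj) {
  d <- step_vectors(traj)
  sqrt(d[, 1L]^2 + d[, 2L]^2)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s'> %d positions (%d steps), dt = %gs, unit = %s",
              x$id, nrow(x$positions), n_steps(x), x$frame_interval, x$unit))
  if (!is.na(x$treatment)) cat(sprintf(", treatment = %s", x$treatment))
  cat("\n")
  invisible(x)
}

#' Construct a study dataset
#'
#' A labelled collection of trajectories, typically spanning two treatment
#' groups (e.g. control vs predator-cue trials).
#'
#' @param trajectories List of \code{\link{trajectory}} objects with unique
#'   ids.
#' @return An object of class \code{"study_dataset"}.
#' @examples
#' d <- study_dataset(list(
#'   trajectory("a", cbind(0:3, 0), treatment = "control"),
#'   trajectory("b", cbind(0, 0:3), treatment = "predator")))
#' treatments(d)
#' @export
study_dataset <- function(trajectories) {
  if (!is.list(trajectories) ||
      !all(vapply(trajectories, inherits, logical(1), "trajectory")))
    stop("`trajectories` must be a list of trajectory objects", call. = FALSE)
  ids <- vapply(trajectories, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("trajectory ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(trajectories) <- ids
  structure(list(trajectories = trajectories), class = "study_dataset")
}

#' Treatment labels present in a dataset
#' @param dataset A \code{\link{study_dataset}}.
#' @return Character vector of unique non-missing treatment labels.
#' @export
treatments <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  tr <- vapply(dataset$trajectories, `[[`, character(1), "treatment")
  sort(unique(tr[!is.na(tr)]))
}

#' @export
print.study_dataset <- function(x, ...) {
  tr <- vapply(x$trajectories, `[[`, character(1), "treatment")
  cat(sprintf("<study_dataset> %d trajectories\n", length(x$trajectories)))
  if (any(!is.na(tr))) {
    tab <- table(tr, useNA = "ifany")
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.study_dataset <- function(x) length(x$trajectories)

#' @export
`[[.study_dataset` <- function(x, i) x$trajectories[[i]]

#' Convert a dataset to a long data frame
#'
#' One row per (id, frame) with columns \code{id}, \code{frame} (0-based),
#' \code{x}, \code{y}, \code{treatment}, \code{frame_interval}, \code{unit} --
#' the same long layout \code{\link{read_trajectories}} accepts.
#'
#' @param x A \code{\link{study_dataset}}.
#' @param ... Unused.
#' @export
as.data.frame.study_dataset <- function(x, ...) {
  do.call(rbind, lapply(x$trajectories, function(tr) {
    n <- nrow(tr$positions)
    data.frame(id = tr$id, frame = seq_len(n) - 1L,
               x = tr$positions[, 1L], y = tr$positions[, 2L],
               treatment = tr$treatment, frame_interval = tr$frame_interval,
               unit = tr$unit, row.names = NULL)
  }))
}
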