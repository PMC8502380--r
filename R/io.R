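#' Read trajectories from a long ("tidy") CSV
#'
#' The canonical on-disk format is one row per observed frame with columns
#' \code{id}, \code{frame}, \code{x}, \code{y} and optional \code{treatment},
#' \code{frame_interval}, \code{unit}. Frames must number consecutively per
#' individual (any start value, step 1): a gap means a missed frame, which is
#' an error, never silently repaired -- the downstream metrics assume strictly
#' regular sampling.
#'
#' @param path Path to a CSV file.
#' @param frame_interval Default sampling interval in seconds, used when the
#'   file carries no \code{frame_interval} column. Defaults to 30 s.
#' @param scale Optional multiplicative factor applied to x and y on read
#'   (e.g. cm per pixel). Metrics downstream are unit-covariant and the
#'   dimensionless ones (straightness, zeta(q), entropy) unit-invariant.
#' @param unit Unit label recorded when the file has no \code{unit} column.
#' @return A \code{\link{study_dataset}}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = "u1", frame = 0:3, x = 0:3, y = 0),
#'           f, row.names = FALSE)
#' read_trajectories(f)
#' @export
read_trajectories <- function(path, frame_interval = 30, scale = NULL,
                              unit = "px") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "frame", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("format error: x and y must be numeric", call. = FALSE)
  trajs <- lapply(split(df, df$id), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    id <- g$id[1L]
    if (anyDuplicated(g$frame))
      stop("integrity error: duplicated (id, frame) for id '", id, "'",
           call. = FALSE)
    gaps <- which(diff(g$frame) != 1L)
    if (length(gaps))
      stop("integrity error: id '", id, "' missing frame ",
           g$frame[gaps[1L]] + 1L, call. = FALSE)
    xy <- cbind(g$x, g$y)
    if (!is.null(scale)) xy <- xy * scale
    trajectory(
      id = id, positions = xy,
      frame_interval = if ("frame_interval" %in% names(g))
        g$frame_interval[1L] else frame_interval,
      treatment = if ("treatment" %in% names(g))
        as.character(g$treatment[1L]) else NA_character_,
      unit = if (!is.null(scale)) "scaled"
             else if ("unit" %in% names(g)) as.character(g$unit[1L]) else unit)
  })
  study_dataset(unname(trajs))
}

#' Write a study dataset to the long CSV format
#'
#' Numeric columns are written with 17 significant digits so that
#' \code{read_trajectories(write_trajectories(x))} reproduces every
#' coordinate exactly.
#'
#' @param dataset A \code{\link{study_dataset}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectories <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  df <- as.data.frame(dataset)
  df$x <- format_full(df$x)
  df$y <- format_full(df$y)
  df$frame_interval <- format_full(df$frame_interval)
  write_csv_checked(df, path)
}

#' Write a per-individual metrics table to CSV
#'
#' Writes one row per trajectory id with full-precision numerics, so a
#' write/read round trip reproduces the values bit-for-bit (see
#' \code{\link{read_metrics}}).
#'
#' @param metrics Data frame with one row per trajectory id (as produced by
#'   \code{\link{trajectory_metrics}}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(is.data.frame(metrics))
  if ("id" %in% names(metrics) && anyDuplicated(metrics$id))
    stop("metrics must have one row per trajectory id", call. = FALSE)
  out <- metrics
  for (nm in names(out)) out[[nm]] <- format_full(out[[nm]])
  write_csv_checked(out, path)
}

#' Read back a metrics table written by \code{write_metrics}
#' @param path CSV file path.
#' @return Data frame with numeric columns restored.
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

write_csv_checked <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("I/O error writing '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}
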