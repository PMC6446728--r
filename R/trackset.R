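# Core S3 container: a trackset is a data.frame of time-stamped positions
# (one row per cell per timepoint) carrying acquisition metadata as
# attributes.  Units are fixed package-wide: time in minutes, positions in
# micrometres; readers never convert.

#' Named error conditions
#'
#' All validation failures in the package signal classed conditions so
#' callers can distinguish them with `tryCatch(..., ivm_missing_column = )`
#' and friends. The condition class is always `c(<class>, "ivm_error")`.
#'
#' @param class condition class, e.g. `"ivm_missing_column"`.
#' @param msg message.
#' @noRd
ivm_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ivm_error")))
}

#' Construct a trackset
#'
#' A `trackset` holds the trajectories of one imaging position (or one
#' simulated cohort): a data.frame with columns `track_id`, `t` (minutes),
#' `x`, `y` and optionally `z` (micrometres), plus optional cohort label
#' columns `disease`, `stage` and `epoch`. The frame interval (minutes
#' between consecutive frames) and dimensionality are stored as attributes.
#'
#' @param points data.frame with at least `track_id`, `t`, `x`, `y`;
#'   `z` present iff the data are three-dimensional.
#' @param frame_interval minutes between frames; if `NULL`, inferred as the
#'   modal time step between consecutive points within tracks.
#' @param provenance free-text metadata string.
#' @return An object of class `trackset` (a data.frame sorted by
#'   `track_id`, `t`, with attributes `frame_interval` and `dims`).
#' @examples
#' pts <- data.frame(track_id = "a", t = c(0, 3, 6), x = c(0, 1, 2), y = 0)
#' ts <- trackset(pts)
#' frame_interval(ts)
#' @export
trackset <- function(points, frame_interval = NULL, provenance = "") {
  stopifnot(is.data.frame(points))
  need <- c("track_id", "t", "x", "y")
  miss <- setdiff(need, names(points))
  if (length(miss) > 0) {
    ivm_stop("ivm_missing_column",
             paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  has_z <- "z" %in% names(points)
  coord_cols <- c("t", "x", "y", if (has_z) "z")
  for (cc in coord_cols) {
    v <- points[[cc]]
    if (!is.numeric(v)) {
      ivm_stop("ivm_nonnumeric", paste0("column '", cc, "' is not numeric"))
    }
    if (anyNA(v) || any(!is.finite(v))) {
      ivm_stop("ivm_nonnumeric", paste0("column '", cc, "' contains non-finite values"))
    }
  }
  if (nrow(points) > 0 && any(points$t < 0)) {
    ivm_stop("ivm_invalid_time", "times must be >= 0")
  }
  points$track_id <- as.character(points$track_id)
  keep <- intersect(c("track_id", "t", "x", "y", if (has_z) "z",
                      "disease", "stage", "epoch"), names(points))
  points <- points[order(points$track_id, points$t), keep, drop = FALSE]
  rownames(points) <- NULL
  if (anyDuplicated(points[c("track_id", "t")]) > 0) {
    ivm_stop("ivm_duplicate_timepoint",
             "duplicate (track_id, t) rows: broken export?")
  }
  if (is.null(frame_interval)) frame_interval <- infer_frame_interval(points)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    ivm_stop("ivm_invalid_frame_interval", "frame_interval must be a single positive number")
  }
  structure(points,
            frame_interval = frame_interval,
            dims = if (has_z) 3L else 2L,
            provenance = provenance,
            class = c("trackset", "data.frame"))
}

# Modal time step between consecutive within-track points (1 if no steps).
infer_frame_interval <- function(points) {
  d <- unlist(lapply(split(points$t, points$track_id), diff), use.names = FALSE)
  if (length(d) == 0) return(1)
  d <- round(d, 9)
  tab <- table(d)
  as.numeric(names(tab)[which.max(tab)])
}

#' @rdname trackset
#' @param x,ts a `trackset`.
#' @export
is_trackset <- function(x) inherits(x, "trackset")

#' @rdname trackset
#' @export
frame_interval <- function(ts) attr(ts, "frame_interval")

#' @rdname trackset
#' @export
track_dims <- function(ts) attr(ts, "dims")

#' @rdname trackset
#' @export
n_tracks <- function(ts) length(unique(ts$track_id))

#' @rdname trackset
#' @export
track_ids <- function(ts) unique(ts$track_id)

# Coordinate column names for a trackset / track data.frame.
coord_cols <- function(df) c("x", "y", if ("z" %in% names(df)) "z")

#' Split a trackset into per-track data.frames
#'
#' @param ts a `trackset`.
#' @return Named list of data.frames, one per track, rows time-ordered.
#' @export
split_tracks <- function(ts) {
  split(as.data.frame(ts), factor(ts$track_id, levels = unique(ts$track_id)))
}

#' Restrict a trackset to one epoch
#'
#' @param ts a `trackset` with an `epoch` label column.
#' @param epoch `"pre"` or `"post"`.
#' @return A `trackset` with only the requested epoch's points; tracks with
#'   no points in that epoch are dropped.
#' @export
epoch_subset <- function(ts, epoch) {
  if (!"epoch" %in% names(ts)) {
    ivm_stop("ivm_missing_column", "trackset has no 'epoch' column")
  }
  trackset(as.data.frame(ts)[ts$epoch == epoch, , drop = FALSE],
           frame_interval = frame_interval(ts),
           provenance = paste0(attr(ts, "provenance"), " [epoch=", epoch, "]"))
}

#' @export
print.trackset <- function(x, ...) {
  cat(sprintf("<trackset> %d tracks, %d points, %dD, frame interval %g min\n",
              n_tracks(x), nrow(x), track_dims(x), frame_interval(x)))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("provenance:", prov, "\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
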